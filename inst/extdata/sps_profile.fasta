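>SPS_bact1
MTFALEVTRHEFQYVRDKEFPFYCTTCLMRIEEVPFECVDTCGGCYDCGLIFADHEPLKUYKMDSFQFCVTVFQIIELHLVMWSTNLFSIGAPQFKSMLLAWTQQRGRMFSTTVCGGGYR
>SPS_bact2
MTFALEVTRHEFQYVRDKEFPFYCIDAAERTKEVPFECVDTVGTCYDCGLIFATHEPLKUYKMDSFQFCVTVFPIMEEHLYPWSTNKMSIGAPQFKSMLLAWTQQRGRMFSTTACGGGYR
>SPS_arch1
MTFALEVTRHEFLSVRDKE---YCIDALMRKEEVPFEVVDTVGGCYDRGLIFATHEPLKUYKMDSAQFCVTVKQIIERHLVDWSTNHMSIGYPQFKSMLLAWTQQRGRMFSTTVCGGGYR
>SPS_vert1
MTFALEVTRHEFQYWRDKEFPFVCILCLMRIEEVGFEYVDTVGMCFDCGLIFATHEPLKUWKMDSFQFCVKVFQILREHTVPWSTNKMSIGAPQFKSMLLKWTQQYMRMFSTTVCHEGYV
>SPS_vert2
MTFALEVPRHFFNYGRDKEFPMYCIDALMRGEEVPFCVVDTVDGCYDQGLIFATHPPLKUYKMDSFQFCVTVNQHSEEHLEPWSTNKMSIGAPQFASMLLAWTQQRYCMFQTTVYGGGYR
>SPS_fish1
MTFSLEVTRHWFQYVRDQEWHFCCIFALMRIEEVPFECVDTVAGCYLCGLIFATHEPLKUYKMDSFQFNVTVFQIIEEHLVPESTNKMSIGAQQVPSMLLWWTLQRGRMFSTTTCGYGYR
>SPS_nem1
MTKALEMTRTEFQYGRDKEFPFYCIDALMRREEVPFECLDTVGGCYDCGLIFATHEPLYCYKMDSFQFCVTVFQIIENHLVPWSTFKMSIDAPQFKAMLLAWTQQRGRMFLTTVCGGGYA
>SPS_nem2
MTFSLEVTRQQFQYVRDKLFGFYCIDAEMRIEEVPFECVDMVGGCYKCGLIFATHEPLKCYKMRSFQFCVTVFQSIEEFLVPWSNNKMSIGAPQFKSMLLAWTQQCGRMFSTTVCIGGYR
>SPS_ins1
MYFALEVTRHESQGVRDKEFPFYCIDNLMRIEEVPFECVDTVGGCYDCGLIFATHDPLKCYKMDSFQFCVTVFQIIEEHLVPRLTNKMSIGAPQFSSML---DQIRGRMFSTTVCGGGYR
>SPS_ins2
MTFALEVMRHEFQYVRDKEMPFYCNDALMAPEEVPFECVATVLGCGKCGLIFATHEPLKCYKMCSFQFCVTVFMPIEEHLVPWSTNKMSIGAPQFKSMLLAWTQQRIRMFSTTVCRVGYR
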