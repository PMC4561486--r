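#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n row_number desc across all_of
#' @importFrom purrr map map_chr map_dbl map_int map2 pmap imap
#' @importFrom stats setNames rpois runif
NULL

# Standard genetic code, DNA alphabet. TGA is treated contextually:
# translate_cds() renders in-frame TGA as 'U' (selenocysteine); everywhere a
# true terminator is meant (ORF extension, simulator rejection) all three of
# TAA/TAG/TGA count as stops.
GENETIC_CODE_DNA <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"
  ), "")[[1]]
  codons <- character(64)
  k <- 0L
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1L
    codons[k] <- paste0(b1, b2, b3)
  }
  setNames(aas, codons)
})

STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(names(GENETIC_CODE_DNA), STOP_CODONS)
# 62-state space used for ancestral codon reconstruction: 61 sense + TGA (Sec)
CODON_STATES <- c(SENSE_CODONS, "TGA")

AA_ALPHABET_21 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                    "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "U")

translate_codon <- function(codon, sec_tga = TRUE) {
  aa <- GENETIC_CODE_DNA[codon]
  if (sec_tga) aa[codon == "TGA"] <- "U"
  unname(aa)
}

#' Translate an in-frame coding sequence
#'
#' Translates a CDS under the convention used throughout the package: an
#' in-frame TGA is rendered as `U` (selenocysteine), a terminal stop codon is
#' dropped, `N`-containing codons become `X`, and an internal TAA/TAG is
#' rejected as pseudogene-like.
#'
#' @param cds A DNA string with length a multiple of 3.
#' @return A protein string over the 21-letter alphabet (plus `X` for
#'   ambiguous codons).
#' @examples
#' translate_cds("ATGTGAAAATAA")  # "MUK"
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) {
    abort("CDS length must be a multiple of 3", class = "spsevo_frame_error")
  }
  codons <- codon_split(cds)
  n <- length(codons)
  if (n == 0) return("")
  if (codons[n] %in% STOP_CODONS) codons <- codons[-n]
  if (any(codons %in% c("TAA", "TAG"))) {
    abort("internal TAA/TAG stop: pseudogene-like CDS rejected",
          class = "spsevo_pseudogene_error")
  }
  aa <- ifelse(grepl("N", codons), "X", translate_codon(codons))
  paste(aa, collapse = "")
}

codon_split <- function(seq) {
  n <- nchar(seq)
  if (n == 0) return(character(0))
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", vapply(seq, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}
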