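# Planting SPS genes with controlled signals in synthetic genome context:
# residue at the Sec-homologous site, SECIS annotation, the GGG-TG[C/T]
# hexanucleotide, an SRE-like hairpin around the TGA, and terminal fusion
# domains. Every planted feature is returned as ground truth.

AA_CODONS <- local({
  split(names(GENETIC_CODE_DNA)[GENETIC_CODE_DNA != "*"],
        GENETIC_CODE_DNA[GENETIC_CODE_DNA != "*"])
})

reverse_translate <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  vapply(aa, function(a) {
    if (a == "U") return("TGA")
    cods <- AA_CODONS[[a]]
    if (is.null(cods)) abort(paste("cannot reverse-translate symbol", a))
    sample(cods, 1)
  }, character(1), USE.NAMES = FALSE)
}

random_coding_codons <- function(n) {
  if (n == 0) return(character(0))
  sample(setdiff(SENSE_CODONS, "ATG"), n, replace = TRUE)
}

#' Plant a synthetic SPS gene in genomic context
#'
#' Builds a CDS whose translation aligns to the seed profile with the
#' requested residue at the Sec column, embeds it in random flanking
#' sequence bounded by in-frame stop codons, and optionally plants: the
#' hexanucleotide `GGGTG[C/T]` immediately after the in-frame TGA; an
#' SRE-like hairpin (9-bp GC stem with the TGA in its loop); and a terminal
#' fusion domain of `fusion_len` aa encoded in frame beyond the annotated
#' gene boundary with no intervening stop (so that ORF extension recovers
#' it).
#'
#' @param profile An `sps_profile`; the gene body is the profile consensus.
#' @param site_residue One of `U`, `C`, `T`, `G`, `L`, `R` (or any standard
#'   amino-acid letter); `U` plants an in-frame TGA.
#' @param secis SECIS annotation flag (boolean attribute, not a synthesized
#'   structure).
#' @param hexamer,hairpin Readthrough signals; only valid with
#'   `site_residue = "U"`.
#' @param fusion_side `"none"`, `"N"` or `"C"`.
#' @param fusion_len Fusion domain length in aa.
#' @param fusion_domain Optional protein string to use as the fusion domain
#'   (recurrent planted families); random if NULL.
#' @param strand `"+"` or `"-"`.
#' @param gene_id,contig_id Identifiers.
#' @param flank Length (nt) of random flanking sequence on each side.
#' @param seed Optional integer seed.
#' @return A list of class `sps_gene`: `genome` (named DNA string),
#'   `annotation` (one-row tibble, 0-based half-open), `cds`, `protein`,
#'   `truth` (the planted specification incl. `uga_codon_index`).
#' @export
generate_sps_gene <- function(profile, site_residue = "U", secis = FALSE,
                              hexamer = FALSE, hairpin = FALSE,
                              fusion_side = c("none", "N", "C"),
                              fusion_len = 0, fusion_domain = NULL,
                              strand = "+", gene_id = "gene1",
                              contig_id = "ctg1", flank = 60, seed = NULL) {
  fusion_side <- match.arg(fusion_side)
  if ((hexamer || hairpin) && site_residue != "U") {
    abort("hexamer/hairpin require site_residue = 'U'",
          class = "spsevo_spec_error")
  }
  if (fusion_len < 0) abort("fusion_len must be >= 0")
  run <- function() {
    prot <- profile$consensus
    prot[1] <- "M"
    sec <- profile$sec_column
    prot[sec] <- site_residue
    codons <- reverse_translate(paste(prot, collapse = ""))
    if (hexamer) {
      codons[sec + 1] <- "GGG"
      codons[sec + 2] <- sample(c("TGC", "TGT"), 1)
    }
    if (hairpin) {
      # codon-aligned 9-bp pure-GC stem whose hairpin loop is the TGA
      # itself: glycine codons upstream, proline codons downstream. With no
      # other G/C complementarity planted nearby, the stem is the unique
      # weight-maximal structure and the TGA ends up in its apical loop.
      codons[(sec - 3):(sec - 1)] <- c("GGG", "GGG", "GGG")
      if (hexamer) {
        codons[(sec + 3):(sec + 5)] <- c("CCC", "CCC", "CCC")
      } else {
        codons[(sec + 1):(sec + 3)] <- c("CCC", "CCC", "CCC")
      }
    }
    core <- codons
    dom <- NULL
    if (fusion_side != "none" && fusion_len > 0) {
      if (is.null(fusion_domain)) {
        dom_aa <- sample(setdiff(AA_ALPHABET_21, c("U", "M")), fusion_len,
                         replace = TRUE)
        fusion_domain <- paste(dom_aa, collapse = "")
      }
      dom <- reverse_translate(fusion_domain)
    }
    left_flank <- random_flank(flank)
    right_flank <- random_flank(flank)
    stopc <- function() sample(c("TAA", "TAG", "TGA"), 1)
    if (fusion_side == "N" && !is.null(dom)) {
      upstream <- c(left_flank, stopc(), dom)
      cds <- c(core, stopc())
      downstream <- c(stopc(), right_flank)
    } else if (fusion_side == "C" && !is.null(dom)) {
      upstream <- c(left_flank, stopc())
      cds <- core
      downstream <- c(dom, stopc(), right_flank)
    } else {
      upstream <- c(left_flank, stopc())
      cds <- c(core, stopc())
      downstream <- c(stopc(), right_flank)
    }
    contig <- paste(c(upstream, cds, downstream), collapse = "")
    start0 <- sum(nchar(upstream))
    end0 <- start0 + sum(nchar(cds))
    if (strand == "-") {
      L <- nchar(contig)
      contig <- revcomp(contig)
      tmp <- start0
      start0 <- L - end0
      end0 <- L - tmp
    }
    ann <- tibble(gene_id = gene_id, contig_id = contig_id,
                  start = start0, end = end0, strand = strand, phase = 0L,
                  complete = TRUE)
    structure(list(
      genome = setNames(contig, contig_id),
      annotation = ann,
      cds = paste(cds, collapse = ""),
      protein = paste(prot, collapse = ""),
      truth = list(site_residue = site_residue, secis = secis,
                   hexamer = hexamer, hairpin = hairpin,
                   fusion_side = fusion_side, fusion_len = fusion_len,
                   fusion_domain = fusion_domain,
                   uga_codon_index = sec,
                   uga_nt_pos = 3 * (sec - 1) + 1)
    ), class = "sps_gene")
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

# random codon-aligned flank without in-frame stops or ATG (inert for ORF
# extension walks)
random_flank <- function(n_nt) {
  n_cod <- ceiling(n_nt / 3)
  random_coding_codons(n_cod)
}

#' @export
print.sps_gene <- function(x, ...) {
  cat("Planted SPS gene", x$annotation$gene_id, "on", x$annotation$strand,
      "strand: site residue", x$truth$site_residue,
      if (x$truth$secis) "(SECIS)" else "", "\n")
  invisible(x)
}

#' Generate a recoding-element window with planted structure
#'
#' Builds a DNA window with an in-frame TGA at its center and a planted
#' secondary-structure context: `"SRE"` (a single 9-bp stem whose loop holds
#' the TGA), `"HRE"` (a three-stem clover with the TGA in the apex of the
#' middle stem), or `"none"` (structure-free). Unpaired regions are drawn
#' from {A, C} only, so they cannot base-pair; planting is therefore exact
#' and the fold is fully determined.
#'
#' @param kind `"SRE"`, `"HRE"` or `"none"`.
#' @param width Total window width in nt (default 123 = TGA +/- 60).
#' @param seed Optional seed (randomizes arm lengths within their class).
#' @return List: `window` (DNA string), `uga_pos` (position of the T of the
#'   TGA), `kind`.
#' @export
generate_recoding_window <- function(kind = c("SRE", "HRE", "none"),
                                     width = 123, seed = NULL) {
  kind <- match.arg(kind)
  run <- function() {
    sp <- function(n) strrep("A", max(0, n))
    half <- (width - 3) %/% 2
    uga_pos <- half + 1
    if (kind == "none") {
      mix <- paste(sample(c("A", "C"), width, replace = TRUE), collapse = "")
      window <- paste0(substr(mix, 1, half), "TGA",
                       substr(mix, half + 4, width))
      return(list(window = window, uga_pos = uga_pos, kind = kind))
    }
    if (kind == "SRE") {
      # single hairpin whose loop is exactly the TGA
      L <- sample(8:11, 1)
      window <- paste0(sp(half - L), strrep("G", L), "TGA", strrep("C", L))
      window <- paste0(window, sp(width - nchar(window)))
      return(list(window = window, uga_pos = uga_pos, kind = kind))
    }
    # HRE: three-stem clover, TGA in the apex of the middle stem
    L1 <- sample(4:6, 1)
    Lm <- sample(8:10, 1)
    L3 <- sample(4:6, 1)
    g1 <- sample(3:5, 1)
    g2 <- sample(3:5, 1)
    stem1 <- paste0(strrep("G", L1), "AAA", strrep("C", L1))
    stem3 <- paste0(strrep("G", L3), "AAA", strrep("C", L3))
    lead <- half - Lm - g1 - nchar(stem1)
    window <- paste0(sp(lead), stem1, sp(g1), strrep("G", Lm), "TGA",
                     strrep("C", Lm), sp(g2), stem3)
    window <- paste0(window, sp(width - nchar(window)))
    list(window = window, uga_pos = uga_pos, kind = kind)
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}
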