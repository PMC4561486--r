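# Reading the residue at the UGA-homologous profile column and classifying
# genes/genomes from it. This is the analytical core: in SPS proteins the
# residue at this single site (Sec/Cys vs Thr/Gly/Leu/Arg or UGA-without-
# SECIS) is a precise marker of function.

#' Call the residue at the Sec-homologous column
#'
#' Reads the protein symbol mapped to the profile's Sec column (`x` if the
#' alignment places a gap there), and measures flank identity: the fraction
#' of the 10 profile columns on either side of the site at which the aligned
#' protein residue equals the profile consensus (gap-mapped columns count as
#' mismatches). The call is confident iff flank identity is at least
#' `confidence`.
#'
#' @param alignment An `sps_alignment` from [align_to_profile()].
#' @param profile The `sps_profile` used for the alignment.
#' @param gene_id Optional identifier carried into the output.
#' @param flank Number of columns on each side of the Sec column (default 10).
#' @param confidence Flank-identity threshold for a confident call
#'   (default 0.4).
#' @return One-row tibble: `gene_id`, `residue`, `flank_identity`,
#'   `confident`.
#' @export
call_site_residue <- function(alignment, profile, gene_id = NA_character_,
                              flank = 10, confidence = 0.4) {
  stopifnot(inherits(alignment, "sps_alignment"),
            inherits(profile, "sps_profile"))
  sec <- profile$sec_column
  p <- strsplit(alignment$protein, "")[[1]]
  pos <- alignment$mapping[sec]
  residue <- if (is.na(pos)) "x" else p[pos]
  cols <- setdiff(max(1, sec - flank):min(profile$n_columns, sec + flank), sec)
  matches <- vapply(cols, function(cl) {
    j <- alignment$mapping[cl]
    !is.na(j) && p[j] == profile$consensus[cl]
  }, logical(1))
  fid <- mean(matches)
  tibble(gene_id = gene_id, residue = residue, flank_identity = fid,
         confident = fid >= confidence & residue != "x")
}

#' Classify SPS genes from site calls
#'
#' Applies the functional nomenclature: `SPS2-Sec` (U at the site with a
#' SECIS), `SPS1-UGA` (U without SECIS), `SPS2-Cys` (C), `SPS1-<res>` for any
#' other residue, `unclassified` for unconfident calls or a gap at the site.
#'
#' @param site_calls Tibble with columns `residue` and `confident` (as from
#'   [call_site_residue()]) plus `secis_flag` (logical), or pass `secis_flag`
#'   separately.
#' @param secis_flag Optional logical vector recycled against the rows of
#'   `site_calls`; ignored if the tibble already has a `secis_flag` column.
#' @return `site_calls` with a `class` column added.
#' @export
classify_sps <- function(site_calls, secis_flag = NULL) {
  if (!"secis_flag" %in% names(site_calls)) {
    if (is.null(secis_flag)) abort("secis_flag required")
    site_calls$secis_flag <- secis_flag
  }
  mutate(site_calls, class = dplyr::case_when(
    !confident | residue == "x" ~ "unclassified",
    residue == "U" & secis_flag ~ "SPS2-Sec",
    residue == "U" & !secis_flag ~ "SPS1-UGA",
    residue == "C" ~ "SPS2-Cys",
    TRUE ~ paste0("SPS1-", residue)
  ))
}

#' Call genome-level Sec capability from gene classes
#'
#' A genome is Sec-capable iff it carries at least one `SPS2-Sec` or
#' `SPS2-Cys` gene. When a selenoproteome size is supplied, a consistency
#' flag marks genomes whose capability call disagrees with
#' `selenoproteome_size > 0`.
#'
#' @param gene_classes Tibble with `genome_id` and `class` (one row per
#'   gene; a genome with no genes is simply absent — pass it with class
#'   `"none"` to include it).
#' @param selenoproteome Optional tibble `genome_id`, `selenoproteome_size`.
#' @return Tibble with `genome_id`, `sec_capable`, and (when sizes are
#'   given) `consistent`.
#' @export
classify_genome <- function(gene_classes, selenoproteome = NULL) {
  out <- gene_classes |>
    group_by(genome_id) |>
    summarise(sec_capable = any(class %in% c("SPS2-Sec", "SPS2-Cys")),
              .groups = "drop")
  if (!is.null(selenoproteome)) {
    out <- out |>
      left_join(selenoproteome, by = "genome_id") |>
      mutate(consistent = sec_capable == (selenoproteome_size > 0))
  }
  out
}

#' End-to-end site classification of protein sequences
#'
#' Convenience wrapper: aligns each protein to the profile, calls the site
#' residue and classifies. Proteins come as a named character vector;
#' `secis` is a named logical vector over the same ids.
#'
#' @param proteins Named character vector of protein sequences.
#' @param profile An `sps_profile`.
#' @param secis Named logical vector (SECIS annotation per gene id).
#' @param ... Passed to [call_site_residue()].
#' @return Tibble: one row per protein with residue, flank identity,
#'   confidence and class.
#' @export
classify_proteins <- function(proteins, profile, secis, ...) {
  rows <- imap(proteins, function(seq, id) {
    aln <- align_to_profile(seq, profile)
    call_site_residue(aln, profile, gene_id = id, ...)
  })
  calls <- bind_rows(rows)
  classify_sps(calls, secis_flag = unname(secis[calls$gene_id]))
}
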