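# Genome x marker matrices and selenium-utilization trait calls. The Sec
# trait requires SelD plus at least one of SelA, tRNAsec, or a nonempty
# selenoproteome; the SeU (2-selenouridine) trait requires SelD plus ybbB;
# SelD with neither is an orphan (the Enterococcus-like configuration).

#' Call selenium-utilization traits from a marker matrix
#'
#' @param markers Tibble with logical columns `SelD`, `SelA`, `ybbB`,
#'   `tRNAsec` and integer `selenoproteome_size`, plus `genome_id`.
#' @return Tibble: `genome_id`, `sec`, `seu`, `orphan_selD`.
#' @export
call_traits <- function(markers) {
  required <- c("genome_id", "SelD", "SelA", "ybbB", "tRNAsec",
                "selenoproteome_size")
  miss <- setdiff(required, names(markers))
  if (length(miss)) abort(paste("missing marker columns:",
                                paste(miss, collapse = ", ")))
  markers |>
    mutate(
      sec = SelD & (SelA | tRNAsec | selenoproteome_size > 0),
      seu = SelD & ybbB,
      orphan_selD = SelD & !sec & !seu
    ) |>
    select(genome_id, sec, seu, orphan_selD)
}

#' One-tailed exact test for Sec/SeU trait co-occurrence
#'
#' Hypergeometric upper tail `P(X >= observed both-count)` with margins fixed
#' to the two trait counts, computed via log-gamma (`lchoose`) with
#' log-sum-exp accumulation — exact enrichment direction, as for a one-tailed
#' Fisher test on the 2x2 trait table.
#'
#' @param calls Tibble from [call_traits()] (columns `sec`, `seu`).
#' @return Object of class `sps_overlap`: list with `p.value`, `table`
#'   (2x2), `n`, and the margin counts.
#' @export
fisher_overlap_test <- function(calls) {
  if (nrow(calls) == 0) abort("empty input", class = "spsevo_input_error")
  n <- nrow(calls)
  k_sec <- sum(calls$sec)
  k_seu <- sum(calls$seu)
  both <- sum(calls$sec & calls$seu)
  p <- hyper_upper_tail(both, k_sec, k_seu, n)
  tab <- matrix(c(both, k_sec - both, k_seu - both, n - k_sec - k_seu + both),
                2, 2, dimnames = list(sec = c("yes", "no"),
                                      seu = c("yes", "no")))
  structure(list(p.value = p, table = tab, n = n, n_sec = k_sec,
                 n_seu = k_seu, n_both = both),
            class = "sps_overlap")
}

# P(X >= x) for X ~ Hypergeometric(margins k1, k2 out of n), via lchoose.
hyper_upper_tail <- function(x, k1, k2, n) {
  hi <- min(k1, k2)
  if (x <= max(0, k1 + k2 - n)) return(1)
  ks <- x:hi
  if (length(ks) == 0) return(0)
  lp <- lchoose(k1, ks) + lchoose(n - k1, k2 - ks) - lchoose(n, k2)
  m <- max(lp)
  exp(m + log(sum(exp(lp - m))))
}

#' @export
print.sps_overlap <- function(x, ...) {
  cat("Sec/SeU co-occurrence:", x$n_both, "of", x$n, "genomes carry both",
      sprintf("(Sec %d, SeU %d)\n", x$n_sec, x$n_seu))
  cat("one-tailed exact P =", format(x$p.value, digits = 4), "\n")
  invisible(x)
}

#' Summarize a marker panel
#'
#' Fractions of genomes with SelD, with the Sec trait, with the SeU trait,
#' with both, and — over SelD-bearing genomes — the fraction whose SelD
#' carries a Sec (U) residue.
#'
#' @param markers Marker tibble (with optional `SelD_residue` column over
#'   `{"U","C","none"}`).
#' @return One-row tibble of fractions plus `n_genomes`.
#' @export
summarize_panel <- function(markers) {
  calls <- call_traits(markers)
  n <- nrow(markers)
  res <- tibble(
    n_genomes = n,
    frac_selD = mean(markers$SelD),
    frac_sec = mean(calls$sec),
    frac_seu = mean(calls$seu),
    frac_both = mean(calls$sec & calls$seu),
    frac_orphan = mean(calls$orphan_selD)
  )
  if ("SelD_residue" %in% names(markers) && any(markers$SelD)) {
    res$frac_selD_sec_residue <-
      mean(markers$SelD_residue[markers$SelD] == "U")
  }
  res
}

#' Plot a marker panel as a presence/absence tile map
#'
#' @param markers Marker tibble.
#' @return A ggplot object.
#' @export
plot_marker_panel <- function(markers) {
  long <- markers |>
    mutate(selenoproteins = selenoproteome_size > 0) |>
    select(genome_id, SelD, SelA, ybbB, tRNAsec, selenoproteins) |>
    tidyr::pivot_longer(-genome_id, names_to = "marker",
                        values_to = "present")
  ggplot2::ggplot(long, ggplot2::aes(x = marker, y = genome_id,
                                     fill = present)) +
    ggplot2::geom_tile(color = "grey90") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2b8cbe",
                                          `FALSE` = "grey95")) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
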