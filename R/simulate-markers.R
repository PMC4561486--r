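# Synthetic genome x marker panels with controlled trait overlap. Category
# counts are fixed (nearest-integer of the requested frequencies, residual
# to "none"), so planted frequencies are recovered exactly; only the
# assignment of genomes to categories and the optional-marker fill-in are
# random.

#' Generate a marker panel with planted trait labels
#'
#' @param n_genomes Panel size.
#' @param p_sec,p_seu,p_both Target frequencies of the Sec trait, the SeU
#'   trait, and their overlap (`p_both <= min(p_sec, p_seu)`).
#' @param p_orphan Frequency of orphan-SelD genomes (SelD with no other
#'   marker).
#' @param p_sec_residue_u Fraction of SelD-bearing genomes whose SelD
#'   carries Sec (U) rather than Cys.
#' @param seed Optional seed.
#' @return List of class `sps_panel`: `markers` (tibble, one row per
#'   genome) and `truth` (tibble `genome_id`, `label` over
#'   `{both, sec, seu, orphan, none}`).
#' @export
generate_marker_panel <- function(n_genomes, p_sec, p_seu, p_both,
                                  p_orphan = 0, p_sec_residue_u = 0.19,
                                  seed = NULL) {
  probs <- c(p_sec, p_seu, p_both, p_orphan)
  if (any(probs < 0 | probs > 1)) abort("probabilities must be in [0, 1]",
                                        class = "spsevo_param_error")
  if (p_both > min(p_sec, p_seu)) {
    abort("p_both must not exceed min(p_sec, p_seu)",
          class = "spsevo_param_error")
  }
  n_both <- round(n_genomes * p_both)
  n_sec_only <- round(n_genomes * p_sec) - n_both
  n_seu_only <- round(n_genomes * p_seu) - n_both
  n_orphan <- round(n_genomes * p_orphan)
  n_none <- n_genomes - n_both - n_sec_only - n_seu_only - n_orphan
  if (n_none < 0) abort("inconsistent probabilities",
                        class = "spsevo_param_error")
  run <- function() {
    labels <- sample(rep(c("both", "sec", "seu", "orphan", "none"),
                         c(n_both, n_sec_only, n_seu_only, n_orphan, n_none)))
    ids <- sprintf("g%03d", seq_len(n_genomes))
    sec_like <- labels %in% c("both", "sec")
    # Sec-trait genomes need SelD plus >= 1 of {SelA, tRNAsec,
    # selenoproteins}; draw each and force SelA when all three miss
    selA <- sec_like & runif(n_genomes) < 0.7
    trna <- sec_like & runif(n_genomes) < 0.8
    sp_pos <- sec_like & runif(n_genomes) < 0.9
    none_of3 <- sec_like & !selA & !trna & !sp_pos
    selA[none_of3] <- TRUE
    selD <- labels != "none"
    markers <- tibble(
      genome_id = ids,
      SelD = selD,
      SelA = selA,
      ybbB = labels %in% c("both", "seu"),
      tRNAsec = trna,
      selenoproteome_size = ifelse(sp_pos, 1L + rpois(n_genomes, 3), 0L)
    )
    n_selD <- sum(selD)
    n_u <- round(n_selD * p_sec_residue_u)
    residue <- rep("none", n_genomes)
    selD_idx <- which(selD)
    u_idx <- sample(selD_idx, n_u)
    residue[selD_idx] <- "C"
    residue[u_idx] <- "U"
    markers$SelD_residue <- residue
    structure(list(markers = markers,
                   truth = tibble(genome_id = ids, label = labels)),
              class = "sps_panel")
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' Compare recovered trait calls with planted labels
#'
#' @param panel An `sps_panel`.
#' @return Tibble joining truth labels with [call_traits()] output plus a
#'   `recovered` logical (the call matches the planted label).
#' @export
check_panel_recovery <- function(panel) {
  calls <- call_traits(panel$markers)
  out <- left_join(panel$truth, calls, by = "genome_id") |>
    mutate(called = dplyr::case_when(
      sec & seu ~ "both",
      sec ~ "sec",
      seu ~ "seu",
      orphan_selD ~ "orphan",
      TRUE ~ "none"
    ),
    recovered = called == label)
  out
}

#' @export
print.sps_panel <- function(x, ...) {
  cat("Synthetic marker panel:", nrow(x$markers), "genomes;",
      paste(names(table(x$truth$label)), table(x$truth$label),
            sep = "=", collapse = " "), "\n")
  invisible(x)
}
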