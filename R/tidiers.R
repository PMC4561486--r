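#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the Sec/SeU overlap test into a one-row tibble
#'
#' @param x An `sps_overlap` object.
#' @param ... Unused.
#' @return A tibble with the margin counts and p-value.
#' @export
tidy.sps_overlap <- function(x, ...) {
  tibble(n = x$n, n_sec = x$n_sec, n_seu = x$n_seu, n_both = x$n_both,
         p.value = x$p.value,
         method = "one-tailed exact hypergeometric (enrichment)")
}

#' @rdname tidy.sps_overlap
#' @export
glance.sps_overlap <- function(x, ...) tidy(x)

#' Tidy a fold into its pair list
#'
#' @param x An `sps_fold` object.
#' @param ... Unused.
#' @return The pair tibble (`i`, `j`, `weight`).
#' @export
tidy.sps_fold <- function(x, ...) x$pairs

#' @export
glance.sps_fold <- function(x, ...) {
  tibble(score = x$score, n_pairs = nrow(x$pairs), n_stems = x$n_stems,
         uga_context = x$uga_context)
}

#' Tidy an ancestral reconstruction into a long node/column table
#'
#' @param x An `sps_ancestral` object.
#' @param ... Unused.
#' @return Tibble: `node`, `branch`, `column`, `codon`.
#' @export
tidy.sps_ancestral <- function(x, ...) {
  nnode <- nrow(x$states)
  labels <- vapply(seq_len(nnode), function(n) node_label(x$tree, n),
                   character(1))
  tidyr::expand_grid(node = seq_len(nnode), column = seq_len(ncol(x$states))) |>
    mutate(branch = labels[node], codon = x$states[cbind(node, column)]) |>
    select(node, branch, column, codon)
}

#' @export
glance.sps_ancestral <- function(x, ...) {
  tibble(n_tips = length(x$tree$tip.label), n_codons = ncol(x$states),
         parsimony_score = x$score)
}

#' Arc diagram of a folded window
#'
#' @param object An `sps_fold` object.
#' @param ... Unused.
#' @return A ggplot object: base positions on the x axis, pairing arcs
#'   above, the UGA highlighted when known.
#' @export
autoplot.sps_fold <- function(object, ...) {
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(ggplot2::aes(x = 1, xend = object$n, y = 0,
                                       yend = 0), color = "grey60")
  if (nrow(object$pairs)) {
    arcs <- object$pairs |>
      mutate(xm = (i + j) / 2, h = (j - i) / 2)
    p <- p + ggplot2::geom_curve(
      data = arcs,
      ggplot2::aes(x = i, xend = j, y = 0, yend = 0),
      curvature = -0.5, color = "#2b8cbe"
    )
  }
  if (!is.null(object$uga_pos)) {
    p <- p + ggplot2::annotate("rect", xmin = object$uga_pos - 0.5,
                               xmax = object$uga_pos + 2.5, ymin = -0.4,
                               ymax = 0.4, fill = "red", alpha = 0.3)
  }
  p + ggplot2::labs(x = "window position (nt)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
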