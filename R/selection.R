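#' Per-branch Ka/Ks from reconstructed ancestral codons
#'
#' Applies [ng86_pairwise()] to the (parent state, child state) codon pair of
#' every branch of a rooted tree, using ancestral sequences from
#' [fitch_ancestral_codons()]. The selenocysteine site column, when given, is
#' masked: the U/C/other change at that site is the object of study, not
#' background selection.
#'
#' @param ancestors An `sps_ancestral` object.
#' @param mask Integer vector of codon columns to exclude (e.g. the Sec
#'   site).
#' @return A tibble, one row per branch (identified by the child node:
#'   `branch` is the tip label for terminal branches, `node<k>` otherwise),
#'   with the [ng86_pairwise()] columns plus `parent`, `node`, and
#'   `saturated` (TRUE for branches beyond Jukes-Cantor saturation, whose
#'   rate columns are NA rather than an error).
#' @export
branch_ka_ks <- function(ancestors, mask = integer(0)) {
  stopifnot(inherits(ancestors, "sps_ancestral"))
  tree <- ancestors$tree
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  rows <- lapply(seq_len(nrow(edge)), function(e) {
    par <- edge[e, 1]; chd <- edge[e, 2]
    pa <- ancestors$states[par, ]
    ch <- ancestors$states[chd, ]
    res <- tryCatch(ng86_pairwise(pa, ch, mask = mask),
                    spsevo_saturation_error = function(cnd) NULL)
    sat <- is.null(res)
    if (sat) {
      res <- tibble(codons = length(pa) - length(mask), N = NA_real_,
                    S = NA_real_, Nd = NA_real_, Sd = NA_real_, pN = NA_real_,
                    pS = NA_real_, Ka = NA_real_, Ks = NA_real_,
                    omega = NA_real_)
    }
    mutate(res,
           node = chd,
           parent = par,
           branch = node_label(tree, chd),
           saturated = sat)
  })
  dplyr::relocate(bind_rows(rows), branch, node, parent)
}

node_label <- function(tree, node) {
  ntip <- length(tree$tip.label)
  ifelse(node <= ntip, tree$tip.label[node], paste0("node", node))
}

#' Aggregate branch-wise Ka/Ks by clade
#'
#' Summarizes [branch_ka_ks()] results over branch groups (e.g. the SPS1 and
#' SPS2 clades after a duplication and the pre-duplication backbone). The
#' pooled estimator sums the site and difference counts over the group's
#' branches before taking the ratio `(Nd/N) / (Sd/S)`, which is the stable
#' choice when individual branches are short.
#'
#' @param branches Tibble from [branch_ka_ks()].
#' @param groups Named character vector or tibble (`branch`, `group`)
#'   assigning every branch to a group.
#' @return A tibble with one row per group: `n_branches`, `mean_omega`,
#'   `median_omega` (over branches with defined omega), `pooled_omega`,
#'   and the pooled count columns.
#' @export
aggregate_omega <- function(branches, groups) {
  if (is.data.frame(groups)) {
    grp <- setNames(groups$group, groups$branch)
  } else {
    grp <- groups
  }
  missing <- setdiff(branches$branch, names(grp))
  if (length(missing)) {
    abort(paste("branches without a group:", paste(missing, collapse = ", ")),
          class = "spsevo_group_error")
  }
  branches |>
    mutate(group = unname(grp[branch])) |>
    group_by(group) |>
    summarise(
      n_branches = n(),
      mean_omega = mean(omega[is.finite(omega)], na.rm = TRUE),
      median_omega = stats::median(omega[is.finite(omega)], na.rm = TRUE),
      N = sum(N), S = sum(S), Nd = sum(Nd), Sd = sum(Sd),
      pooled_omega = ifelse(Sd > 0 & N > 0, (Nd / N) / (Sd / S), NA_real_),
      .groups = "drop"
    )
}

#' Plot branch-wise omega by clade
#'
#' @param branches Tibble from [branch_ka_ks()].
#' @param groups As in [aggregate_omega()].
#' @return A ggplot object (boxplot of branch omega per group).
#' @export
plot_branch_omega <- function(branches, groups) {
  if (is.data.frame(groups)) groups <- setNames(groups$group, groups$branch)
  df <- branches |>
    mutate(group = unname(groups[branch])) |>
    filter(is.finite(omega))
  ggplot2::ggplot(df, ggplot2::aes(x = group, y = omega)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Ka/Ks per branch") +
    ggplot2::theme_minimal()
}
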