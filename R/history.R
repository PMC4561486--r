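# Duplication labeling on gene trees (species-overlap rule) and parsimony
# reconstruction of the Sec-site residue history, emitting the event
# vocabulary: GD (gene duplication), SC (Sec-to-Cys conversion), SO
# (Sec-to-other conversion).

#' Label gene-tree nodes as duplication or speciation (species overlap)
#'
#' An internal node is a duplication iff the species sets of its child
#' subtrees intersect.
#'
#' @param gene_tree A rooted `ape::phylo` tree.
#' @param species_of Named character vector mapping every leaf label to a
#'   species.
#' @return Tibble: `node` (ape numbering), `label`
#'   (`duplication`/`speciation`).
#' @export
label_duplications <- function(gene_tree, species_of) {
  tips <- gene_tree$tip.label
  unmapped <- setdiff(tips, names(species_of))
  if (length(unmapped)) {
    abort(paste("unmapped leaves:", paste(unmapped, collapse = ", ")),
          class = "spsevo_leaf_error")
  }
  ntip <- length(tips)
  edge <- gene_tree$edge
  po <- order_edges_preorder(gene_tree)
  children_of <- split(edge[, 2], edge[, 1])
  internal_post <- rev(unique(edge[po, 1]))
  spsets <- vector("list", ntip + gene_tree$Nnode)
  for (i in seq_len(ntip)) spsets[[i]] <- species_of[[tips[i]]]
  labels <- character(0)
  nodes <- integer(0)
  for (nd in internal_post) {
    kids <- children_of[[as.character(nd)]]
    kid_sets <- lapply(kids, function(k) spsets[[k]])
    overlap <- FALSE
    if (length(kid_sets) > 1) {
      for (i in seq_len(length(kid_sets) - 1)) {
        for (j in (i + 1):length(kid_sets)) {
          if (length(intersect(kid_sets[[i]], kid_sets[[j]]))) overlap <- TRUE
        }
      }
    }
    spsets[[nd]] <- unique(unlist(kid_sets))
    nodes <- c(nodes, nd)
    labels <- c(labels, if (overlap) "duplication" else "speciation")
  }
  tibble(node = nodes, label = labels) |> arrange(node)
}

#' Reconstruct the Sec-site residue history on a gene tree
#'
#' Parsimony (minimum change) over the residue alphabet with deterministic
#' tie resolution encoding a Sec-bearing ancestor: the root prefers `U`,
#' then `C`, then the alphabetically smallest residue (configurable via
#' `root_preference`). Each branch on which the state changes emits an
#' event: `SC` for U to C, `SO` for U to any residue other than C, `other`
#' for changes not starting from U. `GD` events are copied from the
#' duplication labels. Leaves with unknown residue (`x`) are excluded from
#' state inference.
#'
#' @param gene_tree A rooted `ape::phylo` tree.
#' @param leaf_states Named character vector mapping leaf labels to
#'   residues (one-letter; `x` = unknown).
#' @param duplication_labels Optional tibble from [label_duplications()].
#' @param root_preference Character vector of states tried first at
#'   ties (default `c("U", "C")`, then alphabetical).
#' @return List of class `sps_history`: `events` tibble (`node`, `branch`,
#'   `event`, `from_state`, `to_state`), `ancestral_states` (named by node),
#'   `score` (parsimony changes), `tree` (possibly pruned of `x` leaves).
#' @export
reconstruct_site_history <- function(gene_tree, leaf_states,
                                     duplication_labels = NULL,
                                     root_preference = c("U", "C")) {
  known <- names(leaf_states)[leaf_states != "x"]
  if (length(known) == 0) abort("all leaves have unknown residue",
                                class = "spsevo_input_error")
  drop <- setdiff(gene_tree$tip.label, known)
  tree <- gene_tree
  if (length(drop)) {
    tree <- ape::drop.tip(gene_tree, drop)
    if (is.null(tree)) abort("tree empty after dropping unknown leaves")
  }
  m <- matrix(leaf_states[tree$tip.label], ncol = 1,
              dimnames = list(tree$tip.label, NULL))
  res <- parsimony_reconstruct(tree, m,
                               residue_preference_factory(root_preference))
  states <- res$states[, 1]
  ntip <- length(tree$tip.label)
  node_names <- vapply(seq_along(states), function(n) node_label(tree, n),
                       character(1))
  edge <- tree$edge
  ev <- list()
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1]; chd <- edge[e, 2]
    if (states[par] != states[chd]) {
      from <- states[par]; to <- states[chd]
      event <- if (from == "U" && to == "C") "SC"
      else if (from == "U") "SO"
      else "other"
      ev[[length(ev) + 1L]] <- tibble(node = chd,
                                      branch = node_names[chd],
                                      event = event, from_state = from,
                                      to_state = to)
    }
  }
  events <- if (length(ev)) bind_rows(ev) else
    tibble(node = integer(), branch = character(), event = character(),
           from_state = character(), to_state = character())
  if (!is.null(duplication_labels)) {
    if (length(drop)) {
      warn(paste("leaves with unknown residue were pruned; supply",
                 "duplication labels computed on the pruned tree"))
    }
    gd <- duplication_labels |>
      filter(label == "duplication") |>
      mutate(branch = vapply(node, function(n) node_label(tree, n),
                             character(1)),
             event = "GD", from_state = NA_character_,
             to_state = NA_character_) |>
      select(node, branch, event, from_state, to_state)
    events <- bind_rows(events, gd) |> arrange(node)
  }
  structure(list(events = events,
                 ancestral_states = setNames(states, node_names),
                 score = sum(res$score), tree = tree),
            class = "sps_history")
}

#' @export
print.sps_history <- function(x, ...) {
  cat("Site-residue history:", x$score, "change(s);",
      sum(x$events$event == "SC"), "SC,",
      sum(x$events$event == "SO"), "SO,",
      sum(x$events$event == "GD"), "GD\n")
  invisible(x)
}
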