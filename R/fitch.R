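# Small-parsimony ancestral reconstruction with unit costs (Fitch counting,
# realized as a Sankoff dynamic program so that multifurcations are exact).
# The candidate state space per column is the set of states observed at the
# leaves, which always contains a minimum-change labeling under unit costs.

# Generic engine: leaf_states is a character matrix (rows = tip labels,
# columns = characters). preference orders states for root/tie resolution.
# Returns states for every node (tips then internals, ape numbering) and the
# per-column parsimony score.
parsimony_reconstruct <- function(tree, leaf_states, preference) {
  if (is.null(tree$edge)) abort("not a phylo tree")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  if (!all(rownames(leaf_states) %in% tree$tip.label) ||
      !all(tree$tip.label %in% rownames(leaf_states))) {
    abort("leaf states do not match tip labels", class = "spsevo_leaf_error")
  }
  leaf_states <- leaf_states[tree$tip.label, , drop = FALSE]
  edge <- tree$edge
  po <- order_edges_preorder(tree)
  internal_post <- rev(unique(edge[po, 1]))
  children_of <- split(edge[, 2], edge[, 1])
  ncol_ <- ncol(leaf_states)
  all_states <- matrix(NA_character_, ntip + nnode, ncol_)
  all_states[seq_len(ntip), ] <- leaf_states
  score <- integer(ncol_)
  root <- setdiff(edge[, 1], edge[, 2])[1]
  for (col in seq_len(ncol_)) {
    obs <- leaf_states[, col]
    space <- unique(obs)
    ord <- preference(space)
    space <- space[order(ord)]
    ns <- length(space)
    if (ns == 1) {
      all_states[, col] <- space
      next
    }
    cost <- matrix(Inf, ntip + nnode, ns)
    cost[cbind(seq_len(ntip), match(obs, space))] <- 0
    # bottom-up over internal nodes in postorder
    for (nd in internal_post) {
      kids <- children_of[[as.character(nd)]]
      cv <- numeric(ns)
      for (k in kids) {
        kc <- cost[k, ]
        # min over child state s: kc[s] + (s != parent_state)
        best <- min(kc)
        cv <- cv + pmin(kc, best + 1)
      }
      cost[nd, ] <- cv
    }
    score[col] <- as.integer(min(cost[root, ]))
    # top-down assignment
    pick <- function(cvec, parent_state) {
      if (!is.null(parent_state)) {
        # candidate set given parent: argmin of cvec[s] + (s != parent)
        tot <- cvec + (space != parent_state)
        cand <- which(tot == min(tot))
        if (match(parent_state, space) %in% cand) return(parent_state)
        return(space[cand[1]])
      }
      space[which.min(cvec)]
    }
    assign_state <- character(ntip + nnode)
    assign_state[root] <- pick(cost[root, ], NULL)
    for (e in po) {
      par <- edge[e, 1]; chd <- edge[e, 2]
      if (chd <= ntip) next
      assign_state[chd] <- pick(cost[chd, ], assign_state[par])
    }
    all_states[(ntip + 1):(ntip + nnode), col] <-
      assign_state[(ntip + 1):(ntip + nnode)]
  }
  list(states = all_states, score = score, root = root)
}

# Edge indices ordered so parents precede children (preorder).
order_edges_preorder <- function(tree) {
  edge <- tree$edge
  root <- setdiff(edge[, 1], edge[, 2])[1]
  out <- integer(0)
  stack <- which(edge[, 1] == root)
  while (length(stack)) {
    e <- stack[1]
    stack <- stack[-1]
    out <- c(out, e)
    stack <- c(which(edge[, 1] == edge[e, 2]), stack)
  }
  out
}

codon_preference <- function(space) {
  rank <- match(space, c("TGA", "TGC", "TGT"))
  rank[is.na(rank)] <- 3 + rank(space[is.na(match(space, c("TGA", "TGC", "TGT")))])
  rank
}

residue_preference_factory <- function(order_head = c("U", "C")) {
  function(space) {
    rank <- match(space, order_head)
    miss <- is.na(rank)
    rank[miss] <- length(order_head) + rank(space[miss])
    rank
  }
}

#' Ancestral codon reconstruction by parsimony
#'
#' Reconstructs codon states at every internal node of a rooted tree by
#' minimum-change parsimony over the 62-state codon space (61 sense codons
#' plus TGA, the selenocysteine state). Ties are resolved deterministically:
#' at the root TGA is preferred, then the cysteine codons TGC/TGT, then the
#' lexicographically smallest codon; below the root a child keeps its
#' parent's state whenever that is change-minimal.
#'
#' @param aln Named character vector of in-frame codon sequences (names must
#'   match the tree's tip labels), or a list of codon vectors.
#' @param tree A rooted `ape::phylo` tree.
#' @return An object of class `sps_ancestral`: list with `states` (character
#'   matrix, rows = nodes in ape numbering, columns = codon positions),
#'   `score` (total parsimony score), `per_column_score`, `tree`.
#' @export
fitch_ancestral_codons <- function(aln, tree) {
  m <- codon_matrix(aln)
  if (any(m %in% c("TAA", "TAG"))) {
    abort("alignment contains internal stop codons TAA/TAG",
          class = "spsevo_pseudogene_error")
  }
  bad <- setdiff(rownames(m), tree$tip.label)
  if (length(bad)) {
    abort(paste("unknown leaves:", paste(bad, collapse = ", ")),
          class = "spsevo_leaf_error")
  }
  res <- parsimony_reconstruct(tree, m, codon_preference)
  structure(list(states = res$states, score = sum(res$score),
                 per_column_score = res$score, tree = tree, root = res$root),
            class = "sps_ancestral")
}

codon_matrix <- function(aln) {
  if (is.list(aln)) {
    lens <- lengths(aln)
    if (length(unique(lens)) != 1) abort("ragged alignment")
    return(do.call(rbind, aln) |> `rownames<-`(names(aln)))
  }
  lens <- nchar(aln)
  if (length(unique(lens)) != 1) abort("ragged alignment")
  if (unique(lens) %% 3 != 0) abort("alignment length not a multiple of 3",
                                    class = "spsevo_frame_error")
  m <- do.call(rbind, lapply(aln, codon_split))
  rownames(m) <- names(aln)
  toupper(m)
}

#' @export
print.sps_ancestral <- function(x, ...) {
  cat("Ancestral codon reconstruction:", ncol(x$states), "codons,",
      length(x$tree$tip.label), "tips, parsimony score", x$score, "\n")
  invisible(x)
}
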