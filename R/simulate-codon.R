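# Codon substitution simulator with per-branch omega. Branch lengths are
# expected *candidate* point mutations per codon (pre-acceptance): per branch,
# candidates arise Poisson(length * n_codons); each proposes a single-
# nucleotide change with transition:transversion weight kappa:1, and is
# accepted with probability 1 if synonymous, omega if nonsynonymous, 0 if it
# would create a stop codon. So omega, not branch length, is the recoverable
# quantity.

#' Simulate codon evolution on a tree with known per-branch omega
#'
#' @param tree A rooted `ape::phylo` tree with branch lengths (expected
#'   candidate mutation events per codon).
#' @param omega A single nonnegative value, or a named numeric vector with an
#'   entry for every branch (named by child node as in [branch_ka_ks()]:
#'   tip label or `node<k>`).
#' @param kappa Transition:transversion rate ratio of candidate mutations
#'   (> 0).
#' @param n_codons Number of codons in the root sequence (sampled uniformly
#'   from the 61 sense codons).
#' @param seed Optional integer seed; the run is reproducible given it.
#' @return An object of class `sps_sim`: list with `alignment` (named codon
#'   sequences at the tips), `tree`, and `truth` (root sequence, complete
#'   per-event log, per-branch omega, kappa).
#' @examples
#' tr <- ape::read.tree(text = "(A:0.3,B:0.3);")
#' sim <- simulate_codon_evolution(tr, omega = 0.2, kappa = 2,
#'                                 n_codons = 100, seed = 1)
#' @export
simulate_codon_evolution <- function(tree, omega, kappa, n_codons, seed = NULL) {
  if (kappa <= 0) abort("kappa must be > 0", class = "spsevo_param_error")
  if (is.null(tree$edge.length)) abort("tree must have branch lengths")
  edge <- tree$edge
  branch_names <- vapply(edge[, 2], function(n) node_label(tree, n), character(1))
  if (length(omega) == 1 && is.null(names(omega))) {
    omega <- setNames(rep(omega, nrow(edge)), branch_names)
  }
  missing <- setdiff(branch_names, names(omega))
  if (length(missing)) {
    abort(paste("branch without omega entry:", paste(missing, collapse = ", ")),
          class = "spsevo_param_error")
  }
  if (any(omega < 0)) abort("omega must be >= 0", class = "spsevo_param_error")
  run <- function() {
    ntip <- length(tree$tip.label)
    root <- setdiff(edge[, 1], edge[, 2])[1]
    seqs <- vector("list", ntip + tree$Nnode)
    root_seq <- sample(SENSE_CODONS, n_codons, replace = TRUE)
    seqs[[root]] <- root_seq
    events <- list()
    for (e in order_edges_preorder(tree)) {
      par <- edge[e, 1]; chd <- edge[e, 2]
      bname <- branch_names[e]
      s <- seqs[[par]]
      n_ev <- rpois(1, tree$edge.length[e] * n_codons)
      w <- omega[[bname]]
      if (n_ev > 0) {
        for (i in seq_len(n_ev)) {
          col <- sample.int(n_codons, 1)
          pos <- sample.int(3, 1)
          from_codon <- s[col]
          b <- strsplit(from_codon, "")[[1]]
          alts <- setdiff(NUCS, b[pos])
          wts <- ifelse(is_transition(b[pos], alts), kappa, 1)
          nt <- sample(alts, 1, prob = wts)
          b2 <- b
          b2[pos] <- nt
          to_codon <- paste(b2, collapse = "")
          if (to_codon %in% STOP_CODONS) next
          syn <- GENETIC_CODE_DNA[from_codon] == GENETIC_CODE_DNA[to_codon]
          if (!syn && runif(1) >= w) next
          s[col] <- to_codon
          events[[length(events) + 1L]] <-
            list(branch = bname, column = col, from = from_codon,
                 to = to_codon, type = if (syn) "syn" else "nonsyn")
        }
      }
      seqs[[chd]] <- s
    }
    aln <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""),
                  character(1))
    names(aln) <- tree$tip.label
    ev <- if (length(events)) bind_rows(lapply(events, as_tibble)) else
      tibble(branch = character(), column = integer(), from = character(),
             to = character(), type = character())
    structure(list(alignment = aln, tree = tree,
                   truth = list(root_seq = root_seq, events = ev,
                                omega = omega, kappa = kappa)),
              class = "sps_sim")
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' Replay a simulation's event log from the root sequence
#'
#' Applies the truth log branch by branch down the tree; the result must
#' reproduce the simulated tip sequences exactly (this is the simulator's
#' internal consistency invariant).
#'
#' @param sim An `sps_sim` object.
#' @return Named codon sequences at the tips.
#' @export
replay_events <- function(sim) {
  tree <- sim$tree
  edge <- tree$edge
  ntip <- length(tree$tip.label)
  root <- setdiff(edge[, 1], edge[, 2])[1]
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- sim$truth$root_seq
  ev <- sim$truth$events
  for (e in order_edges_preorder(tree)) {
    par <- edge[e, 1]; chd <- edge[e, 2]
    s <- seqs[[par]]
    bname <- node_label(tree, chd)
    bev <- ev[ev$branch == bname, ]
    if (nrow(bev)) {
      for (i in seq_len(nrow(bev))) s[bev$column[i]] <- bev$to[i]
    }
    seqs[[chd]] <- s
  }
  out <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""),
                character(1))
  setNames(out, tree$tip.label)
}

#' Balanced tree with constant branch lengths for simulation studies
#'
#' @param n_leaves Number of tips (a power of two gives a fully balanced
#'   shape; otherwise a coalescent-like random topology is used).
#' @param branch_length Length assigned to every branch.
#' @param seed Optional seed for the random topology case.
#' @return An `ape::phylo` tree.
#' @export
sim_tree <- function(n_leaves, branch_length = 0.2, seed = NULL) {
  make <- function() {
    if (log2(n_leaves) %% 1 == 0) {
      tr <- ape::stree(n_leaves, type = "balanced")
    } else {
      tr <- ape::rtree(n_leaves, rooted = TRUE, br = NULL)
    }
    tr$tip.label <- paste0("t", seq_len(n_leaves))
    tr$edge.length <- rep(branch_length, nrow(tr$edge))
    tr
  }
  if (!is.null(seed)) withr::with_seed(seed, make()) else make()
}

#' @export
print.sps_sim <- function(x, ...) {
  cat("Simulated codon alignment:", length(x$alignment), "tips,",
      nchar(x$alignment[1]) / 3, "codons,",
      nrow(x$truth$events), "substitution events\n")
  invisible(x)
}
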