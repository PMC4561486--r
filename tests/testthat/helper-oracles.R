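# Independent oracles used across the suite. Each is a deliberately naive
# implementation (enumeration / exact integer arithmetic), kept separate
# from the package's own algorithms.

# All valid nested structures of a short sequence, by explicit recursive
# enumeration over "position 1 unpaired" vs "position 1 paired with k";
# returns the maximum total pair weight. Weights GC=3, AU=2, GU=1,
# hairpin loop >= 3.
oracle_fold_max <- function(seq) {
  s <- strsplit(toupper(seq), "")[[1]]
  w <- function(a, b) {
    p <- paste0(a, b)
    if (p %in% c("GC", "CG")) return(3)
    if (p %in% c("AT", "TA")) return(2)
    if (p %in% c("GT", "TG")) return(1)
    0
  }
  enum <- function(pos) {
    # pos: integer vector of available positions (increasing)
    if (length(pos) < 5) return(0)
    i <- pos[1]
    best <- enum(pos[-1])
    for (k in pos[-1]) {
      if (k - i < 4) next
      wk <- w(s[i], s[k])
      if (wk == 0) next
      inside <- pos[pos > i & pos < k]
      outside <- pos[pos > k]
      best <- max(best, wk + enum(inside) + enum(outside))
    }
    best
  }
  enum(seq_along(s))
}

# Exhaustive small-parsimony minimum: try every assignment of observed
# states to the internal nodes and count changes.
oracle_parsimony_min <- function(tree, leaf_states) {
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  states <- unique(unname(leaf_states))
  internals <- sort(unique(edge[, 1]))
  leaf_vec <- leaf_states[tree$tip.label]
  count_changes <- function(assignment) {
    full <- c(leaf_vec, assignment[as.character(internals)])
    names(full) <- c(seq_len(ntip), internals)
    sum(full[as.character(edge[, 1])] != full[as.character(edge[, 2])])
  }
  grids <- rep(list(states), length(internals))
  combos <- do.call(expand.grid, c(grids, stringsAsFactors = FALSE))
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    a <- setNames(as.character(combos[r, ]), as.character(internals))
    best <- min(best, count_changes(a))
  }
  best
}

# Exact hypergeometric upper tail using integer arithmetic only: every
# binomial coefficient involved is bounded by choose(n, k) <= choose(30, 15),
# well inside exact double-integer range.
oracle_hyper_upper <- function(x, k1, k2, n) {
  lo <- max(0, k1 + k2 - n)
  hi <- min(k1, k2)
  if (x <= lo) return(1)
  num <- 0
  for (k in x:hi) num <- num + choose(k1, k) * choose(n - k1, k2 - k)
  num / choose(n, k2)
}

# Per-codon synonymous site count by direct mutant enumeration.
oracle_syn_sites <- function(codon, code) {
  b <- strsplit(codon, "")[[1]]
  aa0 <- code[codon]
  s <- 0
  for (pos in 1:3) {
    for (nt in setdiff(c("A", "C", "G", "T"), b[pos])) {
      m <- b
      m[pos] <- nt
      aam <- code[paste(m, collapse = "")]
      if (aam != "*" && aam == aa0) s <- s + 1 / 3
    }
  }
  s
}

random_codon_string <- function(n) {
  sense <- setdiff(names(spsevo:::GENETIC_CODE_DNA),
                   c("TAA", "TAG", "TGA"))
  paste(sample(sense, n, replace = TRUE), collapse = "")
}

# Check that a dot-bracket string parses as properly nested.
is_nested_dotbracket <- function(db) {
  depth <- 0
  for (ch in strsplit(db, "")[[1]]) {
    if (ch == "(") depth <- depth + 1
    if (ch == ")") depth <- depth - 1
    if (depth < 0) return(FALSE)
  }
  depth == 0
}

seed_profile <- function() sps_seed_profile()

# Apply off-site amino-acid substitution noise to a protein.
add_protein_noise <- function(protein, rate, site) {
  aa <- strsplit(protein, "")[[1]]
  mutable <- setdiff(seq_along(aa), site)
  hit <- mutable[runif(length(mutable)) < rate]
  aa20 <- setdiff(spsevo:::AA_ALPHABET_21, "U")
  if (length(hit)) aa[hit] <- sample(aa20, length(hit), replace = TRUE)
  paste(aa, collapse = "")
}
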