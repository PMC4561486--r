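# Readthrough-signal detection around in-frame UGA codons: exact scan for
# the GGG-TG[C/T] hexanucleotide, single-sequence stem-loop folding by
# maximum-weighted-pair dynamic programming (GC=3, AU=2, GU=1, hairpin loop
# >= 3), and an alignment-level consensus fold with covariation support.
# Folding operates on the DNA alphabet with T standing for U.

pair_weight_nt <- function(a, b) {
  w <- matrix(0, 4, 4, dimnames = list(NUCS, NUCS))
  w["G", "C"] <- w["C", "G"] <- 3
  w["A", "T"] <- w["T", "A"] <- 2
  w["G", "T"] <- w["T", "G"] <- 1
  w
}

#' Scan for the readthrough-enhancing hexanucleotide after a UGA
#'
#' Exact string match of `GGGTGC` / `GGGTGT` starting 1-9 nt after the
#' in-frame TGA; a hit at offset 1 (immediately adjacent) is flagged
#' `adjacent`, later starts `proximal`.
#'
#' @param cds DNA string.
#' @param uga_position 1-based position of the `T` of the in-frame TGA.
#' @param gene_id Optional id carried into the output.
#' @return Tibble of hits: `gene_id`, `offset`, `variant`, `adjacency`
#'   (zero rows if none).
#' @export
scan_hexamer <- function(cds, uga_position, gene_id = NA_character_) {
  cds <- toupper(cds)
  if (substr(cds, uga_position, uga_position + 2) != "TGA") {
    abort("uga_position does not index a TGA codon",
          class = "spsevo_position_error")
  }
  hits <- list()
  for (off in 1:9) {
    s <- uga_position + 3 + off - 1
    hex <- substr(cds, s, s + 5)
    if (hex %in% c("GGGTGC", "GGGTGT")) {
      hits[[length(hits) + 1L]] <- tibble(
        gene_id = gene_id, offset = off, variant = hex,
        adjacency = if (off == 1) "adjacent" else "proximal"
      )
    }
  }
  if (length(hits)) bind_rows(hits) else
    tibble(gene_id = character(), offset = integer(), variant = character(),
           adjacency = character())
}

#' Fold a sequence window by maximum-weighted base pairing
#'
#' Nussinov-style dynamic programming maximizing the summed pair weights
#' (GC = 3, AU = 2, GU = 1) over all nested structures with hairpin loops of
#' at least 3 nt. Traceback is deterministic: prefer leaving the 5' base
#' unpaired, then pairing it with the smallest admissible partner.
#' Stems are maximal runs of >= 3 stacked pairs.
#'
#' @param window DNA string (20-200 nt).
#' @param uga_pos Optional 1-based position of the `T` of a TGA within the
#'   window; enables the `uga_context` call.
#' @return An object of class `sps_fold`: `pairs` tibble (`i`, `j`,
#'   `weight`), `dotbracket`, `score`, `stems` tibble, `n_stems`,
#'   `uga_context` (one of `in_apical_loop`, `in_stem`, `unpaired_outside`,
#'   or NA when `uga_pos` is not given).
#' @export
fold_window <- function(window, uga_pos = NULL) {
  window <- toupper(chartr("U", "T", window))
  n <- nchar(window)
  if (n < 1) abort("empty window")
  s <- strsplit(window, "")[[1]]
  if (!all(s %in% c(NUCS, "N"))) abort("non-nucleotide characters in window")
  W <- pair_weight_nt()
  wm <- matrix(0, n, n)
  known <- s %in% NUCS
  for (i in seq_len(n)) {
    if (!known[i]) next
    wm[i, known] <- W[s[i], s[known]]
  }
  fold <- fold_weight_matrix(wm, n, uga_pos)
  fold$window <- window
  fold
}

build_fold <- function(pairs_tbl, n, score, uga_pos, window = NULL) {
  db <- rep(".", n)
  db[pairs_tbl$i] <- "("
  db[pairs_tbl$j] <- ")"
  stems <- find_stems(pairs_tbl)
  uga_context <- NA_character_
  if (!is.null(uga_pos)) {
    uga_context <- call_uga_context(pairs_tbl, uga_pos, n)
  }
  structure(list(pairs = pairs_tbl, dotbracket = paste(db, collapse = ""),
                 score = score, stems = stems, n_stems = nrow(stems),
                 uga_pos = uga_pos, window = window,
                 uga_context = uga_context, n = n),
            class = "sps_fold")
}

# Maximal runs of >= 3 stacked pairs: (i,j), (i+1,j-1), ...
find_stems <- function(pairs_tbl) {
  if (nrow(pairs_tbl) == 0) {
    return(tibble(i_start = integer(), i_end = integer(), j_start = integer(),
                  j_end = integer(), length = integer()))
  }
  p <- arrange(pairs_tbl, i)
  key <- paste(p$i, p$j)
  runs <- list()
  used <- rep(FALSE, nrow(p))
  for (r in seq_len(nrow(p))) {
    if (used[r]) next
    i0 <- p$i[r]; j0 <- p$j[r]
    len <- 1L
    while (paste(i0 + len, j0 - len) %in% key) len <- len + 1L
    idx <- match(paste(i0 + 0:(len - 1), j0 - 0:(len - 1)), key)
    used[idx] <- TRUE
    runs[[length(runs) + 1L]] <- tibble(
      i_start = i0, i_end = i0 + len - 1L,
      j_start = j0 - len + 1L, j_end = j0, length = len
    )
  }
  filter(bind_rows(runs), length >= 3)
}

call_uga_context <- function(pairs_tbl, uga_pos, n) {
  u <- uga_pos:(uga_pos + 2)
  paired_pos <- c(pairs_tbl$i, pairs_tbl$j)
  # hairpin loops: closing pairs with no pairs inside
  if (nrow(pairs_tbl)) {
    for (r in seq_len(nrow(pairs_tbl))) {
      i <- pairs_tbl$i[r]; j <- pairs_tbl$j[r]
      interior <- (i + 1):(j - 1)
      if (!any(interior %in% paired_pos) &&
          all(u > i) && all(u < j)) {
        return("in_apical_loop")
      }
    }
  }
  if (any(u %in% paired_pos)) return("in_stem")
  "unpaired_outside"
}

#' @export
print.sps_fold <- function(x, ...) {
  cat("Fold: score", x$score, ";", nrow(x$pairs), "pairs;",
      x$n_stems, "stem(s)")
  if (!is.na(x$uga_context)) cat("; UGA", x$uga_context)
  cat("\n", x$dotbracket, "\n", sep = "")
  invisible(x)
}

#' Consensus fold of aligned sequence windows with covariation support
#'
#' A column pair is admissible iff it is complementary (including GU) in at
#' least a fraction `q` of the rows that are gapless at both columns; its
#' weight is the mean pair weight over those rows. The admissible weight
#' matrix is folded as in [fold_window()]. Covariation counts consensus
#' pairs at which at least one row differs from the modal nucleotide pair at
#' both positions while remaining complementary.
#'
#' @param windows Named character vector of aligned windows (equal length,
#'   gap `-`), at least 4 sequences, per-column gap fraction <= 0.5.
#' @param q Minimum pairability (default 0.8).
#' @param uga_pos Optional UGA position in alignment coordinates.
#' @return An object of class `sps_consensus`: the `sps_fold` fields plus
#'   `pairability` per consensus pair and `covariation` (count).
#' @export
consensus_fold <- function(windows, q = 0.8, uga_pos = NULL) {
  if (length(windows) < 4) abort("need >= 4 aligned windows",
                                 class = "spsevo_input_error")
  lens <- nchar(windows)
  if (length(unique(lens)) != 1) abort("ragged alignment",
                                       class = "spsevo_ragged_error")
  m <- do.call(rbind, strsplit(toupper(chartr("U", "T", windows)), ""))
  n <- ncol(m)
  gap_frac <- colMeans(m == "-")
  if (any(gap_frac > 0.5)) abort("column gap fraction > 0.5",
                                 class = "spsevo_input_error")
  W <- pair_weight_nt()
  wm <- matrix(0, n, n)
  pm <- matrix(0, n, n)
  for (i in seq_len(n - 4)) {
    for (j in (i + 4):n) {
      rows <- m[, i] != "-" & m[, j] != "-" & m[, i] %in% NUCS & m[, j] %in% NUCS
      if (!any(rows)) next
      wts <- W[cbind(m[rows, i], m[rows, j])]
      pab <- mean(wts > 0)
      pm[i, j] <- pab
      if (pab >= q) wm[i, j] <- mean(wts)
    }
  }
  fold <- fold_weight_matrix(wm, n, uga_pos)
  cov <- 0L
  if (nrow(fold$pairs)) {
    pairability <- pm[cbind(fold$pairs$i, fold$pairs$j)]
    fold$pairs$pairability <- pairability
    for (r in seq_len(nrow(fold$pairs))) {
      i <- fold$pairs$i[r]; j <- fold$pairs$j[r]
      rows <- m[, i] != "-" & m[, j] != "-"
      pr <- paste0(m[rows, i], m[rows, j])
      modal <- names(sort(table(pr), decreasing = TRUE))[1]
      ma <- substr(modal, 1, 1); mb <- substr(modal, 2, 2)
      compl <- W[cbind(m[rows, i], m[rows, j])] > 0
      differs <- m[rows, i] != ma & m[rows, j] != mb
      if (any(compl & differs)) cov <- cov + 1L
    }
  }
  fold$covariation <- cov
  class(fold) <- c("sps_consensus", "sps_fold")
  fold
}

# Nussinov on an arbitrary admissible-weight matrix (upper triangle).
fold_weight_matrix <- function(wm, n, uga_pos = NULL) {
  F <- matrix(0, n, n)
  if (n >= 5) {
    for (len in 5:n) {
      for (i in seq_len(n - len + 1)) {
        j <- i + len - 1
        best <- F[i + 1, j]
        ks <- (i + 4):j
        ks <- ks[wm[i, ks] > 0]
        if (length(ks)) {
          inner <- vapply(ks, function(k) if (k - 1 >= i + 1) F[i + 1, k - 1] else 0, numeric(1))
          right <- vapply(ks, function(k) if (k + 1 <= j) F[k + 1, j] else 0, numeric(1))
          best <- max(best, max(wm[i, ks] + inner + right))
        }
        F[i, j] <- best
      }
    }
  }
  pairs <- matrix(integer(0), ncol = 2)
  stack <- list(c(1L, n))
  tol <- 1e-9
  while (length(stack)) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- iv[1]; j <- iv[2]
    while (i < j) {
      if (j - i < 4) break
      if (abs(F[i, j] - F[i + 1, j]) < tol) {
        i <- i + 1L
        next
      }
      ks <- (i + 4):j
      ks <- ks[wm[i, ks] > 0]
      hit <- NA_integer_
      for (k in ks) {
        inner <- if (k - 1 >= i + 1) F[i + 1, k - 1] else 0
        right <- if (k + 1 <= j) F[k + 1, j] else 0
        if (abs(F[i, j] - (wm[i, k] + inner + right)) < tol) {
          hit <- k
          break
        }
      }
      pairs <- rbind(pairs, c(i, hit))
      if (hit + 1 <= j) stack[[length(stack) + 1L]] <- c(hit + 1L, j)
      j <- hit - 1L
      i <- i + 1L
    }
  }
  pairs_tbl <- if (nrow(pairs)) {
    tibble(i = pairs[, 1], j = pairs[, 2], weight = wm[pairs]) |> arrange(i)
  } else {
    tibble(i = integer(), j = integer(), weight = numeric())
  }
  build_fold(pairs_tbl, n, score = F[1, n], uga_pos = uga_pos)
}

#' Classify a folded UGA window as a recoding element
#'
#' `HRE` (hymenopteran readthrough element): at least three stems with the
#' UGA in an apical loop or in the apical half of the central stem — the
#' three-stem clover with the UGA at the middle-stem apex. `SRE` (Sec
#' redefinition element): one or two stems, the first beginning no later
#' than 12 nt downstream of the UGA. `bSECIS-like` (prokaryotic scan mode
#' only): a single stem entirely 3' of the UGA. Otherwise `none`.
#'
#' @param fold An `sps_fold` with `uga_pos` set.
#' @param mode `"eukaryotic"` (default) or `"prokaryotic"`.
#' @return One of `"HRE"`, `"SRE"`, `"bSECIS-like"`, `"none"`.
#' @export
classify_recoding_element <- function(fold, mode = c("eukaryotic", "prokaryotic")) {
  mode <- match.arg(mode)
  if (is.null(fold$uga_pos)) abort("fold lacks uga_pos")
  uga_end <- fold$uga_pos + 2
  st <- fold$stems
  if (fold$n_stems >= 3) {
    if (fold$uga_context == "in_apical_loop") return("HRE")
    # apical half of the central stem
    mid <- st[order(abs((st$i_start + st$j_end) / 2 - fold$uga_pos)), ][1, ]
    u <- fold$uga_pos:uga_end
    run <- seq(0, mid$length - 1)
    depth_i <- mid$i_start + run
    depth_j <- mid$j_end - run
    apical <- run >= mid$length / 2
    if (any(u %in% c(depth_i[apical], depth_j[apical]))) return("HRE")
  }
  if (mode == "prokaryotic" && fold$n_stems == 1 &&
      st$i_start[1] > uga_end) {
    return("bSECIS-like")
  }
  if (fold$n_stems >= 1 && fold$n_stems <= 2 &&
      min(st$i_start) <= uga_end + 12) {
    return("SRE")
  }
  "none"
}
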