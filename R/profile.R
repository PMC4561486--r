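# Seed-profile handling and overlap (free-end-gap) alignment of candidate SPS
# proteins against it. The profile is a plain aligned FASTA with a marked
# selenocysteine column; scoring is per-column log-odds over the 21-letter
# alphabet (20 amino acids + U) with add-one pseudocounts.

PROFILE_GAP <- "-"

#' Build a position-specific profile from an alignment
#'
#' Per-column symbol frequencies over the 21-letter alphabet (20 amino acids
#' plus U, selenocysteine) with add-one pseudocounts —
#' `(count + 1) / (non-gap count + 21)` — and log-odds scores against the
#' uniform background 1/21 (in half-bits, `2 * log2(21 * freq)`).
#'
#' @param aligned Named character vector of aligned protein sequences of
#'   equal length (gap `-`).
#' @param sec_column 1-based index of the column homologous to the
#'   selenocysteine UGA site; at least one sequence must carry `U` there.
#' @return An object of class `sps_profile`.
#' @export
build_profile <- function(aligned, sec_column) {
  if (length(aligned) < 2) abort("need >= 2 aligned sequences")
  lens <- nchar(aligned)
  if (length(unique(lens)) != 1) abort("ragged alignment",
                                       class = "spsevo_ragged_error")
  L <- unique(lens)
  if (sec_column < 1 || sec_column > L) abort("sec_column out of range")
  m <- do.call(rbind, strsplit(toupper(aligned), ""))
  bad <- setdiff(unique(as.vector(m)), c(AA_ALPHABET_21, PROFILE_GAP, "X"))
  if (length(bad)) abort(paste("illegal symbols:", paste(bad, collapse = " ")))
  if (all(m[, sec_column] == PROFILE_GAP)) {
    abort("sec_column is all-gap", class = "spsevo_profile_error")
  }
  if (!any(m[, sec_column] == "U")) {
    abort("no sequence carries U at sec_column", class = "spsevo_profile_error")
  }
  freq <- vapply(seq_len(L), function(j) {
    col <- m[, j]
    col <- col[col != PROFILE_GAP & col != "X"]
    (tabulate(match(col, AA_ALPHABET_21), 21) + 1) / (length(col) + 21)
  }, numeric(21))
  rownames(freq) <- AA_ALPHABET_21
  score <- 2 * log2(21 * freq)
  score <- rbind(score, X = 0)
  consensus <- AA_ALPHABET_21[apply(freq, 2, which.max)]
  structure(list(freq = freq, score = score, sec_column = sec_column,
                 consensus = consensus, n_columns = L,
                 n_seq = length(aligned), alignment = aligned),
            class = "sps_profile")
}

#' @export
print.sps_profile <- function(x, ...) {
  cat("SPS profile:", x$n_seq, "sequences x", x$n_columns,
      "columns; Sec column", x$sec_column, "\n")
  invisible(x)
}

#' Read a profile from aligned FASTA plus a sidecar Sec-column key
#'
#' @param path Aligned FASTA file.
#' @param sec_column Sec column index; if `NULL`, read from the sidecar file
#'   `<path without extension>.sec_column.txt` (a single integer).
#' @return An `sps_profile`.
#' @export
read_profile <- function(path, sec_column = NULL) {
  aligned <- read_fasta(path, type = "protein", aligned = TRUE)
  if (is.null(sec_column)) {
    sidecar <- paste0(sub("\\.[^.]+$", "", path), ".sec_column.txt")
    if (!file.exists(sidecar)) abort(paste("sidecar not found:", sidecar))
    sec_column <- as.integer(readLines(sidecar, warn = FALSE)[1])
  }
  build_profile(aligned, sec_column)
}

#' The packaged seed SPS profile
#'
#' A small curated alignment (10 sequences x 120 columns) of synthetic SPS
#' family members with the selenocysteine column marked; both U and C occur
#' at that column, as in real SPS2 families.
#'
#' @return An `sps_profile`.
#' @export
sps_seed_profile <- function() {
  read_profile(system.file("extdata", "sps_profile.fasta",
                           package = "spsevo", mustWork = TRUE))
}

#' Align a protein to a profile (overlap alignment)
#'
#' Free-end-gap dynamic programming maximizing summed per-column log-odds
#' with affine gap costs (default open 11, extend 1). Terminal overhangs on
#' either side are unpenalized, so fused domains dangle instead of truncating
#' the core map. Traceback is deterministic: on ties diagonal is preferred,
#' then a profile-column gap, then a protein insertion.
#'
#' @param protein Protein string over the 21-letter alphabet (plus `X`).
#' @param profile An `sps_profile`.
#' @param gap_open,gap_ext Positive gap penalties.
#' @return An object of class `sps_alignment`: list with `mapping` (integer
#'   vector over profile columns; the protein position aligned to each column
#'   or NA for a gap), `score`, `protein`.
#' @export
align_to_profile <- function(protein, profile, gap_open = 11, gap_ext = 1) {
  stopifnot(inherits(profile, "sps_profile"))
  protein <- toupper(protein)
  if (nchar(protein) == 0) abort("empty protein", class = "spsevo_input_error")
  p <- strsplit(protein, "")[[1]]
  bad <- setdiff(unique(p), c(AA_ALPHABET_21, "X"))
  if (length(bad)) {
    abort(paste("symbols outside alphabet:", paste(bad, collapse = " ")),
          class = "spsevo_input_error")
  }
  L <- profile$n_columns
  n <- length(p)
  S <- profile$score[p, , drop = FALSE] # n x L: score of residue j at column i
  NEG <- -1e9
  M <- matrix(NEG, L + 1, n + 1)   # column i aligned to residue j
  Ix <- matrix(NEG, L + 1, n + 1)  # profile column skipped (gap in protein)
  Iy <- matrix(NEG, L + 1, n + 1)  # protein residue unaligned (insertion)
  H <- matrix(NEG, L + 1, n + 1)
  H[1, ] <- 0  # free leading protein overhang
  H[, 1] <- 0  # free leading unmatched profile columns
  for (i in seq_len(L)) {
    M[i + 1, 2:(n + 1)] <- H[i, 1:n] + S[, i]
    Ix[i + 1, ] <- pmax(H[i, ] - gap_open, Ix[i, ] - gap_ext)
    G <- pmax(M[i + 1, ], Ix[i + 1, ])
    # Iy along the row via running maximum of G[k] + k*gap_ext
    cm <- cummax(G[1:n] + seq_len(n) * gap_ext)
    Iy[i + 1, 2:(n + 1)] <- cm - gap_open - (2:(n + 1)) * gap_ext + gap_ext
    H[i + 1, ] <- pmax(G, Iy[i + 1, ])
    H[i + 1, 1] <- 0 # leading unmatched profile columns stay free
  }
  # free trailing overhangs: best cell on last row or last column
  end_row <- H[L + 1, ]
  end_col <- H[, n + 1]
  if (max(end_row) >= max(end_col)) {
    j <- which.max(end_row) - 1L; i <- L
  } else {
    i <- which.max(end_col) - 1L; j <- n
  }
  score <- H[i + 1, j + 1]
  mapping <- rep(NA_integer_, L)
  tol <- 1e-7
  state <- "H"
  while (i > 0 || j > 0) {
    if (state == "H") {
      if (i == 0 || j == 0) break # free leading overhang
      h <- H[i + 1, j + 1]
      state <- if (abs(h - M[i + 1, j + 1]) < tol) "M"
      else if (abs(h - Ix[i + 1, j + 1]) < tol) "Ix"
      else "Iy"
    } else if (state == "M") {
      mapping[i] <- j
      i <- i - 1L; j <- j - 1L
      state <- "H"
    } else if (state == "Ix") {
      opened <- abs(Ix[i + 1, j + 1] - (H[i, j + 1] - gap_open)) < tol
      i <- i - 1L
      if (opened) state <- "H"
    } else { # Iy
      g <- max(M[i + 1, j], Ix[i + 1, j])
      opened <- abs(Iy[i + 1, j + 1] - (g - gap_open)) < tol
      closing_state <- if (abs(g - M[i + 1, j]) < tol) "M" else "Ix"
      j <- j - 1L
      if (opened) state <- closing_state
    }
  }
  structure(list(mapping = mapping, score = score, protein = protein),
            class = "sps_alignment")
}

#' @export
print.sps_alignment <- function(x, ...) {
  cat("Profile alignment: score", round(x$score, 2), ";",
      sum(!is.na(x$mapping)), "of", length(x$mapping), "columns mapped\n")
  invisible(x)
}
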