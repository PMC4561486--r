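# Nei-Gojobori (1986) counting: synonymous/nonsynonymous site and difference
# counts with Jukes-Cantor correction. Codon-level tables are enumerated once
# from the genetic code and cached.

.spsevo_cache <- new.env(parent = emptyenv())

NUCS <- c("A", "C", "G", "T")

codon_mutants <- function(codon) {
  b <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (pos in 1:3) {
    for (nt in setdiff(NUCS, b[pos])) {
      m <- b
      m[pos] <- nt
      out <- c(out, paste(m, collapse = ""))
    }
  }
  out
}

# Per-codon synonymous site count: each position contributes the fraction of
# its 3 single-nucleotide mutants that are synonymous. Mutants that create a
# stop codon count as nonsynonymous (stop_mode = "nonsyn", the default that
# preserves N + S = 3) or are excluded from the denominator ("exclude").
syn_sites_codon <- function(codon, stop_mode = c("nonsyn", "exclude")) {
  stop_mode <- match.arg(stop_mode)
  aa0 <- GENETIC_CODE_DNA[codon]
  b <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    muts <- vapply(setdiff(NUCS, b[pos]), function(nt) {
      m <- b
      m[pos] <- nt
      paste(m, collapse = "")
    }, character(1))
    aam <- GENETIC_CODE_DNA[muts]
    if (stop_mode == "exclude") {
      keep <- aam != "*"
      if (!any(keep)) next
      s <- s + sum(aam[keep] == aa0) / sum(keep)
    } else {
      s <- s + sum(aam == aa0 & aam != "*") / 3
    }
  }
  s
}

ng86_site_table <- function(stop_mode = "nonsyn") {
  key <- paste0("sites_", stop_mode)
  if (is.null(.spsevo_cache[[key]])) {
    s <- vapply(SENSE_CODONS, syn_sites_codon, numeric(1), stop_mode = stop_mode)
    .spsevo_cache[[key]] <- s
  }
  .spsevo_cache[[key]]
}

# Syn/nonsyn difference counts between two codons, averaging over all
# mutational pathways (orders of the differing positions). Pathways passing
# through a stop codon are excluded; if every pathway does, all are included
# with the stop-entering steps counted as nonsynonymous.
ng86_pair_diff <- function(c1, c2) {
  b1 <- strsplit(c1, "")[[1]]
  b2 <- strsplit(c2, "")[[1]]
  dpos <- which(b1 != b2)
  nd <- length(dpos)
  if (nd == 0) return(c(syn = 0, nonsyn = 0))
  perms <- if (nd == 1) list(dpos) else {
    if (nd == 2) list(dpos, rev(dpos)) else {
      idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                  c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
      lapply(idx, function(i) dpos[i])
    }
  }
  path_counts <- function(order, stops_nonsyn) {
    cur <- b1
    s <- 0; n <- 0
    for (pos in order) {
      nxt <- cur
      nxt[pos] <- b2[pos]
      a1 <- GENETIC_CODE_DNA[paste(cur, collapse = "")]
      a2 <- GENETIC_CODE_DNA[paste(nxt, collapse = "")]
      if (a2 == "*" || a1 == "*") {
        if (!stops_nonsyn) return(NULL)
        n <- n + 1
      } else if (a1 == a2) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    c(s, n)
  }
  res <- lapply(perms, path_counts, stops_nonsyn = FALSE)
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0) res <- lapply(perms, path_counts, stops_nonsyn = TRUE)
  m <- do.call(rbind, res)
  c(syn = mean(m[, 1]), nonsyn = mean(m[, 2]))
}

ng86_diff_tables <- function() {
  if (is.null(.spsevo_cache$diff_syn)) {
    k <- length(CODON_STATES)
    syn <- matrix(0, k, k, dimnames = list(CODON_STATES, CODON_STATES))
    non <- syn
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        if (i == j) next
        d <- ng86_pair_diff(CODON_STATES[i], CODON_STATES[j])
        syn[i, j] <- d["syn"]
        non[i, j] <- d["nonsyn"]
      }
    }
    .spsevo_cache$diff_syn <- syn
    .spsevo_cache$diff_nonsyn <- non
  }
  list(syn = .spsevo_cache$diff_syn, nonsyn = .spsevo_cache$diff_nonsyn)
}

#' Pairwise Ka/Ks by the Nei-Gojobori counting method
#'
#' Counts synonymous (S) and nonsynonymous (N) sites averaged over the two
#' sequences, synonymous (Sd) and nonsynonymous (Nd) differences averaged over
#' all mutational pathways, and applies the Jukes-Cantor correction
#' `K = -3/4 * log(1 - 4p/3)` to the raw proportions. Single-nucleotide
#' mutants that create a stop codon count as nonsynonymous, which preserves
#' the identity `N + S = 3 * codons`; pathways through stop codons are
#' excluded unless all are, in which case stop-entering steps count as
#' nonsynonymous.
#'
#' @param a,b Codon vectors (e.g. from [codon_split()]) or in-frame DNA
#'   strings of equal length. TGA is permitted (Sec site); mask it with
#'   `mask` if it should not be counted.
#' @param mask Optional integer vector of codon columns to exclude.
#' @param correct Apply the Jukes-Cantor correction (default). With
#'   `correct = FALSE` only counts and raw proportions are returned (Ka, Ks,
#'   omega are NA) and saturation is not an error — useful for inspecting
#'   counts on very short stretches.
#' @return A one-row tibble with columns `codons`, `N`, `S`, `Nd`, `Sd`,
#'   `pN`, `pS`, `Ka`, `Ks`, `omega` (`NA` when `Ks` is 0).
#' @examples
#' ng86_pairwise("TTTATG", "TTCATG")  # one synonymous difference
#' @export
ng86_pairwise <- function(a, b, mask = integer(0), correct = TRUE) {
  if (length(a) == 1 && nchar(a[1]) > 3) a <- codon_split(a)
  if (length(b) == 1 && nchar(b[1]) > 3) b <- codon_split(b)
  if (length(a) != length(b)) {
    abort("sequences differ in codon length", class = "spsevo_length_error")
  }
  keep <- setdiff(seq_along(a), mask)
  a <- toupper(a[keep]); b <- toupper(b[keep])
  ok <- a %in% CODON_STATES & b %in% CODON_STATES
  a <- a[ok]; b <- b[ok]
  nc <- length(a)
  if (nc == 0) {
    return(tibble(codons = 0L, N = 0, S = 0, Nd = 0, Sd = 0,
                  pN = 0, pS = 0, Ka = 0, Ks = 0, omega = NA_real_))
  }
  st <- ng86_site_table()
  # TGA carries no site definition in the standard table; treat like the
  # counting of its non-stop mutants (it only appears when unmasked on purpose)
  s_of <- function(x) ifelse(x == "TGA", syn_sites_codon_tga(), st[x])
  S <- (sum(s_of(a)) + sum(s_of(b))) / 2
  N <- 3 * nc - S
  dt <- ng86_diff_tables()
  idx <- cbind(match(a, CODON_STATES), match(b, CODON_STATES))
  Sd <- sum(dt$syn[idx])
  Nd <- sum(dt$nonsyn[idx])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  if (!correct) {
    return(tibble(codons = nc, N = N, S = S, Nd = Nd, Sd = Sd, pN = pN,
                  pS = pS, Ka = NA_real_, Ks = NA_real_, omega = NA_real_))
  }
  if (pS >= 3 / 4 || pN >= 3 / 4) {
    abort("substitution proportion at or beyond Jukes-Cantor saturation",
          class = "spsevo_saturation_error")
  }
  jc <- function(p) -3 / 4 * log(1 - 4 * p / 3)
  Ka <- jc(pN); Ks <- jc(pS)
  tibble(codons = nc, N = N, S = S, Nd = Nd, Sd = Sd, pN = pN, pS = pS,
         Ka = Ka, Ks = Ks, omega = if (Ks > 0) Ka / Ks else NA_real_)
}

syn_sites_codon_tga <- function() {
  if (is.null(.spsevo_cache$tga_sites)) {
    # TGA as the Sec state: mutants to TAA/TAG are stops (nonsyn), others
    # change the residue; no synonymous mutant exists.
    .spsevo_cache$tga_sites <- 0
  }
  .spsevo_cache$tga_sites
}
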