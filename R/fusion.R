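# Extension/fusion detection: extend each annotated CDS in frame to the
# flanking stop codons, align the extended translation to the seed profile,
# report terminal stretches not covered by the profile, and cluster
# recurrent extensions by similarity.

#' Extend an annotated CDS to the flanking in-frame stop codons
#'
#' Walks upstream and downstream of the annotated gene codon-by-codon in
#' frame, stopping (exclusively) at the first stop codon or the contig
#' edge. Minus-strand genes are handled by reverse complement; coordinates
#' are 0-based half-open.
#'
#' @param genome Named DNA string (or plain string) for the contig.
#' @param annotation One-row tibble with `start`, `end`, `strand` (as from
#'   [read_cds_annotations()]).
#' @return List: `cds` (extended, in gene orientation), `up_codons`,
#'   `down_codons` (codons gained on each side).
#' @export
extend_orf <- function(genome, annotation) {
  seq <- unname(genome[[1]])
  L <- nchar(seq)
  start <- annotation$start[1]
  end <- annotation$end[1]
  if (start < 0 || end > L) abort("gene coordinates outside contig",
                                  class = "spsevo_coord_error")
  if (annotation$strand[1] == "-") {
    seq <- revcomp(seq)
    tmp <- start
    start <- L - end
    end <- L - tmp
  }
  core <- substr(seq, start + 1, end)
  up <- 0L
  pos <- start
  repeat {
    if (pos - 3 < 0) break
    codon <- substr(seq, pos - 2, pos)
    if (codon %in% STOP_CODONS || grepl("[^ACGT]", codon)) break
    up <- up + 1L
    pos <- pos - 3L
  }
  down <- 0L
  pos <- end
  repeat {
    if (pos + 3 > L) break
    codon <- substr(seq, pos + 1, pos + 3)
    if (codon %in% STOP_CODONS || grepl("[^ACGT]", codon)) break
    down <- down + 1L
    pos <- pos + 3L
  }
  ext <- substr(seq, start - 3 * up + 1, end + 3 * down)
  list(cds = ext, up_codons = up, down_codons = down)
}

#' Detect terminal extensions relative to the profile alignment
#'
#' Aligns the extended translation to the profile; residues before the
#' first / after the last profile-aligned position form N-/C-terminal
#' extension candidates, reported when at least `min_extension` aa long.
#'
#' @param extended_protein Protein string (e.g. translation of
#'   [extend_orf()] output; in-frame TGA as `U`).
#' @param profile An `sps_profile`.
#' @param gene_id Identifier carried into the report.
#' @param min_extension Minimum reportable extension length (aa).
#' @return Tibble: `gene_id`, `side` (`N`/`C`), `extension_len`,
#'   `extension_sequence` (zero rows when nothing reaches threshold).
#' @export
detect_extension <- function(extended_protein, profile, gene_id = NA_character_,
                             min_extension = 50) {
  aln <- align_to_profile(extended_protein, profile)
  mapped <- aln$mapping[!is.na(aln$mapping)]
  out <- tibble(gene_id = character(), side = character(),
                extension_len = integer(), extension_sequence = character())
  if (length(mapped) == 0) return(out)
  n <- nchar(extended_protein)
  n_ext <- min(mapped) - 1L
  c_ext <- n - max(mapped)
  if (n_ext >= min_extension) {
    out <- bind_rows(out, tibble(
      gene_id = gene_id, side = "N", extension_len = n_ext,
      extension_sequence = substr(extended_protein, 1, n_ext)
    ))
  }
  if (c_ext >= min_extension) {
    out <- bind_rows(out, tibble(
      gene_id = gene_id, side = "C", extension_len = c_ext,
      extension_sequence = substr(extended_protein, max(mapped) + 1, n)
    ))
  }
  out
}

#' Cluster recurrent extensions by similarity
#'
#' Single-linkage clustering: two extensions are linked iff their global
#' alignment identity is at least `min_identity` over at least
#' `min_coverage` mutual length coverage. Cluster ids are assigned by
#' decreasing cluster size, ties broken by the lexicographically smallest
#' member gene id; clusters with at least two members are `confidence =
#' "high"`, singletons `"low"`.
#'
#' @param reports Tibble from [detect_extension()] (>= 1 row).
#' @param min_identity Identity threshold (matches / longer length).
#' @param min_coverage Mutual coverage threshold (shorter / longer length).
#' @return `reports` with `cluster_id` and `confidence` columns, ordered by
#'   cluster.
#' @export
cluster_extensions <- function(reports, min_identity = 0.30,
                               min_coverage = 0.80) {
  n <- nrow(reports)
  if (n == 0) abort("no extension reports", class = "spsevo_input_error")
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (extension_link(reports$extension_sequence[i],
                           reports$extension_sequence[j],
                           min_identity, min_coverage)) {
          parent[find(j)] <- find(i)
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  sizes <- table(comp)
  firsts <- vapply(split(reports$gene_id, comp), function(g) min(sort(g)),
                   character(1))
  ord <- order(-as.integer(sizes), firsts)
  id_map <- setNames(seq_along(ord), names(sizes)[ord])
  reports |>
    mutate(cluster_id = unname(id_map[as.character(comp)]),
           confidence = ifelse(as.integer(sizes[as.character(comp)]) >= 2,
                               "high", "low")) |>
    arrange(cluster_id, gene_id)
}

extension_link <- function(a, b, min_identity, min_coverage) {
  la <- nchar(a); lb <- nchar(b)
  if (min(la, lb) / max(la, lb) < min_coverage) return(FALSE)
  identity_global(a, b) >= min_identity
}

# global alignment identity = matches / longer sequence length
identity_global <- function(a, b) {
  mat <- match_substitution_matrix()
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = mat, gapOpening = 10, gapExtension = 4,
    type = "global"
  )
  Biostrings::nmatch(pa) / max(nchar(a), nchar(b))
}

match_substitution_matrix <- function() {
  if (is.null(.spsevo_cache$submat)) {
    letters_aa <- c(AA_ALPHABET_21, "X", "*")
    m <- matrix(-1, length(letters_aa), length(letters_aa),
                dimnames = list(letters_aa, letters_aa))
    diag(m) <- 2
    .spsevo_cache$submat <- m
  }
  .spsevo_cache$submat
}
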