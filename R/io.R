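# Readers/writers for the standard formats the pipeline touches. Internal
# coordinates are 0-based half-open; GFF3's 1-based inclusive coordinates are
# converted at the boundary.

IUPAC_NT <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N")

#' Read a FASTA file into a named character vector
#'
#' Sequences are upper-cased and validated; for nucleotide input, `U` is
#' mapped to `T`. Duplicate ids, empty sequences and symbols outside the
#' IUPAC nucleotide / amino-acid sets are errors.
#'
#' @param path FASTA file.
#' @param type `"dna"` or `"protein"`.
#' @param aligned Allow the gap character `-` (aligned FASTA).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("dna", "protein"), aligned = FALSE) {
  type <- match.arg(type)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(paste("duplicate FASTA id:", ids[duplicated(ids)][1]),
          class = "spsevo_duplicate_id_error")
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (any(nchar(seqs) == 0)) {
    abort("empty sequence in FASTA", class = "spsevo_empty_seq_error")
  }
  allowed <- if (type == "dna") IUPAC_NT else c(AA_ALPHABET_21, "X", "*")
  if (aligned) allowed <- c(allowed, "-")
  chars <- unique(unlist(strsplit(seqs, "")))
  bad <- setdiff(chars, allowed)
  if (length(bad)) {
    abort(paste("illegal characters in FASTA:", paste(bad, collapse = " ")),
          class = "spsevo_alphabet_error")
  }
  if (type == "dna") seqs <- chartr("U", "T", seqs)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    abort("all sequences must be named")
  }
  if (anyDuplicated(names(seqs))) {
    abort("duplicate ids", class = "spsevo_duplicate_id_error")
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read CDS annotations from GFF3
#'
#' Imports CDS features and converts 1-based inclusive GFF3 coordinates to
#' the package's 0-based half-open convention. Minus-strand features keep
#' genomic coordinate order (`start < end`); orientation is handled
#' downstream. CDS whose length is not a multiple of 3 are flagged
#' incomplete.
#'
#' @param path GFF3 file.
#' @return Tibble with `gene_id`, `contig_id`, `start`, `end` (0-based
#'   half-open), `strand`, `phase`, `complete`.
#' @export
read_cds_annotations <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0) abort("no CDS features in GFF3")
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    abort("unknown strand symbol in GFF3", class = "spsevo_strand_error")
  }
  ids <- gr$ID
  if (is.null(ids)) ids <- gr$Name
  if (is.null(ids) || any(is.na(ids))) {
    ids <- paste0("cds", seq_along(gr))
  }
  start0 <- BiocGenerics::start(gr) - 1L
  end0 <- BiocGenerics::end(gr)
  if (any(start0 >= end0)) abort("start > end in GFF3",
                                 class = "spsevo_coord_error")
  tibble(
    gene_id = as.character(ids),
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = start0,
    end = end0,
    strand = strand,
    phase = as.integer(as.character(gr$phase)),
    complete = (end0 - start0) %% 3 == 0
  )
}

#' Write CDS annotations to GFF3
#'
#' Converts the package's 0-based half-open coordinates back to 1-based
#' inclusive GFF3.
#'
#' @param ann Tibble as returned by [read_cds_annotations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_annotations <- function(ann, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = ann$contig_id,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ann$strand
  )
  gr$type <- "CDS"
  gr$ID <- ann$gene_id
  gr$phase <- ann$phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read / write newick trees with validation
#'
#' Thin wrappers over `ape` that reject duplicate leaf labels.
#'
#' @param path Newick file.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) abort("could not parse newick", class = "spsevo_newick_error")
  if (anyDuplicated(tr$tip.label)) {
    abort("duplicate leaf labels in newick",
          class = "spsevo_duplicate_leaf_error")
  }
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0)) {
    abort("negative branch length", class = "spsevo_newick_error")
  }
  tr
}

#' @rdname read_newick
#' @param tree An `ape::phylo` tree.
#' @export
write_newick <- function(tree, path) {
  if (anyDuplicated(tree$tip.label)) {
    abort("duplicate leaf labels", class = "spsevo_duplicate_leaf_error")
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}
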