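#' Index all CpG sites of a reference genome
#'
#' Scans the forward strand of every sequence for CG dinucleotides and records
#' the 0-based position of the C. The index is strand-collapsed: a read mapping
#' to the reverse strand reports the same CpG site, because the model operates
#' on fragments, not strands. Sites containing N are excluded; matching is
#' case-insensitive.
#'
#' @param genome_fasta path to a FASTA file (an accompanying `.fai` is not
#'   required), or a [Biostrings::DNAStringSet].
#' @return object of class `cpg_index`: list with `positions` (named list of
#'   strictly increasing integer vectors, 0-based) and `seqlengths` (named
#'   integer vector).
#' @export
build_cpg_index <- function(genome_fasta) {
  seqs <- if (inherits(genome_fasta, "DNAStringSet")) genome_fasta
          else Biostrings::readDNAStringSet(genome_fasta)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyNA(nm) || any(nm == "")) stop("FASTA with missing sequence names")
  if (anyDuplicated(nm)) stop("duplicate chromosome names in FASTA")
  names(seqs) <- nm
  pos <- lapply(seq_along(seqs), function(i) {
    m <- Biostrings::matchPattern("CG", seqs[[i]], fixed = TRUE)
    as.integer(BiocGenerics::start(m) - 1L)  # 0-based C position
  })
  names(pos) <- nm
  structure(list(positions = pos,
                 seqlengths = setNames(Biostrings::width(seqs), nm)),
            class = "cpg_index")
}

#' @export
print.cpg_index <- function(x, ...) {
  cat(sprintf("CpG index: %d sequence(s), %d CpG sites\n",
              length(x$positions), sum(lengths(x$positions))))
  invisible(x)
}
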