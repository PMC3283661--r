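# Genome assembly I/O and queries.
#
# A genome assembly is represented as a named Biostrings::DNAStringSet, one
# entry per linkage group (LG), in file order. IUPAC ambiguity codes are
# retained (the reference-ambiguity filter rule needs them) but sequences
# are upper-cased on read.

#' Read a genome assembly from FASTA
#'
#' One linkage group per FASTA record; record order is preserved and names
#' are truncated at the first whitespace. Sequences are upper-cased; IUPAC
#' ambiguity codes other than A/C/G/T are retained.
#'
#' @param path path to a FASTA file.
#' @return a named [Biostrings::DNAStringSet], one element per linkage group.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) abort("genome FASTA not found: %s", path)
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    abort("duplicate linkage-group names in %s", path)
  if (any(Biostrings::width(seqs) == 0))
    abort("empty sequence record in %s", path)
  Biostrings::DNAStringSet(toupper(as.character(seqs)))
}

#' Write a genome assembly to FASTA
#'
#' @param genome a named `DNAStringSet` (or named character vector).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Linkage-group lengths of an assembly
#'
#' @param genome a named `DNAStringSet`.
#' @return named integer vector of sequence lengths (bp).
#' @export
lg_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

# 1-based positions of non-ACGT bases, per linkage group
ambiguity_positions <- function(genome) {
  chars <- as.character(genome)
  out <- lapply(chars, function(s) {
    m <- gregexpr("[^ACGT]", s)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m)
  })
  names(out) <- names(genome)
  out
}
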