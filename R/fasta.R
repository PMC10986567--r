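#' Read a genome assembly from FASTA
#'
#' Sequences are uppercased and RNA `U` is normalised to `T`. Record ids are
#' taken up to the first whitespace. Duplicate ids, empty sequences, and
#' ambiguity codes other than `N` are errors.
#'
#' @param path FASTA file.
#' @param tag Assembly tag; defaults to the file name without extension.
#' @param mito Contig ids to flag as mitochondrial.
#' @return A `genome_assembly`.
#' @export
read_fasta <- function(path, tag = NULL,
                       mito = character()) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop(sprintf("no records in %s", path))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  names(seqs) <- ids
  new_assembly(seqs,
               tag = tag %||% sub("\\.(fa|fasta|fna)$", "", basename(path)),
               source = path, mito = mito)
}

#' Write a genome assembly to FASTA
#'
#' Records are wrapped at 60 columns.
#'
#' @param assembly A `genome_assembly`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(assembly, path) {
  set <- Biostrings::DNAStringSet(assembly$contigs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Write arbitrary named sequences (e.g. proteins or alignments) to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_seqs_fasta <- function(seqs, path, width = 60L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
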