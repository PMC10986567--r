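#' Construct a genome assembly
#'
#' A genome assembly is a named, tagged collection of contig sequences.
#' Sequences are stored uppercase over the alphabet `{A,C,G,T,N}`; other
#' ambiguity codes are rejected because the downstream codon tests assume
#' unambiguous bases (or N).
#'
#' @param contigs Named character vector of DNA sequences; names are contig
#'   ids and must be unique and non-empty.
#' @param tag Short assembly identifier (the 4-5 character genome tag used
#'   throughout family tables and reports).
#' @param source Free-text provenance.
#' @param mito Character vector of contig ids designated mitochondrial.
#'   Gene models on these contigs are translated with the yeast
#'   mitochondrial code (transl_table 3).
#' @return An object of class `genome_assembly`.
#' @export
new_assembly <- function(contigs, tag = "ASM1", source = "", mito = character()) {
  if (!is.character(contigs) || length(contigs) == 0)
    stop("'contigs' must be a non-empty named character vector")
  ids <- names(contigs)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("every contig needs a non-empty id")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate contig id: %s", ids[duplicated(ids)][1]))
  contigs[] <- toupper(chartr("u", "t", contigs))
  contigs[] <- chartr("U", "T", contigs)
  if (any(nchar(contigs) == 0))
    stop(sprintf("empty sequence for contig '%s'", ids[nchar(contigs) == 0][1]))
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad))
    stop(sprintf("contig '%s' contains characters outside {A,C,G,T,N}",
                 ids[bad][1]))
  if (!all(mito %in% ids))
    stop("'mito' names a contig that is not in the assembly")
  structure(list(tag = tag, contigs = contigs, source = source, mito = mito),
            class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  st <- assembly_stats(x)
  cat(sprintf("genome_assembly '%s': %d contigs, %s bp, N50 %s bp\n",
              x$tag, st$n_contigs, format(st$genome_size, big.mark = ","),
              format(st$n50, big.mark = ",")))
  invisible(x)
}

#' Total assembly length in bp
#' @param assembly A `genome_assembly`.
#' @return Integer genome size.
#' @export
genome_size <- function(assembly) sum(nchar(assembly$contigs))

#' Contig N50
#'
#' The N50 is the contig length L such that contigs of length >= L cover at
#' least half the genome.
#'
#' @param lengths Integer vector of contig lengths.
#' @return The N50 length.
#' @export
calc_n50 <- function(lengths) {
  if (length(lengths) == 0) stop("no contig lengths given")
  s <- sort(lengths, decreasing = TRUE)
  unname(s[which(cumsum(as.numeric(s)) >= sum(as.numeric(s)) / 2)[1]])
}

#' Basic assembly statistics
#'
#' @param assembly A `genome_assembly`.
#' @return A list with `n_contigs`, `genome_size`, `n50` and
#'   `mean_contig_length`.
#' @export
assembly_stats <- function(assembly) {
  len <- nchar(assembly$contigs)
  list(n_contigs = length(len),
       genome_size = sum(len),
       n50 = calc_n50(len),
       mean_contig_length = sum(len) / length(len))
}

# reverse complement of a plain character DNA string
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
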