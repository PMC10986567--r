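# Gene models are kept in a data.frame with one row per model and a
# `segments` list-column: each element is an integer matrix with columns
# (start, end), 1-based inclusive, rows in transcription order (descending
# start for minus-strand models). `start`/`end` columns hold the genomic
# span. `origin` is one of reference/blastn/maker, `status` one of
# complete/candidate/discarded_no_codon/discarded_pseudo. `parent` carries
# the reference model id for transferred (blastn) models.

#' Construct a gene-model table
#'
#' @param id,contig,strand Character vectors (strand in `+`/`-`).
#' @param segments List of integer matrices with columns (start, end),
#'   1-based inclusive, in transcription order.
#' @param code_id Integer translation-table id per model (1 or 3).
#' @param origin `"reference"`, `"blastn"` or `"maker"`.
#' @param status Model status; `"complete"` for finished models.
#' @param parent Reference model id for transferred models, else `NA`.
#' @param pseudo Logical pseudogene flag (set by [read_gff()] for
#'   `pseudogene`-typed reference features).
#' @return A data.frame of class `gene_models`.
#' @export
new_gene_models <- function(id, contig, strand, segments, code_id = 1L,
                            origin = "reference", status = "complete",
                            parent = NA_character_, pseudo = FALSE) {
  n <- length(id)
  if (anyDuplicated(id)) stop("duplicate model id")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  segments <- lapply(segments, function(m) {
    m <- matrix(as.integer(m), ncol = 2,
                dimnames = list(NULL, c("start", "end")))
    if (any(m[, "end"] < m[, "start"])) stop("segment end before start")
    m
  })
  df <- data.frame(id = id, contig = contig, strand = strand,
                   start = vapply(segments, function(m) min(m[, "start"]), 1L),
                   end = vapply(segments, function(m) max(m[, "end"]), 1L),
                   code_id = rep_len(as.integer(code_id), n),
                   origin = rep_len(origin, n),
                   status = rep_len(status, n),
                   parent = rep_len(parent, n),
                   pseudo = rep_len(pseudo, n),
                   stringsAsFactors = FALSE)
  df$segments <- segments
  class(df) <- c("gene_models", "data.frame")
  df
}

empty_gene_models <- function() {
  new_gene_models(character(0), character(0), character(0), list())
}

#' Bind gene-model tables
#' @param ... `gene_models` objects.
#' @return A combined `gene_models` table.
#' @export
bind_models <- function(...) {
  parts <- Filter(function(x) nrow(x) > 0, list(...))
  if (length(parts) == 0) return(empty_gene_models())
  out <- do.call(rbind, lapply(parts, function(x) { class(x) <- "data.frame"; x }))
  rownames(out) <- NULL
  if (anyDuplicated(out$id)) stop("duplicate model id after binding")
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Total coding length (bp) of each model
#' @param models A `gene_models` table.
#' @return Integer vector of summed CDS segment lengths.
#' @export
model_cds_length <- function(models) {
  vapply(models$segments,
         function(m) sum(m[, "end"] - m[, "start"] + 1L), 1L)
}

#' Extract the spliced coding sequence of one model
#'
#' Segments are concatenated in transcription order; minus-strand models are
#' reverse-complemented.
#'
#' @param assembly The `genome_assembly` the model lies on.
#' @param model One-row `gene_models` table (or a list with the same fields).
#' @return DNA string of the CDS.
#' @export
model_cds <- function(assembly, model) {
  seq <- assembly$contigs[[model$contig]]
  if (is.null(seq)) stop(sprintf("model '%s' references unknown contig '%s'",
                                 model$id, model$contig))
  segs <- if (is.list(model$segments) && is.matrix(model$segments[[1]]))
    model$segments[[1]] else model$segments
  parts <- substring(seq, segs[, "start"], segs[, "end"])
  if (model$strand == "+") paste(parts, collapse = "")
  else paste(vapply(parts, revcomp, ""), collapse = "")
}

#' Translate every model of an assembly into a protein table
#'
#' The trailing stop codon is not part of the protein. Models whose
#' translation fails the complete-model contract are reported with the
#' failure rather than silently dropped.
#'
#' @param models A `gene_models` table (status `complete`).
#' @param assembly The assembly the models lie on.
#' @param tag Genome tag recorded per protein; defaults to `assembly$tag`.
#' @return A data.frame (`protein_set`) with columns id, tag, seq, length,
#'   origin, parent.
#' @export
model_proteins <- function(models, assembly, tag = assembly$tag) {
  if (nrow(models) == 0)
    return(data.frame(id = character(0), tag = character(0),
                      seq = character(0), length = integer(0),
                      origin = character(0), parent = character(0),
                      stringsAsFactors = FALSE))
  seqs <- vapply(seq_len(nrow(models)), function(i) {
    tr <- translate_cds(model_cds(assembly, models[i, ]),
                        models$code_id[i])
    if (tr$internal_stop)
      stop(sprintf("model '%s' has an internal stop codon", models$id[i]))
    tr$protein
  }, "")
  data.frame(id = models$id, tag = tag, seq = seqs, length = nchar(seqs),
             origin = models$origin, parent = models$parent,
             stringsAsFactors = FALSE)
}
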