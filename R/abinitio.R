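# Step 2 of the pipeline: gene prediction on the masked assembly. The
# external-predictor route (MAKER-style GFF3) is an adapter; the internal
# fallback is a six-frame ORF caller so the two-step architecture is fully
# testable offline. The reference-database reduction and the short-model
# filter are the pipeline's own computations.

#' Reduce a protein reference database
#'
#' Non-reference proteins highly similar to a reference homolog (identity,
#' query coverage and subject coverage all at or above their thresholds
#' simultaneously) are excluded; all reference proteins are kept.
#'
#' @param s288c Reference protein set (data.frame with `id`, `seq`).
#' @param others Non-reference protein set.
#' @param id_cut Identity threshold in percent (default 70).
#' @param qcov Query-coverage threshold; the query is the non-reference
#'   protein.
#' @param scov Subject-coverage threshold; the subject is the reference
#'   protein.
#' @return Combined data.frame of retained proteins.
#' @export
reduce_protein_db <- function(s288c, others, id_cut = 70, qcov = 95,
                              scov = 95) {
  if (nrow(s288c) == 0 || nrow(others) == 0)
    stop("both protein sets must be non-empty")
  edges <- pairwise_search(others, s288c)
  drop <- unique(edges$a[edges$identity >= id_cut &
                         edges$a_cov >= qcov & edges$b_cov >= scov])
  rbind(s288c, others[!others$id %in% drop, , drop = FALSE])
}

# ORF scan of one frame of one strand; codons containing N act as barriers
# (ORFs never overlap masked positions), as do stop codons and sequence ends
.orfs_in_frame <- function(codons, code) {
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  has_n <- grepl("N", codons, fixed = TRUE)
  is_stop <- aa == "*" & !has_n
  barrier <- which(is_stop | has_n)
  is_atg <- codons == "ATG"
  out <- list()
  prev <- 0L
  for (b in barrier) {
    if (is_stop[b]) {
      cand <- which(is_atg[(prev + 1L):(b - 1L)])
      if (length(cand)) {
        atg <- prev + cand[1]
        out[[length(out) + 1L]] <- c(atg = atg, stop = b)
      }
    }
    prev <- b
  }
  out
}

#' Predict ORFs on unmasked regions (internal step-2 fallback)
#'
#' Scans all six frames for `ATG`...stop open reading frames that do not
#' overlap any `N` position. Nested ORFs sharing a stop codon are resolved
#' to the longest. Models on contigs flagged mitochondrial use translation
#' table 3.
#'
#' @param masked A (typically masked) `genome_assembly`.
#' @param min_orf_len_aa Minimum protein length in amino acids (default 15,
#'   matching the downstream short-model filter).
#' @param id_prefix Prefix for model ids.
#' @return A `gene_models` table with origin `"maker"`.
#' @export
predict_orfs <- function(masked, min_orf_len_aa = 15L, id_prefix = NULL) {
  id_prefix <- id_prefix %||% masked$tag
  rows <- list()
  n <- 0L
  for (cn in names(masked$contigs)) {
    code_id <- if (cn %in% masked$mito) 3L else 1L
    code <- genetic_code(code_id)
    fwd <- masked$contigs[[cn]]
    L <- nchar(fwd)
    for (strand in c("+", "-")) {
      seq <- if (strand == "+") fwd else revcomp(fwd)
      for (frame in 0:2) {
        nc <- (L - frame) %/% 3L
        if (nc < min_orf_len_aa + 1L) next
        starts <- seq(frame + 1L, by = 3L, length.out = nc)
        codons <- substring(seq, starts, starts + 2L)
        for (orf in .orfs_in_frame(codons, code)) {
          aa_len <- orf[["stop"]] - orf[["atg"]]
          if (aa_len < min_orf_len_aa) next
          a <- starts[orf[["atg"]]]            # first base, scan coords
          b <- starts[orf[["stop"]]] + 2L      # last base of stop codon
          if (strand == "-") { tmp <- a; a <- L - b + 1L; b <- L - tmp + 1L }
          n <- n + 1L
          rows[[n]] <- list(id = sprintf("%s_m%04d", id_prefix, n),
                            contig = cn, strand = strand,
                            seg = c(a, b), code_id = code_id)
        }
      }
    }
  }
  if (!length(rows)) return(empty_gene_models())
  new_gene_models(
    id = vapply(rows, `[[`, "", "id"),
    contig = vapply(rows, `[[`, "", "contig"),
    strand = vapply(rows, `[[`, "", "strand"),
    segments = lapply(rows, function(r) matrix(r$seg, ncol = 2)),
    code_id = vapply(rows, `[[`, 1L, "code_id"),
    origin = "maker", status = "complete")
}

#' Remove too-short models
#'
#' Models with a protein shorter than `min_len` amino acids (strictly) are
#' removed; a model of exactly `min_len` is kept. Protein length is the
#' coding length over 3 minus the stop codon.
#'
#' @param models A `gene_models` table.
#' @param min_len Minimum protein length in aa (default 15).
#' @return The filtered table.
#' @export
filter_short <- function(models, min_len = 15L) {
  if (nrow(models) == 0) return(models)
  aa_len <- model_cds_length(models) %/% 3L - 1L
  out <- models[aa_len >= min_len, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Pool blastn-models and maker-models into the final model set
#'
#' The union is returned unchanged (no deduplication); overlapping
#' blastn/maker models trigger a warning but both are kept. The maker-model
#' ratio (maker count over total) is attached as attribute `maker_ratio`
#' (percent).
#'
#' @param blastn_models,maker_models `gene_models` tables.
#' @return Combined `gene_models` with attribute `maker_ratio`.
#' @export
merge_models <- function(blastn_models, maker_models) {
  out <- bind_models(blastn_models, maker_models)
  if (nrow(blastn_models) > 0 && nrow(maker_models) > 0) {
    for (cn in intersect(blastn_models$contig, maker_models$contig)) {
      b <- blastn_models[blastn_models$contig == cn, ]
      k <- maker_models[maker_models$contig == cn, ]
      if (any(outer(b$start, k$end, `<=`) & outer(b$end, k$start, `>=`))) {
        warning(sprintf("overlapping blastn/maker models on contig '%s'", cn))
        break
      }
    }
  }
  attr(out, "maker_ratio") <-
    if (nrow(out) == 0) 0 else 100 * nrow(maker_models) / nrow(out)
  out
}

#' Read external predictor output (adapter contract)
#'
#' Ingests GFF3 produced by an external gene predictor (e.g. a MAKER run)
#' as maker-models. Coordinates must be on the same assembly that was
#' masked, so they need no translation.
#'
#' @param gff_path GFF3 file from the predictor.
#' @param assembly The (masked) `genome_assembly` the predictions refer to.
#' @return A `gene_models` table with origin `"maker"`.
#' @export
read_external_predictions <- function(gff_path, assembly) {
  read_gff(gff_path, assembly, origin = "maker")
}
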