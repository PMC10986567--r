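# Pipeline orchestration: the three annotation modes and the
# self-annotation benchmark.

#' Annotate a query genome with the two-step pipeline
#'
#' `"full"` runs homology transfer (step 1) followed by ORF prediction on
#' the masked assembly (step 2); `"step1"` stops after the transfer;
#' `"step2"` runs prediction on the unmasked assembly only. The final model
#' set pools blastn-models and maker-models without deduplication.
#'
#' @param query,reference `genome_assembly` objects.
#' @param ref_models Reference `gene_models` (pseudogenes are dropped).
#' @param mode `"full"`, `"step1"` or `"step2"`.
#' @param min_block_len,min_identity,k,window Step-1 parameters, see
#'   [annotate_step1()].
#' @param min_orf_len_aa Step-2 minimum protein length (also the
#'   short-model filter threshold).
#' @param external_gff Optional GFF3 from an external predictor used in
#'   place of the internal ORF caller for step 2.
#' @return List with `models` (final `gene_models`, `maker_ratio`
#'   attribute set), `blastn_models`, `maker_models`, `masked`, `log`.
#' @export
annotate_genome <- function(query, reference, ref_models,
                            mode = c("full", "step1", "step2"),
                            min_block_len = 100L, min_identity = 90,
                            k = 13L, window = 300L, min_orf_len_aa = 15L,
                            external_gff = NULL) {
  mode <- match.arg(mode)
  blastn <- empty_gene_models()
  masked <- query
  log <- NULL
  if (mode %in% c("full", "step1")) {
    s1 <- annotate_step1(query, reference, ref_models,
                         min_block_len = min_block_len,
                         min_identity = min_identity, k = k, window = window)
    blastn <- s1$models
    masked <- s1$masked
    log <- s1$log
  }
  maker <- empty_gene_models()
  if (mode %in% c("full", "step2")) {
    target <- if (mode == "full") masked else query
    maker <- if (is.null(external_gff))
      predict_orfs(target, min_orf_len_aa = min_orf_len_aa)
    else read_external_predictions(external_gff, target)
    maker <- filter_short(maker, min_len = min_orf_len_aa)
  }
  models <- merge_models(blastn, maker)
  list(models = models, blastn_models = blastn, maker_models = maker,
       masked = masked, log = log)
}

#' Benchmark the pipeline by self-annotation of an annotated reference
#'
#' The reference is annotated against itself in the requested mode and the
#' produced models are compared with the reference models. A model is an
#' exact recovery when contig, strand and all segment coordinates match.
#'
#' @param reference A `genome_assembly` annotated by `ref_models`.
#' @param ref_models Pseudogene-free reference `gene_models`.
#' @param mode Annotation mode, see [annotate_genome()].
#' @param ... Further arguments to [annotate_genome()].
#' @return List with `recall`, `precision_by_count`, `precision_by_length`
#'   (percent), `n_reference`, `n_produced`, and the annotation `result`.
#' @export
run_benchmark <- function(reference, ref_models, mode = "step1", ...) {
  ref_models <- drop_pseudogenes(ref_models)
  res <- annotate_genome(reference, reference, ref_models, mode = mode, ...)
  key <- function(models) {
    vapply(seq_len(nrow(models)), function(i)
      paste(models$contig[i], models$strand[i],
            paste(t(models$segments[[i]]), collapse = ","), sep = ":"), "")
  }
  ref_keys <- key(ref_models)
  got_keys <- if (nrow(res$models)) key(res$models) else character(0)
  recovered <- ref_keys %in% got_keys
  matching <- got_keys %in% ref_keys
  ref_len <- model_cds_length(ref_models)
  got_len <- if (nrow(res$models)) model_cds_length(res$models) else integer(0)
  list(recall = 100 * mean(recovered),
       precision_by_count = if (length(got_keys)) 100 * mean(matching) else NA_real_,
       precision_by_length = if (length(got_keys))
         100 * sum(got_len[matching]) / sum(got_len) else NA_real_,
       n_reference = nrow(ref_models), n_produced = nrow(res$models),
       result = res)
}
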