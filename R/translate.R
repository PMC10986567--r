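# Genetic code handling. Code ids follow NCBI transl_table numbering:
# 1 = standard, 3 = yeast mitochondrial (CTN -> Thr, ATA -> Met, TGA -> Trp).

.code_env <- new.env(parent = emptyenv())

#' Genetic code table
#'
#' Returns the codon -> amino-acid map for an NCBI translation table, as
#' provided by Biostrings. Stop codons are `"*"`.
#'
#' @param code_id 1 (standard) or 3 (yeast mitochondrial).
#' @return Named character vector over the 64 codons.
#' @export
genetic_code <- function(code_id) {
  key <- as.character(code_id)
  if (!key %in% c("1", "3"))
    stop(sprintf("unsupported genetic code id: %s", key))
  if (is.null(.code_env[[key]]))
    .code_env[[key]] <- Biostrings::getGeneticCode(key)
  .code_env[[key]]
}

#' Stop codons of a genetic code
#' @param code_id Translation table id.
#' @return Character vector of stop codons.
#' @export
stop_codons <- function(code_id) {
  code <- genetic_code(code_id)
  names(code)[code == "*"]
}

#' Translate a coding sequence
#'
#' Translation proceeds codon by codon and stops at the first stop codon.
#' Codons containing `N` translate to `X`. The flags report whether a stop
#' codon was reached (`stop_terminated`) and whether it occurred before the
#' final codon (`internal_stop`).
#'
#' @param cds DNA string; length must be >= 3. With `complete = TRUE`
#'   (default) a length not divisible by 3 is an error.
#' @param code_id Translation table id (1 or 3).
#' @param complete Enforce the complete-model contract (length divisible
#'   by 3).
#' @return List with `protein`, `stop_terminated`, `internal_stop`.
#' @export
translate_cds <- function(cds, code_id = 1, complete = TRUE) {
  n <- nchar(cds)
  if (n < 3) stop("coding sequence shorter than one codon")
  if (complete && n %% 3 != 0)
    stop(sprintf("coding length %d not divisible by 3", n))
  code <- genetic_code(code_id)
  nc <- n %/% 3
  codons <- substring(cds, seq(1L, by = 3L, length.out = nc),
                      seq(3L, by = 3L, length.out = nc))
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  stop_idx <- which(aa == "*")
  if (length(stop_idx) == 0) {
    return(list(protein = paste(aa, collapse = ""),
                stop_terminated = FALSE, internal_stop = FALSE))
  }
  first <- stop_idx[1]
  list(protein = paste(aa[seq_len(first - 1L)], collapse = ""),
       stop_terminated = TRUE,
       internal_stop = first < nc)
}
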