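# Step 1 of the annotation pipeline: transfer reference gene models onto a
# query assembly through whole-genome alignment blocks, repair start/stop
# codons, discard pseudogenised copies, and mask the annotated regions.

# O(1) reference-position -> column-index lookup for one block
.block_rindex <- function(block) {
  idx <- integer(block$r_end)
  ok <- !is.na(block$r_col)
  idx[block$r_col[ok]] <- which(ok)
  idx
}

#' Transfer reference models through alignment blocks
#'
#' A model is transferred iff some single block fully covers its reference
#' span and the alignment columns over that span contain no insertion or
#' deletion. Mapped coordinates follow the block's column correspondence and
#' the model strand is composed with the block strand. A reference model may
#' yield candidates at several distinct query loci (duplicated regions); at
#' one locus only the best-identity block is used (ties: longer block, then
#' lexicographic query contig).
#'
#' @param blocks `alignment_blocks` from [align_genomes()].
#' @param ref_models Reference `gene_models`, pseudogene-free (see
#'   [drop_pseudogenes()]); an error is raised if a `pseudo` model slips in.
#' @param query The query `genome_assembly`.
#' @return A `gene_models` table of candidates (status `"candidate"`,
#'   origin `"blastn"`, `parent` = reference model id).
#' @export
transfer_models <- function(blocks, ref_models, query) {
  if (any(ref_models$pseudo))
    stop("ref_models must exclude pseudogene-flagged entries")
  rindex <- lapply(blocks, .block_rindex)
  out <- list()
  for (i in seq_len(nrow(ref_models))) {
    m <- ref_models[i, ]
    cands <- list()
    for (b in seq_along(blocks)) {
      bl <- blocks[[b]]
      if (bl$r_contig != m$contig || bl$r_start > m$start || bl$r_end < m$end)
        next
      ridx <- rindex[[b]]
      i0 <- ridx[m$start]; i1 <- ridx[m$end]
      if (i0 == 0L || i1 == 0L) next
      span <- bl$r_col[i0:i1]
      qspan <- bl$q_col[i0:i1]
      if (anyNA(span) || anyNA(qspan)) next      # indel inside the span
      segs <- m$segments[[1]]
      qsegs <- matrix(0L, nrow = nrow(segs), ncol = 2,
                      dimnames = list(NULL, c("start", "end")))
      bad <- FALSE
      for (s in seq_len(nrow(segs))) {
        qa <- bl$q_col[ridx[segs[s, "start"]]]
        qb <- bl$q_col[ridx[segs[s, "end"]]]
        if (is.na(qa) || is.na(qb)) { bad <- TRUE; break }
        qsegs[s, ] <- sort(c(qa, qb))
      }
      if (bad) next
      strand <- if (bl$strand == "+") m$strand else setdiff(c("+", "-"), m$strand)
      # keep transcription order: re-sort segments along transcription
      ord <- order(qsegs[, "start"], decreasing = (strand == "-"))
      qsegs <- qsegs[ord, , drop = FALSE]
      cands[[length(cands) + 1L]] <- list(
        contig = bl$q_contig, strand = strand, segments = qsegs,
        identity = bl$identity,
        block_len = bl$r_end - bl$r_start + 1L)
    }
    if (!length(cands)) next
    # group candidates into query loci (same contig, overlapping span)
    loci <- list()
    for (cd in cands) {
      placed <- FALSE
      for (l in seq_along(loci)) {
        ref <- loci[[l]][[1]]
        if (ref$contig == cd$contig &&
            min(cd$segments[, "start"]) <= max(ref$segments[, "end"]) &&
            max(cd$segments[, "end"]) >= min(ref$segments[, "start"])) {
          loci[[l]] <- c(loci[[l]], list(cd)); placed <- TRUE; break
        }
      }
      if (!placed) loci[[length(loci) + 1L]] <- list(cd)
    }
    copy <- 0L
    for (l in seq_along(loci)) {
      grp <- loci[[l]]
      pick <- order(-vapply(grp, `[[`, 0, "identity"),
                    -vapply(grp, `[[`, 0, "block_len"),
                    vapply(grp, `[[`, "", "contig"))[1]
      cd <- grp[[pick]]
      copy <- copy + 1L
      out[[length(out) + 1L]] <- list(
        id = if (copy == 1L) paste0(query$tag, "_", m$id)
             else sprintf("%s_%s.%d", query$tag, m$id, copy),
        contig = cd$contig, strand = cd$strand, segments = cd$segments,
        code_id = m$code_id, parent = m$id)
    }
  }
  if (!length(out)) return(empty_gene_models())
  new_gene_models(
    id = vapply(out, `[[`, "", "id"),
    contig = vapply(out, `[[`, "", "contig"),
    strand = vapply(out, `[[`, "", "strand"),
    segments = lapply(out, `[[`, "segments"),
    code_id = vapply(out, `[[`, 1L, "code_id"),
    origin = "blastn", status = "candidate",
    parent = vapply(out, `[[`, "", "parent"))
}

#' Repair start and stop codons of a transferred candidate model
#'
#' Mirrors the transfer pipeline's codon inspection: a mutated stop codon is
#' repaired by extending downstream (in frame, within `window` bp) to the
#' first stop codon; a mutated start codon by scanning upstream in frame for
#' the first ATG (aborting at an in-frame stop or the contig edge), then
#' downstream within the model. A model that cannot be repaired is
#' discarded (`discarded_no_codon`); a repaired model with a stop codon in
#' its interior is discarded as a pseudogene (`discarded_pseudo`).
#'
#' The window bounds the distance between the first base of the original
#' codon and the first base of its replacement. Start codons are ATG only.
#'
#' @param candidate One-row `gene_models` table (status `"candidate"`).
#' @param query The query `genome_assembly`.
#' @param window Scan window in nucleotides (default 300).
#' @return A list with `model` (one-row `gene_models`, status updated),
#'   `status`, and `log` (character vector of repair actions).
#' @export
repair_model <- function(candidate, query, window = 300L) {
  m <- as.list(candidate[1, ])
  m$segments <- candidate$segments[[1]]
  seq <- query$contigs[[m$contig]]
  L <- nchar(seq)
  stops <- stop_codons(m$code_id)
  dirn <- if (m$strand == "+") 1L else -1L
  codon_at <- function(p) {
    # p = genomic position of the codon's first base in transcription order
    if (m$strand == "+") {
      if (p < 1L || p + 2L > L) return(NA_character_)
      substr(seq, p, p + 2L)
    } else {
      if (p - 2L < 1L || p > L) return(NA_character_)
      revcomp(substr(seq, p - 2L, p))
    }
  }
  segs <- m$segments
  nseg <- nrow(segs)
  log <- character(0)
  fail <- function(status) {
    cand <- candidate
    cand$status <- status
    list(model = cand, status = status, log = log)
  }

  # --- stop codon ---
  stop_pos <- if (m$strand == "+") segs[nseg, "end"] - 2L else segs[nseg, "start"] + 2L
  if (!isTRUE(codon_at(stop_pos) %in% stops)) {
    shift <- NA_integer_
    for (s in seq(3L, window, 3L)) {
      cd <- codon_at(stop_pos + dirn * s)
      if (is.na(cd)) break
      if (cd %in% stops) { shift <- s; break }
    }
    if (is.na(shift)) return(fail("discarded_no_codon"))
    if (m$strand == "+") segs[nseg, "end"] <- segs[nseg, "end"] + shift
    else segs[nseg, "start"] <- segs[nseg, "start"] - shift
    log <- c(log, sprintf("stop_shift+%d", shift))
  }

  # --- start codon ---
  start_pos <- if (m$strand == "+") segs[1, "start"] else segs[1, "end"]
  if (!identical(codon_at(start_pos), "ATG")) {
    shift <- NA_integer_
    for (s in seq(3L, window, 3L)) {           # upstream scan
      cd <- codon_at(start_pos - dirn * s)
      if (is.na(cd) || cd %in% stops) break    # contig edge / in-frame stop
      if (cd == "ATG") { shift <- -s; break }
    }
    if (is.na(shift)) {                         # downstream scan
      cds_len <- sum(segs[, "end"] - segs[, "start"] + 1L)
      for (s in seq(3L, min(window, cds_len - 6L), 3L)) {
        cd <- codon_at(start_pos + dirn * s)
        if (is.na(cd)) break
        if (cd == "ATG") { shift <- s; break }
      }
    }
    if (is.na(shift)) return(fail("discarded_no_codon"))
    if (m$strand == "+") segs[1, "start"] <- segs[1, "start"] + shift
    else segs[1, "end"] <- segs[1, "end"] - shift
    log <- c(log, sprintf("start_shift%+d", shift))
  }

  # --- internal stop check on the repaired model ---
  repaired <- new_gene_models(
    id = m$id, contig = m$contig, strand = m$strand,
    segments = list(segs), code_id = m$code_id,
    origin = "blastn", status = "complete", parent = m$parent)
  tr <- translate_cds(model_cds(query, repaired[1, ]), m$code_id)
  if (tr$internal_stop) {
    repaired$status <- "discarded_pseudo"
    return(list(model = repaired, status = "discarded_pseudo", log = log))
  }
  if (!tr$stop_terminated) return(fail("discarded_no_codon"))
  list(model = repaired, status = "complete", log = log)
}

#' Mask annotated regions with N
#'
#' Every position covered by a kept model segment is replaced by `N`;
#' lengths and all other positions are unchanged.
#'
#' @param query A `genome_assembly`.
#' @param models `gene_models` whose segments are to be masked.
#' @return The masked `genome_assembly`.
#' @export
mask_regions <- function(query, models) {
  if (nrow(models) == 0) return(query)
  out <- query
  for (cn in unique(models$contig)) {
    seq <- out$contigs[[cn]]
    if (is.null(seq)) stop(sprintf("model on unknown contig '%s'", cn))
    raw <- charToRaw(seq)
    rows <- which(models$contig == cn)
    for (i in rows) {
      segs <- models$segments[[i]]
      for (s in seq_len(nrow(segs))) {
        if (segs[s, "end"] > length(raw)) stop("model extends past contig end")
        raw[segs[s, "start"]:segs[s, "end"]] <- charToRaw("N")
      }
    }
    out$contigs[[cn]] <- rawToChar(raw)
  }
  out
}

#' Homology-transfer annotation (step 1)
#'
#' Composes alignment, model transfer, codon repair and masking. Candidates
#' mapping to identical query coordinates (e.g. through overlapping blocks)
#' are reported once. Discarded candidates are logged with their reason.
#'
#' @param query,reference `genome_assembly` objects.
#' @param ref_models Reference `gene_models`; pseudogene-flagged entries are
#'   dropped automatically.
#' @param min_block_len,min_identity,k Passed to [align_genomes()].
#' @param window Repair window, see [repair_model()].
#' @param blocks Optional precomputed `alignment_blocks` (e.g. from an
#'   external aligner adapter); skips the internal alignment.
#' @return List with `models` (kept blastn models), `masked` (the masked
#'   assembly), `log` (data.frame: candidate id, parent, status, actions).
#' @export
annotate_step1 <- function(query, reference, ref_models,
                           min_block_len = 100L, min_identity = 90,
                           k = 13L, window = 300L, blocks = NULL) {
  ref_models <- drop_pseudogenes(ref_models)
  if (is.null(blocks))
    blocks <- align_genomes(query, reference, min_block_len = min_block_len,
                            min_identity = min_identity, k = k)
  cands <- transfer_models(blocks, ref_models, query)
  kept <- list()
  log <- list()
  seen <- character(0)
  for (i in seq_len(nrow(cands))) {
    rep <- repair_model(cands[i, ], query, window = window)
    key <- paste(rep$model$contig[1], rep$model$strand[1],
                 paste(rep$model$segments[[1]], collapse = ","), sep = ":")
    dupe <- rep$status == "complete" && key %in% seen
    log[[i]] <- data.frame(id = cands$id[i], parent = cands$parent[i],
                           status = if (dupe) "duplicate_locus" else rep$status,
                           actions = paste(rep$log, collapse = ";"),
                           stringsAsFactors = FALSE)
    if (rep$status == "complete" && !dupe) {
      seen <- c(seen, key)
      kept[[length(kept) + 1L]] <- rep$model
    }
  }
  models <- if (length(kept)) do.call(bind_models, kept) else empty_gene_models()
  list(models = models,
       masked = mask_regions(query, models),
       log = if (length(log)) do.call(rbind, log) else
         data.frame(id = character(0), parent = character(0),
                    status = character(0), actions = character(0)))
}
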