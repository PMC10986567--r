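# Synthetic genome simulator. Generates a compact intronless reference
# genome with known single-exon gene models, and query assemblies derived
# from it by substitutions, short indels, contig fragmentation and optional
# whole-genome duplication, together with a ground-truth record of every
# edit. These fixtures stand in for real assemblies in all offline tests.

.sample_codons <- function(n, code_id) {
  code <- genetic_code(code_id)
  pool <- names(code)[code != "*"]
  sample(pool, n, replace = TRUE)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.random_gene <- function(aa_len, code_id) {
  stop_pool <- stop_codons(code_id)
  paste0("ATG",
         paste(.sample_codons(aa_len - 1L, code_id), collapse = ""),
         sample(stop_pool, 1))
}

#' Generate a synthetic reference genome with known gene models
#'
#' Genes are single-exon (the yeast genome is predominantly intronless),
#' start with ATG, end with a stop codon of their translation table, and
#' contain no internal stop. Both strands are used. Genes are separated by
#' fixed-length random intergenic spacers and distributed evenly over
#' `n_contigs` contigs. With `mito = TRUE` one extra small contig is flagged
#' mitochondrial and carries genes using translation table 3.
#'
#' @param n_genes Number of nuclear genes (>= 1).
#' @param mean_gene_len Mean gene length in bp including start and stop
#'   codons; actual lengths are drawn uniformly within +/-20%. The default
#'   1,470 bp mirrors the mean length of the S288c reference models.
#' @param intergenic_len Spacer length in bp between genes and at contig
#'   ends.
#' @param n_contigs Number of nuclear contigs.
#' @param mito Add a mitochondrial contig with 3 code-3 genes.
#' @param n_mito_genes Number of genes on the mitochondrial contig.
#' @param seed Integer seed; the same seed reproduces the genome exactly.
#' @return List with `assembly` (a `genome_assembly`, tag `"SREF"`) and
#'   `models` (a `gene_models` table, ids `g0001`...).
#' @export
make_reference <- function(n_genes = 200L, mean_gene_len = 1470L,
                           intergenic_len = 300L, n_contigs = 4L,
                           mito = FALSE, n_mito_genes = 3L, seed = 1L) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (n_contigs < 1 || n_contigs > n_genes)
    stop("cannot fit genes into contigs: need 1 <= n_contigs <= n_genes")
  set.seed(seed)
  mean_aa <- max(10L, round(mean_gene_len / 3) - 2L)
  aa_len <- pmax(10L, round(stats::runif(n_genes, 0.8, 1.2) * mean_aa))
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  contig_of <- sort(rep_len(seq_len(n_contigs), n_genes))

  contigs <- character(0)
  rows <- list()
  gi <- 0L
  for (ci in seq_len(n_contigs)) {
    idx <- which(contig_of == ci)
    seq <- .random_dna(intergenic_len)
    for (g in idx) {
      gi <- gi + 1L
      gene <- .random_gene(aa_len[g], 1L)
      if (strand[g] == "-") gene <- revcomp(gene)
      start <- nchar(seq) + 1L
      seq <- paste0(seq, gene, .random_dna(intergenic_len))
      rows[[gi]] <- list(id = sprintf("g%04d", gi), contig = sprintf("ctg%02d", ci),
                         strand = strand[g],
                         seg = c(start, start + nchar(gene) - 1L), code = 1L)
    }
    contigs[sprintf("ctg%02d", ci)] <- seq
  }
  mito_ids <- character(0)
  if (mito) {
    seq <- .random_dna(intergenic_len)
    for (k in seq_len(n_mito_genes)) {
      gi <- gi + 1L
      gene <- .random_gene(60L, 3L)
      start <- nchar(seq) + 1L
      seq <- paste0(seq, gene, .random_dna(intergenic_len))
      rows[[gi]] <- list(id = sprintf("m%03d", k), contig = "mito",
                         strand = "+", seg = c(start, start + nchar(gene) - 1L),
                         code = 3L)
    }
    contigs[["mito"]] <- seq
    mito_ids <- "mito"
  }
  assembly <- new_assembly(contigs, tag = "SREF", source = "synthetic",
                           mito = mito_ids)
  models <- new_gene_models(
    id = vapply(rows, `[[`, "", "id"),
    contig = vapply(rows, `[[`, "", "contig"),
    strand = vapply(rows, `[[`, "", "strand"),
    segments = lapply(rows, function(r) matrix(r$seg, ncol = 2)),
    code_id = vapply(rows, `[[`, 1L, "code"),
    origin = "reference", status = "complete")
  list(assembly = assembly, models = models)
}

# apply substitutions/indels to one contig; returns mutated sequence plus
# truth rows (all positions in reference coordinates)
.mutate_contig <- function(seq, sub_rate, indel_rate) {
  L <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  sub_pos <- which(stats::runif(L) < sub_rate)
  subs <- NULL
  if (length(sub_pos)) {
    old <- chars[sub_pos]
    new <- vapply(old, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    chars[sub_pos] <- new
    subs <- data.frame(pos = sub_pos, old = old, new = new,
                       stringsAsFactors = FALSE, row.names = NULL)
  }
  n_ind <- stats::rbinom(1, L, indel_rate)
  indels <- NULL
  if (n_ind > 0) {
    pos <- sort(sample(seq_len(L), n_ind))
    len <- sample(1:3, n_ind, replace = TRUE)
    type <- sample(c("ins", "del"), n_ind, replace = TRUE)
    payload <- character(n_ind)
    for (i in rev(seq_len(n_ind))) {      # right-to-left keeps positions valid
      p <- pos[i]
      if (type[i] == "del") {
        l <- min(len[i], length(chars) - p + 1L)
        payload[i] <- paste(chars[p:(p + l - 1L)], collapse = "")
        chars <- chars[-(p:(p + l - 1L))]
        len[i] <- l
      } else {
        payload[i] <- .random_dna(len[i])
        chars <- append(chars, strsplit(payload[i], "")[[1]], after = p - 1L)
      }
    }
    indels <- data.frame(pos = pos, type = type, len = len, payload = payload,
                         stringsAsFactors = FALSE, row.names = NULL)
  }
  list(seq = paste(chars, collapse = ""), subs = subs, indels = indels)
}

# reference positions whose span is disturbed by an indel record
.indel_hits_span <- function(indels, start, end) {
  if (is.null(indels) || nrow(indels) == 0) return(FALSE)
  del <- indels$type == "del"
  hit_del <- del & indels$pos <= end & (indels$pos + indels$len - 1L) >= start
  # an insertion lands between pos-1 and pos: inside the span iff
  # start < pos <= end
  hit_ins <- !del & indels$pos > start & indels$pos <= end
  any(hit_del | hit_ins)
}

#' Derive a mutated query assembly from a synthetic reference
#'
#' Substitutions are drawn uniformly per position, indels (length 1-3 bp)
#' uniformly, contigs are optionally fragmented at breakpoints, and with
#' `duplicate = TRUE` a second independently mutated haplotype is appended.
#' The returned truth object records every edit in reference coordinates.
#'
#' `expected_transferable` lists models whose reference span contains no
#' indel and no fragmentation breakpoint (either prevents a homology
#' transfer under the no-indel, single-block rule). `disrupted` lists models
#' whose substitutions alone destroy the start codon, the stop codon, or
#' introduce an internal stop. `copy_number` counts, per model, the
#' haplotypes in which its span is intact.
#'
#' @param reference,models Output of [make_reference()].
#' @param sub_rate Per-base substitution rate in \[0, 0.2\].
#' @param indel_rate Per-base indel rate in \[0, 0.2\].
#' @param n_breaks Total number of fragmentation breakpoints (>= 0).
#' @param duplicate Append a second mutated haplotype.
#' @param tag Query tag.
#' @param seed Integer seed.
#' @return List with `assembly` (the query) and `truth` (class
#'   `synthetic_truth`).
#' @export
make_query <- function(reference, models, sub_rate = 0.005,
                       indel_rate = 0.0005, n_breaks = 0L,
                       duplicate = FALSE, tag = "Q001", seed = 1L) {
  if (sub_rate < 0 || sub_rate > 0.2 || indel_rate < 0 || indel_rate > 0.2)
    stop("rates must lie in [0, 0.2]")
  if (n_breaks < 0) stop("n_breaks must be >= 0")
  set.seed(seed)
  haps <- if (duplicate) c("", "_h2") else ""
  contigs <- character(0)
  subs_all <- indels_all <- breaks_all <- list()
  intact <- list()  # per hap: named logical over model ids

  for (h in seq_along(haps)) {
    mut <- lapply(names(reference$contigs), function(cn) {
      .mutate_contig(reference$contigs[[cn]], sub_rate, indel_rate)
    })
    names(mut) <- names(reference$contigs)
    ok <- logical(nrow(models)); names(ok) <- models$id
    for (i in seq_len(nrow(models))) {
      ok[i] <- !.indel_hits_span(mut[[models$contig[i]]]$indels,
                                 models$start[i], models$end[i])
    }
    intact[[h]] <- ok
    for (cn in names(mut)) {
      hap_cn <- paste0(cn, haps[h])
      if (!is.null(mut[[cn]]$subs))
        subs_all[[hap_cn]] <- cbind(contig = cn, hap = h, mut[[cn]]$subs)
      if (!is.null(mut[[cn]]$indels))
        indels_all[[hap_cn]] <- cbind(contig = cn, hap = h, mut[[cn]]$indels)
      contigs[hap_cn] <- mut[[cn]]$seq
    }
  }

  # fragmentation: breakpoints chosen in reference coordinates, applied to
  # the mutated sequence via the indel offset map
  if (n_breaks > 0) {
    lens <- nchar(reference$contigs)
    pick_contig <- sample(rep(names(contigs), length.out = max(n_breaks, length(contigs))),
                          n_breaks)
    out <- contigs
    frag_map <- lapply(names(contigs), function(x) c(0L))
    cuts <- lapply(names(contigs), function(x) integer(0))
    names(cuts) <- names(contigs)
    for (cn in names(contigs)) {
      k <- sum(pick_contig == cn)
      if (k == 0) next
      base <- sub("_h2$", "", cn)
      hap <- if (grepl("_h2$", cn)) 2L else 1L
      ref_pos <- sort(sample(2:(lens[[base]] - 1L), k))
      ind <- indels_all[[cn]]
      mut_pos <- vapply(ref_pos, function(p) {
        off <- 0L
        if (!is.null(ind) && nrow(ind)) {
          ins <- ind$type == "ins" & ind$pos <= p
          del <- ind$type == "del" & (ind$pos + ind$len - 1L) < p
          off <- sum(ind$len[ins]) - sum(ind$len[del])
        }
        min(max(p + off, 1L), nchar(contigs[[cn]]) - 1L)
      }, 1L)
      mut_pos <- unique(mut_pos)
      cuts[[cn]] <- mut_pos
      breaks_all[[cn]] <- data.frame(contig = base, hap = hap, pos = ref_pos,
                                     stringsAsFactors = FALSE)
    }
    frags <- character(0)
    for (cn in names(contigs)) {
      cp <- cuts[[cn]]
      if (length(cp) == 0) { frags[cn] <- contigs[[cn]]; next }
      bounds <- c(0L, cp, nchar(contigs[[cn]]))
      for (j in seq_len(length(bounds) - 1L)) {
        frags[sprintf("%s_f%d", cn, j)] <-
          substr(contigs[[cn]], bounds[j] + 1L, bounds[j + 1L])
      }
    }
    contigs <- frags
  }

  # truth bookkeeping
  bk <- if (length(breaks_all)) do.call(rbind, breaks_all) else
    data.frame(contig = character(0), hap = integer(0), pos = integer(0))
  span_has_break <- function(i, h) {
    b <- bk[bk$contig == models$contig[i] & bk$hap == h, , drop = FALSE]
    nrow(b) > 0 && any(b$pos > models$start[i] & b$pos <= models$end[i])
  }
  copy_number <- integer(nrow(models)); names(copy_number) <- models$id
  for (i in seq_len(nrow(models))) {
    for (h in seq_along(haps)) {
      if (intact[[h]][i] && !span_has_break(i, h))
        copy_number[i] <- copy_number[i] + 1L
    }
  }
  expected_transferable <- models$id[copy_number > 0]

  # disruptive substitutions: translate the substitution-only CDS per model
  ref_sub <- reference
  disrupted <- character(0)
  for (h in seq_along(haps)) {
    mutated <- ref_sub$contigs
    for (cn in names(mutated)) {
      s <- subs_all[[paste0(cn, haps[h])]]
      if (is.null(s) || nrow(s) == 0) next
      ch <- strsplit(mutated[[cn]], "")[[1]]
      ch[s$pos] <- s$new
      mutated[[cn]] <- paste(ch, collapse = "")
    }
    mut_asm <- reference; mut_asm$contigs <- mutated
    for (i in seq_len(nrow(models))) {
      cds <- model_cds(mut_asm, models[i, ])
      tr <- translate_cds(cds, models$code_id[i])
      if (tr$internal_stop || !tr$stop_terminated ||
          substr(cds, 1, 3) != "ATG")
        disrupted <- c(disrupted, models$id[i])
    }
  }
  disrupted <- unique(disrupted)

  assembly <- new_assembly(contigs, tag = tag, source = "synthetic query")
  truth <- structure(list(
    substitutions = if (length(subs_all)) do.call(rbind, unname(subs_all)) else NULL,
    indels = if (length(indels_all)) do.call(rbind, unname(indels_all)) else NULL,
    breakpoints = if (nrow(bk)) bk else NULL,
    expected_transferable = expected_transferable,
    disrupted = disrupted,
    copy_number = copy_number), class = "synthetic_truth")
  list(assembly = assembly, truth = truth)
}

#' Write a synthetic truth table as TSV
#'
#' One row per recorded edit: type (`sub`/`ins`/`del`/`break`), contig,
#' haplotype, reference position, payload.
#'
#' @param truth A `synthetic_truth` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  rows <- list()
  if (!is.null(truth$substitutions))
    rows[[1]] <- data.frame(type = "sub", contig = truth$substitutions$contig,
                            hap = truth$substitutions$hap,
                            pos = truth$substitutions$pos,
                            payload = paste0(truth$substitutions$old, ">",
                                             truth$substitutions$new))
  if (!is.null(truth$indels))
    rows[[2]] <- data.frame(type = truth$indels$type, contig = truth$indels$contig,
                            hap = truth$indels$hap, pos = truth$indels$pos,
                            payload = truth$indels$payload)
  if (!is.null(truth$breakpoints))
    rows[[3]] <- data.frame(type = "break", contig = truth$breakpoints$contig,
                            hap = truth$breakpoints$hap,
                            pos = truth$breakpoints$pos, payload = "")
  df <- if (length(rows)) do.call(rbind, Filter(Negate(is.null), rows)) else
    data.frame(type = character(0), contig = character(0), hap = integer(0),
               pos = integer(0), payload = character(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
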