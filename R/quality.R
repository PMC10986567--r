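# Marker-gene compilation and genome quality evaluation. The internal
# alignment backend anchors every family member to its reference (S288c)
# homolog by global pairwise alignment and merges the results into a
# reference-anchored (star) multiple alignment; member-to-reference
# identities under that construction equal the pairwise global identities.

# global alignment of one member to the reference; returns gapped strings
.global_pair <- function(qseq, rseq) {
  pw <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(qseq), Biostrings::AAString(rseq),
    type = "global", substitutionMatrix = .blosum62(),
    gapOpening = 10, gapExtension = 0.5)
  list(q = strsplit(as.character(Biostrings::alignedPattern(pw)), "")[[1]],
       r = strsplit(as.character(Biostrings::alignedSubject(pw)), "")[[1]],
       identity = 100 * Biostrings::nmatch(pw) /
         max(Biostrings::nmatch(pw) + Biostrings::nmismatch(pw), 1L))
}

#' Reference-anchored multiple alignment of a protein family
#'
#' Each member is aligned globally to the reference sequence; insertions
#' relative to the reference are merged column-wise (star alignment). Rows
#' have equal length; the identity of each member to the reference is
#' computed over columns where both hold a residue.
#'
#' @param seqs Named character vector of member sequences, including the
#'   reference.
#' @param ref_id Name of the reference member.
#' @return List with `rows` (named gapped strings of equal length),
#'   `aln_length`, and `identity` (named, percent identity to the
#'   reference; the reference itself is 100).
#' @export
family_alignment <- function(seqs, ref_id) {
  if (!ref_id %in% names(seqs)) stop("reference member missing from family")
  rseq <- seqs[[ref_id]]
  R <- nchar(rseq)
  others <- setdiff(names(seqs), ref_id)
  pairs <- lapply(seqs[others], .global_pair, rseq = rseq)
  # per-member insertion profile: ins[[m]][as.character(k)] = run length of
  # insertion after reference position k (k = 0..R)
  ins_len <- integer(R + 1L)
  profiles <- list()
  for (m in others) {
    p <- pairs[[m]]
    rpos <- 0L
    runs <- integer(R + 1L)
    placed <- character(0)
    for (j in seq_along(p$r)) {
      if (p$r[j] == "-") runs[rpos + 1L] <- runs[rpos + 1L] + 1L
      else rpos <- rpos + 1L
    }
    profiles[[m]] <- runs
    ins_len <- pmax(ins_len, runs)
  }
  width <- R + sum(ins_len)
  build_row <- function(resid_at, ins_chunks) {
    # resid_at: length-R chars ('-' for deletion); ins_chunks: list of
    # length R+1 character chunks, padded to ins_len
    parts <- vector("list", 2L * R + 1L)
    for (k in 0:R) {
      chunk <- ins_chunks[[k + 1L]]
      pad <- ins_len[k + 1L] - length(chunk)
      parts[[2L * k + 1L]] <- c(chunk, rep("-", pad))
      if (k < R) parts[[2L * k + 2L]] <- resid_at[k + 1L]
    }
    paste(unlist(parts), collapse = "")
  }
  rows <- character(0)
  ref_chars <- strsplit(rseq, "")[[1]]
  rows[ref_id] <- build_row(ref_chars, rep(list(character(0)), R + 1L))
  for (m in others) {
    p <- pairs[[m]]
    resid <- rep("-", R)
    chunks <- rep(list(character(0)), R + 1L)
    rpos <- 0L
    for (j in seq_along(p$r)) {
      if (p$r[j] == "-") {
        chunks[[rpos + 1L]] <- c(chunks[[rpos + 1L]], p$q[j])
      } else {
        rpos <- rpos + 1L
        resid[rpos] <- p$q[j]
      }
    }
    rows[m] <- build_row(resid, chunks)
  }
  identity <- c(setNames(100, ref_id),
                vapply(pairs, `[[`, 0, "identity"))
  list(rows = rows, aln_length = width, identity = identity)
}

# minimum pairwise global identity among a set of sequences
.min_pairwise_identity <- function(seqs) {
  n <- length(seqs)
  if (n < 2) return(100)
  mn <- 100
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      mn <- min(mn, .global_pair(seqs[[i]], seqs[[j]])$identity)
    }
  }
  mn
}

#' Select high-quality genomes
#'
#' Assemblies with high continuity (contig number strictly below
#' `max_contigs`, N50 strictly above `min_n50`) and high similarity to the
#' reference (maker-model ratio strictly below `max_maker_ratio` percent),
#' deduplicated to one assembly per strain.
#'
#' @param reports Data.frame with columns `tag`, `n_contigs`, `n50`,
#'   `maker_ratio`, and (for deduplication) `completeness` where available.
#' @param strain_map Named character vector tag -> strain; `NULL` treats
#'   every tag as its own strain.
#' @param max_contigs,min_n50,max_maker_ratio Thresholds (defaults 100,
#'   500 kb, 33.33%).
#' @return Character vector of selected tags.
#' @export
select_high_quality <- function(reports, strain_map = NULL,
                                max_contigs = 100, min_n50 = 5e5,
                                max_maker_ratio = 100 / 3) {
  keep <- reports$n_contigs < max_contigs & reports$n50 > min_n50 &
    reports$maker_ratio < max_maker_ratio
  select_nonredundant(reports[keep, , drop = FALSE], strain_map)
}

#' Pick one assembly per strain
#'
#' Ranked by completeness (desc), then N50 (desc), then fewest contigs,
#' ties broken by lexicographic tag.
#'
#' @param reports Data.frame with `tag` and ranking columns (missing
#'   ranking columns count as ties).
#' @param strain_map Named character vector tag -> strain name; `NULL`
#'   keeps every tag.
#' @return Character vector of selected tags, sorted.
#' @export
select_nonredundant <- function(reports, strain_map = NULL) {
  if (nrow(reports) == 0) return(character(0))
  if (is.null(strain_map)) return(sort(reports$tag))
  strain <- strain_map[reports$tag]
  strain[is.na(strain)] <- reports$tag[is.na(strain)]
  comp <- if ("completeness" %in% names(reports)) reports$completeness else 0
  n50 <- if ("n50" %in% names(reports)) reports$n50 else 0
  ncont <- if ("n_contigs" %in% names(reports)) reports$n_contigs else 0
  o <- order(strain, -comp, -n50, ncont, reports$tag)
  r <- reports[o, , drop = FALSE]
  sort(r$tag[!duplicated(strain[o])])
}

#' Select medium-high-quality genomes
#'
#' From the non-redundant set: identity to the reference at least
#' `min_identity`, contig number strictly below `max_contigs`, completeness
#' strictly above `min_completeness`.
#'
#' @param reports Data.frame with `tag`, `identity`, `n_contigs`,
#'   `completeness`.
#' @param nonredundant_tags Tags of the non-redundant set.
#' @param min_identity,max_contigs,min_completeness Thresholds (defaults
#'   98.72, 600, 96).
#' @return Character vector of selected tags.
#' @export
select_medium_high_quality <- function(reports, nonredundant_tags,
                                       min_identity = 98.72,
                                       max_contigs = 600,
                                       min_completeness = 96) {
  keep <- reports$tag %in% nonredundant_tags &
    reports$identity >= min_identity &
    reports$n_contigs < max_contigs &
    reports$completeness > min_completeness
  sort(reports$tag[keep])
}

#' Compile the marker gene set
#'
#' Per family series, a family qualifies when it is (i) present in all
#' genomes, (ii) single-copy in every genome, (iii) highly conserved
#' (minimum pairwise global identity >= `min_identity`), (iv) gap-poor
#' (alignment length over reference sequence length <= `max_len_ratio`) and
#' (v) long (reference member >= `min_ref_len` aa). The final marker set is
#' keyed by the reference (S288c) member and consists of the families
#' passing in every series.
#'
#' @param series Named list of `family_set`s over identical tag universes
#'   (restricted to the high-quality genomes, reference included).
#' @param proteins Protein table (`id`, `tag`, `seq`) covering all members.
#' @param ref_tag Tag of the reference genome (default `"S288C"`).
#' @param min_identity,max_len_ratio,min_ref_len Criteria thresholds
#'   (defaults 90, 1.05, 200).
#' @return A `marker_set`: data.frame with `marker` (reference protein id)
#'   and `ref_len`.
#' @export
select_markers <- function(series, proteins, ref_tag = "S288C",
                           min_identity = 90, max_len_ratio = 1.05,
                           min_ref_len = 200) {
  tag_sets <- lapply(series, function(fs) sort(unique(fs$members$tag)))
  if (length(unique(tag_sets)) != 1)
    stop("family series cover different genome tag sets")
  tags <- tag_sets[[1]]
  seqs <- setNames(proteins$seq, proteins$id)
  candidates <- lapply(series, function(fs) {
    keys <- character(0)
    for (f in unique(fs$members$family)) {
      mem <- fs$members[fs$members$family == f, ]
      cnt <- table(mem$tag)
      if (!all(tags %in% names(cnt))) next                  # (i)
      if (any(cnt != 1L)) next                              # (ii)
      ref_member <- mem$protein[mem$tag == ref_tag]
      rlen <- nchar(seqs[[ref_member]])
      if (rlen < min_ref_len) next                          # (v)
      aln <- family_alignment(setNames(seqs[mem$protein], mem$protein),
                              ref_member)
      if (aln$aln_length / rlen > max_len_ratio) next       # (iv)
      if (.min_pairwise_identity(seqs[mem$protein]) < min_identity) next  # (iii)
      keys <- c(keys, ref_member)
    }
    keys
  })
  final <- sort(Reduce(intersect, candidates))
  structure(data.frame(marker = final,
                       ref_len = nchar(seqs[final]),
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("marker_set", "data.frame"))
}

#' Map markers to the families containing them in one series
#'
#' @param markers A `marker_set`.
#' @param families A `family_set`.
#' @return Named character vector marker -> family id (`NA` when the
#'   marker's reference protein is absent from the series).
#' @export
marker_families <- function(markers, families) {
  setNames(families$members$family[match(markers$marker,
                                         families$members$protein)],
           markers$marker)
}

#' Marker-based genome completeness
#'
#' Percentage of marker families with at least one member from the genome.
#'
#' @param genome_tag Genome tag.
#' @param families A `family_set`.
#' @param markers A `marker_set` (non-empty).
#' @return Completeness in percent.
#' @export
completeness <- function(genome_tag, families, markers) {
  if (nrow(markers) == 0) stop("marker set is empty")
  fam <- marker_families(markers, families)
  present <- vapply(fam, function(f) {
    !is.na(f) && any(families$members$tag[families$members$family == f] ==
                       genome_tag)
  }, TRUE)
  100 * mean(present)
}

#' Homolog counts of the marker families in one genome
#'
#' @inheritParams completeness
#' @return List with `counts` (named by marker) and `mean` (over marker
#'   families with at least one member; `NaN` if none).
#' @export
homolog_counts <- function(genome_tag, markers, families) {
  fam <- marker_families(markers, families)
  counts <- vapply(fam, function(f) {
    if (is.na(f)) 0L else
      sum(families$members$tag[families$members$family == f] == genome_tag)
  }, 1L)
  list(counts = counts, mean = mean(counts[counts > 0]))
}

#' Marker-based base quality of a genome
#'
#' Mean amino-acid identity of the genome's marker-gene homologs to their
#' reference (S288c) counterparts, computed from the family alignment. When
#' a genome holds several homologs of one marker family, the one with the
#' highest identity represents the genome. The mean runs over marker
#' families with at least one homolog.
#'
#' @param genome_tag Genome tag.
#' @param markers A `marker_set`.
#' @param families A `family_set`.
#' @param proteins Protein table (`id`, `seq`) covering members and
#'   reference proteins.
#' @return Identity to the reference in percent (`NaN` when no marker has a
#'   homolog).
#' @export
base_quality <- function(genome_tag, markers, families, proteins) {
  seqs <- setNames(proteins$seq, proteins$id)
  fam <- marker_families(markers, families)
  vals <- numeric(0)
  for (m in markers$marker) {
    f <- fam[[m]]
    if (is.na(f)) next
    mem <- families$members[families$members$family == f, ]
    mine <- mem$protein[mem$tag == genome_tag]
    if (!length(mine)) next
    ident <- vapply(mine, function(p) {
      if (p == m) 100 else .global_pair(seqs[[p]], seqs[[m]])$identity
    }, 0)
    vals <- c(vals, max(ident))
  }
  mean(vals)
}
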