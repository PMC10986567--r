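# Two-step single-linkage clustering of protein models into gene families.
# All similarity thresholds are strict (">"): an edge qualifies at cluster
# cutoff c iff identity > c and both alignment coverages > c.

.blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

#' All-versus-all protein similarity search
#'
#' Local (Smith-Waterman) alignment of every pair, BLOSUM62 scoring.
#' Identity is identical residues over alignment columns holding a residue
#' in both sequences; coverage of a sequence is its aligned residues over
#' its full length, in percent. Self-hits are excluded and each unordered
#' pair is reported once.
#'
#' @param a Protein set: data.frame with `id` and `seq` (e.g. from
#'   [model_proteins()]).
#' @param b Optional second set; when `NULL`, `a` is searched against
#'   itself.
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return Data.frame of `SimilarityEdge`s: `a`, `b`, `identity`, `a_cov`,
#'   `b_cov`.
#' @export
pairwise_search <- function(a, b = NULL, gap_opening = 11, gap_extension = 1) {
  self <- is.null(b)
  if (self) b <- a
  if (nrow(a) == 0 || nrow(b) == 0) stop("protein sets must be non-empty")
  if (anyDuplicated(c(a$id, if (!self) b$id)))
    stop("duplicate protein id in search input")
  sm <- .blosum62()
  res <- list()
  for (j in seq_len(nrow(b))) {
    ii <- if (self) seq_len(j - 1L) else seq_len(nrow(a))
    if (!length(ii)) next
    pw <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(a$seq[ii]), Biostrings::AAString(b$seq[j]),
      type = "local", substitutionMatrix = sm,
      gapOpening = gap_opening, gapExtension = gap_extension)
    # a local alignment consumes a contiguous substring of each sequence,
    # so the aligned-residue count is the width of the aligned range
    pat <- Biostrings::pattern(pw)
    sub <- Biostrings::subject(pw)
    a_res <- BiocGenerics::end(pat) - BiocGenerics::start(pat) + 1L
    b_res <- BiocGenerics::end(sub) - BiocGenerics::start(sub) + 1L
    nmat <- Biostrings::nmatch(pw)
    nmis <- Biostrings::nmismatch(pw)
    res[[j]] <- data.frame(
      a = a$id[ii], b = b$id[j],
      identity = 100 * nmat / pmax(nmat + nmis, 1L),
      a_cov = 100 * a_res / nchar(a$seq[ii]),
      b_cov = 100 * b_res / nchar(b$seq[j]),
      stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, Filter(Negate(is.null), res)) else
    data.frame(a = character(0), b = character(0), identity = numeric(0),
               a_cov = numeric(0), b_cov = numeric(0))
  rownames(out) <- NULL
  out
}

# deterministic union-find with path halving
.uf_new <- function(n) seq_len(n)
.uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Single-linkage clustering at a cluster cutoff
#'
#' Connected components of the graph whose edges satisfy
#' `identity > cutoff` and both coverages `> cutoff` (strict). Edges are
#' processed in sorted order so the result is deterministic.
#'
#' @param ids Character vector of all element ids (singletons included).
#' @param edges Edge table from [pairwise_search()] (columns `a`, `b`,
#'   `identity`, `a_cov`, `b_cov`).
#' @param cutoff Cluster cutoff in percent.
#' @return List of character vectors (each sorted), ordered by their
#'   smallest member; together they partition `ids`.
#' @export
single_linkage <- function(ids, edges, cutoff) {
  if (anyDuplicated(ids)) stop("duplicate ids")
  keep <- edges$identity > cutoff & edges$a_cov > cutoff & edges$b_cov > cutoff
  e <- edges[keep, , drop = FALSE]
  if (nrow(e) > 0 && !all(c(e$a, e$b) %in% ids))
    stop("edges refer to unknown ids")
  parent <- .uf_new(length(ids))
  ai <- match(e$a, ids); bi <- match(e$b, ids)
  o <- order(pmin(ai, bi), pmax(ai, bi))
  for (k in o) {
    ra <- .uf_find(parent, ai[k]); rb <- .uf_find(parent, bi[k])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_along(ids), function(i) .uf_find(parent, i), 1L)
  groups <- split(ids, root)
  groups <- lapply(groups, sort)
  groups <- groups[order(vapply(groups, `[[`, "", 1L))]
  names(groups) <- NULL
  groups
}

#' Construct a family set
#'
#' Families are ordered by their smallest member id and assigned ids
#' `SCF<cutoff>_<5-digit index>`.
#'
#' @param groups List of character vectors of protein ids (a partition).
#' @param proteins Protein table (`id`, `tag`) covering all members.
#' @param cutoff Cluster cutoff in percent.
#' @param prefix Series prefix (default `"SCF"`).
#' @return A `family_set`: list with `cutoff`, `label`, and `members`
#'   (data.frame `family`, `tag`, `protein`).
#' @export
new_family_set <- function(groups, proteins, cutoff, prefix = "SCF") {
  ids <- unlist(groups)
  if (anyDuplicated(ids)) stop("groups do not partition the ids")
  if (!all(ids %in% proteins$id)) stop("group member missing from proteins")
  groups <- lapply(groups, sort)
  groups <- groups[order(vapply(groups, `[[`, "", 1L))]
  fam_id <- sprintf("%s%d_%05d", prefix, cutoff, seq_along(groups))
  members <- data.frame(
    family = rep(fam_id, lengths(groups)),
    protein = unlist(groups),
    stringsAsFactors = FALSE)
  members$tag <- proteins$tag[match(members$protein, proteins$id)]
  structure(list(cutoff = cutoff, label = paste0(prefix, cutoff),
                 members = members[, c("family", "tag", "protein")]),
            class = "family_set")
}

#' @export
print.family_set <- function(x, ...) {
  cat(sprintf("family_set %s: %d families, %d proteins, %d genomes\n",
              x$label, length(unique(x$members$family)), nrow(x$members),
              length(unique(x$members$tag))))
  invisible(x)
}

# family id -> member id character vectors
family_groups <- function(fs) {
  split(fs$members$protein, fs$members$family)
}

#' Initial families: the first clustering step
#'
#' Four-stage composition: (1) reference proteins are clustered by single
#' linkage at the cutoff; (2) each blastn protein joins the family of its
#' reference parent model; (3) each maker protein with a qualifying hit to a
#' reference protein (identity and both coverages strictly above the
#' cutoff) joins the family of its best such hit (highest identity, then
#' coverage, then id); (4) the remaining maker proteins are clustered among
#' themselves at the same cutoff. The pooled result is returned as plain
#' groups (no family ids yet).
#'
#' @param ref_proteins,blastn_proteins,maker_proteins Protein tables
#'   (`id`, `seq`, `tag`; blastn rows need `parent` = reference model id).
#' @param cutoff Cluster cutoff in percent.
#' @param edges Optional precomputed edge table over all involved proteins
#'   (memoised search results); missing parts are computed on demand.
#' @return List of character vectors (the initial families).
#' @export
build_initial_families <- function(ref_proteins, blastn_proteins,
                                   maker_proteins, cutoff, edges = NULL) {
  have_edges <- function(xa, xb) {
    if (is.null(edges)) return(NULL)
    edges[(edges$a %in% xa & edges$b %in% xb) |
          (edges$a %in% xb & edges$b %in% xa), , drop = FALSE]
  }
  # (1) reference families
  ref_edges <- have_edges(ref_proteins$id, ref_proteins$id)
  if (is.null(ref_edges))
    ref_edges <- if (nrow(ref_proteins) > 1) pairwise_search(ref_proteins) else
      data.frame(a = character(0), b = character(0), identity = numeric(0),
                 a_cov = numeric(0), b_cov = numeric(0))
  groups <- single_linkage(ref_proteins$id, ref_edges, cutoff)

  # (2) blastn proteins follow their parent
  if (nrow(blastn_proteins) > 0) {
    if (anyNA(blastn_proteins$parent))
      stop("blastn protein without a reference parent id")
    fam_of <- integer(0)
    for (g in seq_along(groups)) fam_of[groups[[g]]] <- g
    gi <- fam_of[blastn_proteins$parent]
    if (anyNA(gi))
      stop(sprintf("blastn protein '%s' has unknown parent '%s'",
                   blastn_proteins$id[is.na(gi)][1],
                   blastn_proteins$parent[is.na(gi)][1]))
    for (i in seq_len(nrow(blastn_proteins)))
      groups[[gi[i]]] <- c(groups[[gi[i]]], blastn_proteins$id[i])
  }

  # (3) maker proteins join the family of their best qualifying ref hit
  leftovers <- maker_proteins
  if (nrow(maker_proteins) > 0 && nrow(ref_proteins) > 0) {
    mr <- have_edges(maker_proteins$id, ref_proteins$id)
    if (is.null(mr)) mr <- pairwise_search(maker_proteins, ref_proteins)
    # orient: a = maker, b = ref
    flip <- mr$a %in% ref_proteins$id
    mr[flip, c("a", "b")] <- mr[flip, c("b", "a")]
    mr[flip, c("a_cov", "b_cov")] <- mr[flip, c("b_cov", "a_cov")]
    mr <- mr[mr$identity > cutoff & mr$a_cov > cutoff & mr$b_cov > cutoff, ,
             drop = FALSE]
    if (nrow(mr) > 0) {
      mr <- mr[order(mr$a, -mr$identity, -pmin(mr$a_cov, mr$b_cov), mr$b), ]
      best <- mr[!duplicated(mr$a), ]
      fam_of <- integer(0)
      for (g in seq_along(groups)) fam_of[groups[[g]]] <- g
      for (i in seq_len(nrow(best))) {
        g <- fam_of[[best$b[i]]]
        groups[[g]] <- c(groups[[g]], best$a[i])
      }
      leftovers <- maker_proteins[!maker_proteins$id %in% best$a, , drop = FALSE]
    }
  }

  # (4) leftover maker proteins cluster among themselves
  if (nrow(leftovers) > 0) {
    le <- have_edges(leftovers$id, leftovers$id)
    if (is.null(le))
      le <- if (nrow(leftovers) > 1) pairwise_search(leftovers) else
        data.frame(a = character(0), b = character(0), identity = numeric(0),
                   a_cov = numeric(0), b_cov = numeric(0))
    groups <- c(groups, single_linkage(leftovers$id, le, cutoff))
  }
  groups
}

#' Merge related initial families (the second clustering step)
#'
#' The longest sequence of each initial family (ties: lexicographically
#' smallest id) is its representative. Family pairs whose representatives
#' match with identity and coverage strictly above `cutoff - 10` are
#' compared member-against-member; if any member pair qualifies at the full
#' cutoff, the pair is related. Related pairs are merged by single linkage.
#' The merge never splits a family.
#'
#' @param groups List of initial families (character vectors of ids).
#' @param proteins Protein table (`id`, `seq`) covering all members.
#' @param cutoff Cluster cutoff in percent.
#' @param edges Optional memoised edge table; missing comparisons are
#'   computed on demand.
#' @param prefilter Apply the representative prefilter (disable to compare
#'   every family pair, e.g. for oracle tests).
#' @return List of merged families.
#' @export
merge_related_families <- function(groups, proteins, cutoff, edges = NULL,
                                   prefilter = TRUE) {
  if (length(groups) < 2) return(groups)
  seqs <- setNames(proteins$seq, proteins$id)
  reps <- vapply(groups, function(g) {
    g <- g[order(-nchar(seqs[g]), g)]
    g[1]
  }, "")
  qual <- function(e, cut) e$identity > cut & e$a_cov > cut & e$b_cov > cut
  get_edges <- function(xa, xb) {
    if (!is.null(edges))
      return(edges[(edges$a %in% xa & edges$b %in% xb) |
                   (edges$a %in% xb & edges$b %in% xa), , drop = FALSE])
    pairwise_search(data.frame(id = xa, seq = unname(seqs[xa])),
                    data.frame(id = xb, seq = unname(seqs[xb])))
  }
  # candidate pairs via representative search (or all pairs)
  cand <- NULL
  if (prefilter) {
    re <- if (!is.null(edges))
      edges[edges$a %in% reps & edges$b %in% reps, , drop = FALSE]
    else if (length(reps) > 1)
      pairwise_search(data.frame(id = reps, seq = unname(seqs[reps])))
    else NULL
    if (!is.null(re) && nrow(re)) {
      re <- re[qual(re, cutoff - 10), , drop = FALSE]
      fi <- match(re$a, reps); fj <- match(re$b, reps)
      cand <- unique(cbind(pmin(fi, fj), pmax(fi, fj)))
    }
  } else {
    cand <- t(utils::combn(length(groups), 2))
  }
  related <- NULL
  if (!is.null(cand) && nrow(cand)) {
    rel <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      ce <- get_edges(groups[[cand[i, 1]]], groups[[cand[i, 2]]])
      # keep only true cross-family edges
      ce <- ce[(ce$a %in% groups[[cand[i, 1]]]) != (ce$b %in% groups[[cand[i, 1]]]), ,
               drop = FALSE]
      rel[i] <- nrow(ce) > 0 && any(qual(ce, cutoff))
    }
    related <- cand[rel, , drop = FALSE]
  }
  if (is.null(related) || nrow(related) == 0) return(groups)
  fam_ids <- as.character(seq_along(groups))
  fedges <- data.frame(a = fam_ids[related[, 1]], b = fam_ids[related[, 2]],
                       identity = 101, a_cov = 101, b_cov = 101)
  comp <- single_linkage(fam_ids, fedges, 100)
  lapply(comp, function(fams) sort(unlist(groups[as.integer(fams)])))
}

#' Build family series at several cluster cutoffs
#'
#' Runs the two-step clustering (initial families by origin, then the
#' related-family merge) once per cutoff over the same protein universe.
#' The all-versus-all similarity search is performed once and its edge
#' table reused across cutoffs.
#'
#' @param proteins Protein table with `id`, `tag`, `seq`, `origin`
#'   (`reference`/`blastn`/`maker`) and `parent` for blastn rows. Proteins
#'   with other origins are treated as maker-models.
#' @param cutoffs Cluster cutoffs in percent (default 50-90 by 10).
#' @param prefilter Apply the representative prefilter in the merge step.
#' @param edges Optional precomputed edge table ([pairwise_search()] over
#'   `proteins`).
#' @return Named list of `family_set`s, one per cutoff (`SCF50`, ...).
#' @export
build_scf <- function(proteins, cutoffs = c(50, 60, 70, 80, 90),
                      prefilter = TRUE, edges = NULL) {
  stopifnot(all(c("id", "tag", "seq", "origin") %in% names(proteins)))
  if (!"parent" %in% names(proteins)) proteins$parent <- NA_character_
  if (is.null(edges)) edges <- pairwise_search(proteins)
  ref <- proteins[proteins$origin == "reference", , drop = FALSE]
  bla <- proteins[proteins$origin == "blastn", , drop = FALSE]
  mak <- proteins[!proteins$origin %in% c("reference", "blastn"), , drop = FALSE]
  out <- list()
  for (cut in cutoffs) {
    groups <- build_initial_families(ref, bla, mak, cut, edges = edges)
    groups <- merge_related_families(groups, proteins, cut, edges = edges,
                                     prefilter = prefilter)
    out[[paste0("SCF", cut)]] <- new_family_set(groups, proteins, cut)
  }
  out
}

#' Restrict a family set to a subset of genomes
#'
#' Members outside `genome_tags` are dropped and families left empty are
#' removed; family ids are kept stable.
#'
#' @param fs A `family_set`.
#' @param genome_tags Tags to keep (must occur in `fs`).
#' @return The restricted `family_set`.
#' @export
subset_families <- function(fs, genome_tags) {
  if (!all(genome_tags %in% fs$members$tag))
    stop("genome_tags must be a subset of the tags in the family set")
  out <- fs
  out$members <- fs$members[fs$members$tag %in% genome_tags, , drop = FALSE]
  rownames(out$members) <- NULL
  out
}

#' Write a family table in the deposited TAB/`|` dialect
#'
#' One row per family; the first column holds the family id, the remaining
#' columns one genome tag each (sorted), with multiple homologs from the
#' same assembly joined by `|` and absence as an empty cell.
#'
#' @param fs A `family_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_family_table <- function(fs, path) {
  tags <- sort(unique(fs$members$tag))
  fams <- sort(unique(fs$members$family))
  cell <- function(f, t) {
    p <- sort(fs$members$protein[fs$members$family == f & fs$members$tag == t])
    paste(p, collapse = "|")
  }
  lines <- paste(c("Family_ID", tags), collapse = "\t")
  for (f in fams) {
    lines <- c(lines,
               paste(c(f, vapply(tags, function(t) cell(f, t), "")),
                     collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a family table written by [write_family_table()]
#'
#' @param path Family table file.
#' @param cutoff Cluster cutoff; parsed from the family ids when `NULL`.
#' @return A `family_set`.
#' @export
read_family_table <- function(path, cutoff = NULL) {
  lines <- readLines(path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  tags <- header[-1]
  rows <- lapply(lines[-1], function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
  members <- list()
  for (r in rows) {
    f <- r[1]
    cells <- c(r[-1], rep("", length(tags) - (length(r) - 1L)))
    for (t in seq_along(tags)) {
      if (cells[t] == "") next
      p <- strsplit(cells[t], "|", fixed = TRUE)[[1]]
      members[[length(members) + 1L]] <-
        data.frame(family = f, tag = tags[t], protein = p,
                   stringsAsFactors = FALSE)
    }
  }
  members <- do.call(rbind, members)
  if (is.null(cutoff)) {
    m <- regmatches(members$family[1], regexec("^[A-Za-z]+([0-9]+)_", members$family[1]))[[1]]
    cutoff <- if (length(m) == 2) as.integer(m[2]) else NA_integer_
  }
  structure(list(cutoff = cutoff,
                 label = sub("_.*$", "", members$family[1]),
                 members = members),
            class = "family_set")
}
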