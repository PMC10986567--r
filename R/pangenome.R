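# Pangenome classification and inter-group homolog-count statistics.
# Kruskal-Wallis is delegated to stats::kruskal.test (tie-corrected H,
# chi-square p with k-1 df); Dunn's post hoc z test is implemented here.

#' Classify families into extended core / character / accessory
#'
#' Presence fraction f = genomes with at least one member over `n_genomes`.
#' The core test is applied first: extended core when f >= `core_frac`,
#' accessory when f <= `acc_frac`, character otherwise.
#'
#' @param families A `family_set`.
#' @param n_genomes Total number of genomes considered.
#' @param core_frac,acc_frac Fraction thresholds (defaults 0.95 and 0.05).
#' @return Named character vector family id -> category.
#' @export
classify_families <- function(families, n_genomes, core_frac = 0.95,
                              acc_frac = 0.05) {
  if (n_genomes < 1) stop("n_genomes must be >= 1")
  pres <- tapply(families$members$tag, families$members$family,
                 function(t) length(unique(t)))
  f <- as.numeric(pres) / n_genomes
  out <- ifelse(f >= core_frac, "extended_core",
                ifelse(f <= acc_frac, "accessory", "character"))
  setNames(out, names(pres))
}

#' Per-genome counts of families and sequences per pangenome category
#'
#' @param families A `family_set`.
#' @param categories Output of [classify_families()].
#' @param tag Genome tag.
#' @return Data.frame with one row per category: `families` (families of
#'   that category with at least one member from the genome) and
#'   `sequences` (total member sequences).
#' @export
per_genome_category_counts <- function(families, categories, tag) {
  mine <- families$members[families$members$tag == tag, , drop = FALSE]
  cat_of <- categories[mine$family]
  cats <- c("extended_core", "character", "accessory")
  data.frame(
    category = cats,
    families = vapply(cats, function(cc)
      length(unique(mine$family[cat_of == cc])), 1L),
    sequences = vapply(cats, function(cc) sum(cat_of == cc), 1L),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Kruskal-Wallis H test over groups of homolog counts
#'
#' Mid-rank H with tie correction and chi-square p on k-1 degrees of
#' freedom. All-identical input short-circuits to H = 0, p = 1.
#'
#' @param groups List of numeric vectors (>= 2 groups, each non-empty).
#' @return List with `H` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) == 0))
    stop("need >= 2 non-empty groups")
  x <- unlist(groups)
  if (length(x) < 3) stop("need a total of >= 3 observations")
  if (length(unique(x)) == 1) return(list(H = 0, p = 1))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Dunn's post hoc test
#'
#' For each group pair, z = (mean rank difference) /
#' sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j)) with the tie term
#' T = sum(t^3 - t) / (12 (N - 1)); two-sided p from the standard normal.
#' No multiplicity adjustment by default.
#'
#' @param groups List of numeric vectors, each non-empty.
#' @param p_adjust Adjustment method passed to [stats::p.adjust()]
#'   (default `"none"`).
#' @return List with matrices `z` and `p` (unit diagonal).
#' @export
dunn_posthoc <- function(groups, p_adjust = "none") {
  k <- length(groups)
  if (any(lengths(groups) == 0)) stop("empty group")
  x <- unlist(groups)
  N <- length(x)
  r <- rank(x)
  g <- rep(seq_len(k), lengths(groups))
  rbar <- tapply(r, g, mean)
  n <- lengths(groups)
  t <- table(x)
  tie <- sum(t^3 - t) / (12 * (N - 1))
  z <- matrix(0, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      v <- (N * (N + 1) / 12 - tie) * (1 / n[i] + 1 / n[j])
      z[i, j] <- if (v <= 0) 0 else (rbar[i] - rbar[j]) / sqrt(v)
    }
  }
  p <- 2 * stats::pnorm(-abs(z))
  diag(p) <- 1
  off <- row(p) != col(p)
  p[off] <- stats::p.adjust(p[off], method = p_adjust)
  list(z = z, p = p)
}

# per-family homolog counts for every tag in the scheme (absent genome -> 0)
.family_count_matrix <- function(families, tags) {
  mem <- families$members[families$members$tag %in% tags, , drop = FALSE]
  fams <- sort(unique(families$members$family))
  m <- matrix(0L, nrow = length(fams), ncol = length(tags),
              dimnames = list(fams, tags))
  if (nrow(mem)) {
    tab <- table(mem$family, mem$tag)
    m[rownames(tab), colnames(tab)] <- tab
  }
  m
}

.flag_one_family <- function(counts, labels, alpha, delta, p_adjust) {
  groups <- split(counts, labels)
  kw <- kruskal_wallis(groups)
  res <- list(H = kw$H, p_kw = kw$p, flagged = FALSE,
              pairs = data.frame(group_a = character(0), group_b = character(0),
                                 p_dunn = numeric(0), delta_mean = numeric(0)))
  if (is.na(kw$p) || kw$p >= alpha) return(res)
  dn <- dunn_posthoc(groups, p_adjust = p_adjust)
  means <- vapply(groups, mean, 0)
  gs <- names(groups)
  pairs <- list()
  for (i in seq_along(gs)[-length(gs)]) {
    for (j in (i + 1):length(gs)) {
      dm <- means[[i]] - means[[j]]
      if (dn$p[i, j] < alpha && abs(dm) > delta)
        pairs[[length(pairs) + 1L]] <- data.frame(
          group_a = gs[i], group_b = gs[j],
          p_dunn = dn$p[i, j], delta_mean = dm, stringsAsFactors = FALSE)
    }
  }
  if (length(pairs)) {
    res$pairs <- do.call(rbind, pairs)
    res$flagged <- TRUE
  }
  res
}

#' Flag families with inter-group homolog-number differences
#'
#' Per family: Kruskal-Wallis over per-genome homolog counts grouped by the
#' scheme (genomes absent from a family count 0); families passing the gate
#' (p below `alpha`) go to Dunn's test; a group pair is significantly
#' different when its Dunn p is below `alpha` and the absolute difference
#' of its mean homolog numbers exceeds `delta`. A family with at least one
#' such pair is flagged.
#'
#' @param families A `family_set`.
#' @param scheme Data.frame with columns `tag` and `group` (>= 2 groups).
#' @param alpha Significance level (default 0.05).
#' @param delta Minimum absolute mean difference (default 0.5).
#' @param p_adjust Dunn p adjustment (default `"none"`).
#' @return Data.frame with one row per family: `family`, `H`, `p_kw`,
#'   `flagged`, `best_pair`, `best_p`, `delta_mean`, plus a `pairs`
#'   list-column of significant pairs.
#' @export
flag_intergroup_families <- function(families, scheme, alpha = 0.05,
                                     delta = 0.5, p_adjust = "none") {
  if (anyDuplicated(scheme$tag)) stop("a tag appears in more than one group")
  counts <- .family_count_matrix(families, scheme$tag)
  labels <- scheme$group[match(colnames(counts), scheme$tag)]
  out <- vector("list", nrow(counts))
  for (i in seq_len(nrow(counts))) {
    r <- .flag_one_family(counts[i, ], labels, alpha, delta, p_adjust)
    best <- if (nrow(r$pairs)) r$pairs[which.min(r$pairs$p_dunn), ] else NULL
    out[[i]] <- data.frame(
      family = rownames(counts)[i], H = r$H, p_kw = r$p_kw,
      flagged = r$flagged,
      best_pair = if (is.null(best)) NA_character_ else
        paste(best$group_a, best$group_b, sep = "/"),
      best_p = if (is.null(best)) NA_real_ else best$p_dunn,
      delta_mean = if (is.null(best)) NA_real_ else best$delta_mean,
      stringsAsFactors = FALSE)
    out[[i]]$pairs <- list(r$pairs)
  }
  do.call(rbind, out)
}

#' Randomised-grouping control for the inter-group family scan
#'
#' Permutes the group labels uniformly (group sizes preserved) and records
#' the number of flagged families per replicate.
#'
#' @inheritParams flag_intergroup_families
#' @param n_reps Number of permutation replicates (>= 1).
#' @param seed Integer seed.
#' @return Integer vector of flagged-family counts, length `n_reps`.
#' @export
randomized_control <- function(families, scheme, n_reps, alpha = 0.05,
                               delta = 0.5, p_adjust = "none", seed = 1L) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  set.seed(seed)
  counts <- .family_count_matrix(families, scheme$tag)
  labels <- scheme$group[match(colnames(counts), scheme$tag)]
  vapply(seq_len(n_reps), function(rep) {
    perm <- sample(labels)
    sum(vapply(seq_len(nrow(counts)), function(i)
      .flag_one_family(counts[i, ], perm, alpha, delta, p_adjust)$flagged,
      TRUE))
  }, 1L)
}

#' Concatenated marker alignment for phylogenetic reconstruction
#'
#' Builds the reference-anchored alignment of each marker family, keeps one
#' row per genome (the best-identity homolog when a genome holds several),
#' and concatenates the alignments in sorted family order. Every genome in
#' `tags` must be present in every marker family. Tree inference itself is
#' left to external tools.
#'
#' @param markers A `marker_set`.
#' @param families A `family_set`.
#' @param proteins Protein table (`id`, `seq`).
#' @param tags Genome tags to include as alignment rows.
#' @param ref_tag Reference genome tag; its sequence anchors each family
#'   alignment and is included as a row.
#' @return Named character vector of equal-length alignment rows
#'   (`ref_tag` first, then `tags` sorted), suitable for FASTA export via
#'   [write_seqs_fasta()].
#' @export
concat_marker_alignment <- function(markers, families, proteins, tags,
                                    ref_tag = "S288C") {
  seqs <- setNames(proteins$seq, proteins$id)
  fam <- marker_families(markers, families)
  tags <- sort(setdiff(tags, ref_tag))
  rows <- setNames(rep("", length(tags) + 1L), c(ref_tag, tags))
  for (m in sort(markers$marker)) {
    f <- fam[[m]]
    if (is.na(f)) stop(sprintf("marker '%s' absent from the family set", m))
    mem <- families$members[families$members$family == f, ]
    pick <- character(0)
    for (t in tags) {
      mine <- mem$protein[mem$tag == t]
      if (!length(mine))
        stop(sprintf("genome '%s' missing from marker family '%s'", t, f))
      if (length(mine) > 1) {
        ident <- vapply(mine, function(p) .global_pair(seqs[[p]], seqs[[m]])$identity, 0)
        mine <- mine[order(-ident, mine)][1]
      }
      pick[t] <- mine
    }
    aln <- family_alignment(setNames(seqs[c(m, unname(pick))],
                                     c(m, unname(pick))), m)
    rows[ref_tag] <- paste0(rows[ref_tag], aln$rows[[m]])
    for (t in tags) rows[t] <- paste0(rows[t], aln$rows[[pick[t]]])
  }
  rows
}
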