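# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files are read.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(len) paste(sample(AA20, len, replace = TRUE),
                                      collapse = "")

# mutate a fraction of residues of a protein (substitutions only)
mutate_protein <- function(seq, frac) {
  ch <- strsplit(seq, "")[[1]]
  k <- max(1L, round(frac * length(ch)))
  idx <- sample(seq_along(ch), k)
  ch[idx] <- vapply(ch[idx], function(a) sample(setdiff(AA20, a), 1), "")
  paste(ch, collapse = "")
}

# a protein table of n "seed" proteins plus mutated copies at the given
# per-copy divergence fractions, assigned round-robin to genome tags
random_protein_set <- function(n_seed = 4, copies_frac = c(0.02, 0.1, 0.3),
                               len = 120, tags = c("S288C", "AAAA", "BBBB"),
                               origin = "reference") {
  rows <- list()
  k <- 0L
  for (i in seq_len(n_seed)) {
    base <- random_protein(len)
    variants <- c(base, vapply(copies_frac, function(f)
      mutate_protein(base, f), ""))
    for (v in seq_along(variants)) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        id = sprintf("p%03d", k),
        tag = tags[(k - 1L) %% length(tags) + 1L],
        seq = variants[v], origin = origin, parent = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df$length <- nchar(df$seq)
  df
}

# brute-force N50: the largest length L with sum(lengths >= L) covering
# at least half the total
n50_oracle <- function(lengths) {
  total <- sum(as.numeric(lengths))
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) {
    if (sum(as.numeric(lengths[lengths >= L])) >= total / 2) return(L)
  }
  min(lengths)
}

# brute-force single linkage: connected components of the thresholded
# similarity graph, via igraph
components_oracle <- function(ids, edges, cutoff) {
  keep <- edges$identity > cutoff & edges$a_cov > cutoff & edges$b_cov > cutoff
  g <- igraph::graph_from_data_frame(edges[keep, c("a", "b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership
  groups <- split(names(comp), comp)
  groups <- lapply(groups, sort)
  groups <- unname(groups[order(vapply(groups, `[[`, "", 1L))])
  groups
}

# small annotated cohort: reference plus substitution-only queries run
# through step-1 annotation; returns proteins table + per-genome gene map
annotated_cohort <- function(n_genes = 10, n_queries = 3, sub_rate = 0.004,
                             mean_gene_len = 660, seed = 5) {
  ref <- make_reference(n_genes = n_genes, mean_gene_len = mean_gene_len,
                        n_contigs = 2, seed = seed)
  ref_prot <- model_proteins(ref$models, ref$assembly, tag = "S288C")
  ref_prot$origin <- "reference"
  prots <- list(ref_prot)
  for (i in seq_len(n_queries)) {
    q <- make_query(ref$assembly, ref$models, sub_rate = sub_rate,
                    indel_rate = 0, seed = seed + 100 + i,
                    tag = sprintf("Q%03d", i))
    s1 <- annotate_step1(q$assembly, ref$assembly, ref$models)
    p <- model_proteins(s1$models, q$assembly)
    p$origin <- "blastn"
    prots[[i + 1L]] <- p
  }
  proteins <- do.call(rbind, prots)
  rownames(proteins) <- NULL
  list(reference = ref, proteins = proteins,
       tags = c("S288C", sprintf("Q%03d", seq_len(n_queries))))
}

# family_set with prescribed per-tag member counts (rows = families,
# columns = genome tags)
counts_family_set <- function(count_matrix, cutoff = 70) {
  rows <- list()
  for (f in rownames(count_matrix)) {
    for (t in colnames(count_matrix)) {
      k <- count_matrix[f, t]
      if (k > 0)
        rows[[length(rows) + 1L]] <- data.frame(
          family = f, tag = t,
          protein = sprintf("%s_%s_%d", f, t, seq_len(k)))
    }
  }
  structure(list(cutoff = cutoff, label = paste0("SCF", cutoff),
                 members = do.call(rbind, rows)),
            class = "family_set")
}

# compact hand-built cohort: marker-sized families over a few genomes plus
# the reference, used by the quality and pangenome tests
marker_cohort <- function(seed = 81, n_fam = 4, tags = c("QAAA", "QBBB")) {
  set.seed(seed)
  fams <- list()
  prot <- list()
  for (f in seq_len(n_fam)) {
    base <- random_protein(250)
    ids <- c(sprintf("ref_%02d", f),
             vapply(seq_along(tags), function(i) sprintf("%s_%02d", tags[i], f), ""))
    seqs <- c(base, vapply(seq_along(tags), function(i)
      mutate_protein(base, 0.01), ""))
    prot[[f]] <- data.frame(id = ids, tag = c("S288C", tags), seq = seqs)
    fams[[f]] <- ids
  }
  proteins <- do.call(rbind, prot)
  proteins$origin <- ifelse(proteins$tag == "S288C", "reference", "blastn")
  proteins$parent <- ifelse(proteins$tag == "S288C", NA,
                            sub("^Q[A-Z]+_", "ref_", proteins$id))
  list(proteins = proteins, groups = fams, tags = c("S288C", tags))
}

as_series <- function(groups, proteins, cutoffs = c(50, 60, 70, 80, 90)) {
  out <- lapply(cutoffs, function(cc) new_family_set(groups, proteins, cc))
  names(out) <- paste0("SCF", cutoffs)
  out
}

# family set built directly from a known gene <-> gene correspondence:
# one family per reference gene, containing each genome's copy
truth_family_set <- function(proteins, cutoff = 70) {
  fam_key <- ifelse(proteins$origin == "reference", proteins$id,
                    proteins$parent)
  groups <- split(proteins$id, fam_key)
  new_family_set(unname(groups), proteins, cutoff)
}
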