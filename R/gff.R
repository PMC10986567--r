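#' Read gene models from GFF3
#'
#' CDS features are grouped by their `Parent` attribute (falling back to
#' `ID` when no parent is present) into one model per parent. Coordinates
#' are used as-is (1-based inclusive). Models whose feature hierarchy
#' includes a `pseudogene`-typed ancestor (or a `pseudo=true` /
#' `gene_biotype=pseudogene` attribute) are flagged `pseudo = TRUE` so that
#' callers can exclude them from the reference set used for transfer.
#'
#' @param path GFF3 file.
#' @param assembly Optional `genome_assembly`: used to check CDS bounds and
#'   to assign the mitochondrial code (`code_id = 3`) on contigs flagged
#'   `mito`.
#' @param origin Origin recorded on the models (default `"reference"`).
#' @return A `gene_models` table.
#' @export
read_gff <- function(path, assembly = NULL, origin = "reference") {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g, stringsAsFactors = FALSE)
  if (nrow(g) == 0) stop(sprintf("no features in %s", path))
  first_chr <- function(x) {
    vapply(x, function(v) {
      v <- as.character(unlist(v))
      if (length(v) == 0) NA_character_ else v[1]
    }, "")
  }
  ids <- if ("ID" %in% names(g)) first_chr(g$ID) else rep(NA_character_, nrow(g))
  parents <- if ("Parent" %in% names(g)) first_chr(g$Parent)
             else rep(NA_character_, nrow(g))
  type <- as.character(g$type)

  # pseudogene detection up the Parent chain
  type_of <- setNames(type, ids)
  parent_of <- setNames(parents, ids)
  attr_pseudo <- rep(FALSE, nrow(g))
  if ("pseudo" %in% names(g))
    attr_pseudo <- attr_pseudo | tolower(as.character(g$pseudo)) %in% "true"
  if ("gene_biotype" %in% names(g))
    attr_pseudo <- attr_pseudo |
      (!is.na(g$gene_biotype) & g$gene_biotype == "pseudogene")
  pseudo_ids <- unique(c(ids[type == "pseudogene"], ids[attr_pseudo]))
  pseudo_ids <- pseudo_ids[!is.na(pseudo_ids)]
  is_pseudo_ancestor <- function(id) {
    seen <- character(0)
    while (!is.na(id) && !id %in% seen) {
      if (id %in% pseudo_ids) return(TRUE)
      if (!is.na(type_of[id]) && identical(unname(type_of[id]), "pseudogene"))
        return(TRUE)
      seen <- c(seen, id)
      id <- if (id %in% names(parent_of)) parent_of[[id]] else NA_character_
    }
    FALSE
  }

  cds <- g[type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0) stop(sprintf("no CDS features in %s", path))
  cds_parent <- parents[type == "CDS"]
  cds_id <- ids[type == "CDS"]
  key <- ifelse(is.na(cds_parent), cds_id, cds_parent)
  if (anyNA(key)) stop("CDS feature without Parent or ID attribute")
  if (!all(cds$strand %in% c("+", "-")))
    stop(sprintf("unknown strand '%s' on a CDS feature",
                 as.character(cds$strand[!cds$strand %in% c("+", "-")][1])))

  keys <- unique(key)
  segments <- vector("list", length(keys))
  contig <- strand <- character(length(keys))
  pseudo <- logical(length(keys))
  for (i in seq_along(keys)) {
    rows <- cds[key == keys[i], , drop = FALSE]
    if (length(unique(as.character(rows$seqid))) != 1 ||
        length(unique(as.character(rows$strand))) != 1)
      stop(sprintf("CDS segments of '%s' disagree on contig or strand", keys[i]))
    contig[i] <- as.character(rows$seqid[1])
    strand[i] <- as.character(rows$strand[1])
    m <- cbind(start = rows$start, end = rows$end)
    m <- m[order(m[, "start"]), , drop = FALSE]
    if (nrow(m) > 1 && any(m[-1, "start"] <= m[-nrow(m), "end"]))
      stop(sprintf("overlapping CDS segments in model '%s'", keys[i]))
    if (strand[i] == "-") m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    segments[[i]] <- m
    pseudo[i] <- is_pseudo_ancestor(keys[i])
  }

  code_id <- rep(1L, length(keys))
  if (!is.null(assembly)) {
    bad <- !contig %in% names(assembly$contigs)
    if (any(bad))
      stop(sprintf("model '%s' lies on unknown contig '%s'",
                   keys[bad][1], contig[bad][1]))
    lens <- nchar(assembly$contigs)[contig]
    ends <- vapply(segments, function(m) max(m[, "end"]), 1)
    if (any(ends > lens))
      stop(sprintf("CDS of model '%s' extends past the end of contig '%s'",
                   keys[ends > lens][1], contig[ends > lens][1]))
    code_id[contig %in% assembly$mito] <- 3L
  }

  new_gene_models(id = keys, contig = contig, strand = strand,
                  segments = segments, code_id = code_id,
                  origin = origin, status = "complete", pseudo = pseudo)
}

#' Drop pseudogene-flagged models
#' @param models A `gene_models` table.
#' @return The table without `pseudo` models.
#' @export
drop_pseudogenes <- function(models) {
  out <- models[!models$pseudo, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Write gene models to GFF3
#'
#' Emits the `##gff-version 3` pragma, one `mRNA` row per model and its
#' `CDS` rows with `Parent` attributes, so that [read_gff()] round-trips.
#'
#' @param models A `gene_models` table.
#' @param path Output file.
#' @param source Value of the GFF source column.
#' @return `path`, invisibly.
#' @export
write_gff <- function(models, path, source = "yeastannot") {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    segs <- m$segments[[1]]
    lines <- c(lines,
      sprintf("%s\t%s\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;origin=%s",
              m$contig, source, m$start, m$end, m$strand, m$id, m$origin))
    phase_off <- 0L
    for (j in seq_len(nrow(segs))) {
      lines <- c(lines,
        sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s",
                m$contig, source, segs[j, "start"], segs[j, "end"],
                m$strand, (3L - phase_off %% 3L) %% 3L, m$id, m$id))
      phase_off <- phase_off + (segs[j, "end"] - segs[j, "start"] + 1L)
    }
  }
  writeLines(lines, path)
  invisible(path)
}
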