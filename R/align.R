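# Internal whole-genome aligner: exact k-mer anchor seeding on reference
# contigs, greedy chaining of co-diagonal anchor runs, global alignment of
# the short inter-anchor gaps (Biostrings), and ungapped X-drop extension of
# block ends. Adequate for assemblies within a few percent divergence of the
# reference, which is the regime the homology-transfer step targets; an
# external aligner can be substituted via read_alignment_blocks().
#
# A block stores a per-column correspondence as two integer vectors (r_col,
# q_col) ordered by ascending reference position; NA marks a gap. Query
# coordinates of minus-strand blocks are on the forward strand (and run
# descending along the columns).

.kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

.nuc_mat <- local({
  m <- NULL
  function() {
    if (is.null(m))
      m <<- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                     baseOnly = FALSE)
    m
  }
})

# exact anchor segments between two sequences (k-mers unique in reference)
.anchor_segments <- function(qseq, rseq, k) {
  rk <- .kmers(rseq, k)
  dup <- duplicated(rk) | duplicated(rk, fromLast = TRUE) | grepl("N", rk, fixed = TRUE)
  ruk <- rk[!dup]
  rupos <- which(!dup)
  if (!length(ruk)) return(NULL)
  qk <- .kmers(qseq, k)
  m <- match(qk, ruk)
  hit <- which(!is.na(m))
  if (!length(hit)) return(NULL)
  qpos <- hit
  rpos <- rupos[m[hit]]
  d <- qpos - rpos
  brk <- which(diff(qpos) != 1L | diff(d) != 0L)
  s <- c(1L, brk + 1L)
  e <- c(brk, length(qpos))
  data.frame(qs = qpos[s], qe = qpos[e] + k - 1L,
             rs = rpos[s], re = rpos[e] + k - 1L, diag = d[s])
}

# greedy chaining of anchor segments into block skeletons. Compatibility
# with the chain tail (gap and diagonal-shift limits) is decided on raw
# coordinates; small overlaps on near diagonals are then trimmed away. An
# isolated incompatible segment (a chance k-mer collision) is skipped when
# the following segment still continues the current chain, so spurious
# anchors neither break nor poison a chain.
.chain_segments <- function(seg, max_gap = 400L, max_dshift = 60L) {
  o <- order(seg$qs, seg$rs)
  qs <- seg$qs[o]; qe <- seg$qe[o]; rs <- seg$rs[o]; re <- seg$re[o]
  dg <- seg$diag[o]
  n <- length(qs)
  compatible <- function(i, last) {
    if (abs(dg[i] - dg[last]) > max_dshift) return(FALSE)
    qgap <- qs[i] - qe[last] - 1L
    rgap <- rs[i] - re[last] - 1L
    qgap <= max_gap && rgap <= max_gap &&
      qgap >= -(qe[i] - qs[i]) && rgap >= -(re[i] - rs[i])
  }
  chains <- list()
  cur <- integer(0)
  flush <- function() {
    if (length(cur))
      chains[[length(chains) + 1L]] <<- data.frame(
        qs = qs[cur], qe = qe[cur], rs = rs[cur], re = re[cur])
  }
  last <- 0L
  for (i in seq_len(n)) {
    if (last == 0L) { cur <- i; last <- i; next }
    if (!compatible(i, last)) {
      # lookahead: drop an isolated off-diagonal segment
      if (i < n && compatible(i + 1L, last)) next
      flush(); cur <- i; last <- i
      next
    }
    # trim overlaps against the chain tail (shared anchor sequence)
    if (qs[i] <= qe[last]) {
      tr <- qe[last] - qs[i] + 1L
      qs[i] <- qs[i] + tr; rs[i] <- rs[i] + tr
    }
    if (qs[i] <= qe[i] && rs[i] <= re[last]) {
      tr <- re[last] - rs[i] + 1L
      rs[i] <- rs[i] + tr; qs[i] <- qs[i] + tr
    }
    if (qs[i] > qe[i] || rs[i] > re[i] || rs[i] <= re[last] || qs[i] <= qe[last])
      next
    cur <- c(cur, i)
    last <- i
  }
  flush()
  chains
}

# ungapped X-drop extension; returns number of columns to extend
.xdrop_extend <- function(qch, rch, q0, r0, dirn, xdrop = 12L, cap = 2000L) {
  best <- 0L; best_n <- 0L; sc <- 0L; n <- 0L
  repeat {
    qi <- q0 + dirn * (n + 1L); ri <- r0 + dirn * (n + 1L)
    if (qi < 1L || ri < 1L || qi > length(qch) || ri > length(rch)) break
    n <- n + 1L
    sc <- sc + if (qch[qi] == rch[ri]) 1L else -3L
    if (sc > best) { best <- sc; best_n <- n }
    if (sc < best - xdrop || n >= cap) break
  }
  best_n
}

# build the per-column correspondence for one chain
.block_from_chain <- function(chain, qseq, rseq, qch, rch) {
  rcols <- list(); qcols <- list(); ci <- 0L
  add <- function(r, q) { ci <<- ci + 1L; rcols[[ci]] <<- r; qcols[[ci]] <<- q }
  for (i in seq_len(nrow(chain))) {
    if (i > 1) {
      pq <- chain$qe[i - 1L]; pr <- chain$re[i - 1L]
      nq <- chain$qs[i]; nr <- chain$rs[i]
      qg <- nq - pq - 1L; rg <- nr - pr - 1L
      if (qg > 0L && rg == 0L) {
        add(rep(NA_integer_, qg), (pq + 1L):(nq - 1L))
      } else if (rg > 0L && qg == 0L) {
        add((pr + 1L):(nr - 1L), rep(NA_integer_, rg))
      } else if (qg > 0L && qg == rg && qg <= 40L) {
        # equal-length short gap between exact anchors: a substitution run,
        # no indel placement needed
        add((pr + 1L):(nr - 1L), (pq + 1L):(nq - 1L))
      } else if (qg > 0L && rg > 0L) {
        pw <- Biostrings::pairwiseAlignment(
          substr(qseq, pq + 1L, nq - 1L), substr(rseq, pr + 1L, nr - 1L),
          type = "global", substitutionMatrix = .nuc_mat(),
          gapOpening = 5, gapExtension = 2)
        pg <- strsplit(as.character(Biostrings::alignedPattern(pw)), "")[[1]]
        sg <- strsplit(as.character(Biostrings::alignedSubject(pw)), "")[[1]]
        rr <- qq <- integer(length(pg))
        qi <- pq; ri <- pr
        for (j in seq_along(pg)) {
          if (pg[j] != "-") { qi <- qi + 1L; qq[j] <- qi } else qq[j] <- NA_integer_
          if (sg[j] != "-") { ri <- ri + 1L; rr[j] <- ri } else rr[j] <- NA_integer_
        }
        add(rr, qq)
      }
    }
    add(chain$rs[i]:chain$re[i], chain$qs[i]:chain$qe[i])
  }
  r_col <- unlist(rcols); q_col <- unlist(qcols)
  # extend both ends, ungapped
  nL <- .xdrop_extend(qch, rch, chain$qs[1], chain$rs[1], -1L)
  if (nL > 0L) {
    r_col <- c((chain$rs[1] - nL):(chain$rs[1] - 1L), r_col)
    q_col <- c((chain$qs[1] - nL):(chain$qs[1] - 1L), q_col)
  }
  nE <- nrow(chain)
  nR <- .xdrop_extend(qch, rch, chain$qe[nE], chain$re[nE], 1L)
  if (nR > 0L) {
    r_col <- c(r_col, (chain$re[nE] + 1L):(chain$re[nE] + nR))
    q_col <- c(q_col, (chain$qe[nE] + 1L):(chain$qe[nE] + nR))
  }
  list(r_col = r_col, q_col = q_col)
}

#' Align a query assembly against a reference assembly
#'
#' Produces local alignment blocks with a full per-column correspondence,
#' which the transfer step uses for its no-indel test. Minus-strand hits are
#' reported with query coordinates on the forward strand and `strand = "-"`.
#'
#' @param query,reference `genome_assembly` objects.
#' @param min_block_len Minimum reference span of a reported block (bp).
#' @param min_identity Minimum percent identity (identical columns over
#'   columns with a residue in both sequences).
#' @param k Anchor k-mer size.
#' @return List of blocks (class `alignment_blocks`); each block is a list
#'   with `q_contig`, `r_contig`, `strand`, `q_start`, `q_end`, `r_start`,
#'   `r_end`, `identity`, `r_col`, `q_col`.
#' @export
align_genomes <- function(query, reference, min_block_len = 100L,
                          min_identity = 90, k = 13L) {
  if (length(query$contigs) == 0 || length(reference$contigs) == 0)
    stop("both assemblies must be non-empty")
  blocks <- list()
  rchars <- lapply(reference$contigs, function(s) strsplit(s, "")[[1]])
  for (qc in names(query$contigs)) {
    qfwd <- query$contigs[[qc]]
    Lq <- nchar(qfwd)
    for (ori in c("+", "-")) {
      qseq <- if (ori == "+") qfwd else revcomp(qfwd)
      qch <- strsplit(qseq, "")[[1]]
      for (rc in names(reference$contigs)) {
        rseq <- reference$contigs[[rc]]
        seg <- .anchor_segments(qseq, rseq, k)
        if (is.null(seg)) next
        for (chain in .chain_segments(seg)) {
          bl <- .block_from_chain(chain, qseq, rseq, qch, rchars[[rc]])
          both <- !is.na(bl$r_col) & !is.na(bl$q_col)
          nmatch <- sum(qch[bl$q_col[both]] == rchars[[rc]][bl$r_col[both]])
          identity <- 100 * nmatch / sum(both)
          r_rng <- range(bl$r_col, na.rm = TRUE)
          if (r_rng[2] - r_rng[1] + 1L < min_block_len) next
          if (identity < min_identity) next
          q_col <- bl$q_col
          if (ori == "-") q_col <- ifelse(is.na(q_col), NA_integer_, Lq - q_col + 1L)
          q_rng <- range(q_col, na.rm = TRUE)
          blocks[[length(blocks) + 1L]] <- list(
            q_contig = qc, r_contig = rc, strand = ori,
            q_start = q_rng[1], q_end = q_rng[2],
            r_start = r_rng[1], r_end = r_rng[2],
            identity = identity, r_col = bl$r_col, q_col = q_col)
        }
      }
    }
  }
  structure(blocks, class = "alignment_blocks")
}

#' Read alignment blocks from an external aligner (adapter contract)
#'
#' Tab-separated input with columns `q_contig`, `r_contig`, `strand`,
#' `q_start`, `q_end`, `r_start`, `r_end`, `identity`, `cigar`, where
#' `cigar` is a run-length string over the states `M` (match/mismatch), `I`
#' (insertion in the query) and `D` (deletion from the query), written along
#' the reference. Query coordinates of minus-strand rows are forward-strand.
#'
#' @param path TSV file.
#' @return An `alignment_blocks` list equivalent to [align_genomes()] output.
#' @export
read_alignment_blocks <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  blocks <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    ops <- regmatches(row$cigar, gregexpr("[0-9]+[MID]", row$cigar))[[1]]
    len <- as.integer(sub("[MID]", "", ops))
    op <- sub("[0-9]+", "", ops)
    r_col <- q_col <- integer(0)
    ri <- row$r_start - 1L
    qi <- if (row$strand == "+") row$q_start - 1L else row$q_end + 1L
    dq <- if (row$strand == "+") 1L else -1L
    for (j in seq_along(op)) {
      n <- len[j]
      if (op[j] == "M") {
        r_col <- c(r_col, (ri + 1L):(ri + n))
        q_col <- c(q_col, seq(qi + dq, by = dq, length.out = n))
        ri <- ri + n; qi <- qi + dq * n
      } else if (op[j] == "I") {
        r_col <- c(r_col, rep(NA_integer_, n))
        q_col <- c(q_col, seq(qi + dq, by = dq, length.out = n))
        qi <- qi + dq * n
      } else {
        r_col <- c(r_col, (ri + 1L):(ri + n))
        q_col <- c(q_col, rep(NA_integer_, n))
        ri <- ri + n
      }
    }
    list(q_contig = row$q_contig, r_contig = row$r_contig, strand = row$strand,
         q_start = row$q_start, q_end = row$q_end,
         r_start = row$r_start, r_end = row$r_end,
         identity = row$identity, r_col = r_col, q_col = q_col)
  })
  structure(blocks, class = "alignment_blocks")
}
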