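# fixture: 120 bp contig, one 60 bp gene at [31,90] on the plus strand
# (ATG, 18 x GCT, TAA), controllable start/stop/internal codons and tail
repair_fixture <- function(start_codon = "ATG", stop_codon = "TAA",
                           internal = "GCT", tail_stop_at = NULL,
                           upstream_atg = TRUE) {
  up <- paste0(strrep("C", 24), if (upstream_atg) "ATG" else "CCC", "AAA")
  body <- rep("GCT", 18)
  body[11] <- internal                       # codon at positions 61-63
  gene <- paste0(start_codon, paste(body, collapse = ""), stop_codon)
  down_codons <- rep("AAA", 10)
  if (!is.null(tail_stop_at)) down_codons[tail_stop_at] <- "TAA"
  asm <- new_assembly(c(chr = paste0(up, gene, paste(down_codons, collapse = ""))),
                      tag = "FIX")
  cand <- new_gene_models(id = "c1", contig = "chr", strand = "+",
                          segments = list(matrix(c(31L, 90L), ncol = 2)),
                          origin = "blastn", status = "candidate",
                          parent = "g1")
  list(assembly = asm, candidate = cand)
}

test_that("a mutated stop codon is repaired by in-frame downstream extension", {
  fx <- repair_fixture(stop_codon = "CAA", tail_stop_at = 3) # stop 9 bp down
  out <- repair_model(fx$candidate, fx$assembly)
  expect_identical(out$status, "complete")
  expect_equal(out$model$end, 99)
  expect_equal(out$model$start, 31)
  expect_identical(out$log, "stop_shift+9")
  tr <- translate_cds(model_cds(fx$assembly, out$model[1, ]), 1)
  expect_true(tr$stop_terminated)
  expect_false(tr$internal_stop)
})

test_that("a mutated start codon is repaired from the nearest upstream ATG", {
  fx <- repair_fixture(start_codon = "ACG")
  out <- repair_model(fx$candidate, fx$assembly)
  expect_identical(out$status, "complete")
  expect_equal(out$model$start, 25)
  expect_equal(out$model$end, 90)
  expect_identical(out$log, "start_shift-6")
})

test_that("without an upstream ATG the start is searched downstream", {
  # no upstream ATG; the first in-frame ATG downstream of the original
  # start is the GCT-run end? none exists, so plant one at codon 4
  fx <- repair_fixture(start_codon = "ACG", upstream_atg = FALSE)
  seq <- fx$assembly$contigs[["chr"]]
  substr(seq, 40, 42) <- "ATG"              # in-frame, +9 from position 31
  fx$assembly$contigs[["chr"]] <- seq
  out <- repair_model(fx$candidate, fx$assembly)
  expect_identical(out$status, "complete")
  expect_equal(out$model$start, 40)
  expect_identical(out$log, "start_shift+9")
})

test_that("an internal in-frame stop marks the model as a pseudogene", {
  fx <- repair_fixture(internal = "TAA")
  out <- repair_model(fx$candidate, fx$assembly)
  expect_identical(out$status, "discarded_pseudo")
})

test_that("a model with no reachable stop codon is discarded", {
  fx <- repair_fixture(stop_codon = "CAA")   # tail has no stop before the end
  out <- repair_model(fx$candidate, fx$assembly)
  expect_identical(out$status, "discarded_no_codon")
})

test_that("repair arithmetic mirrors correctly on the minus strand", {
  fx <- repair_fixture(stop_codon = "CAA", tail_stop_at = 3)
  L <- nchar(fx$assembly$contigs[["chr"]])
  rc <- new_assembly(c(chr = revcomp(fx$assembly$contigs[["chr"]])),
                     tag = "FIXRC")
  cand <- new_gene_models(id = "c1", contig = "chr", strand = "-",
                          segments = list(matrix(c(L - 90L + 1L, L - 31L + 1L),
                                                 ncol = 2)),
                          origin = "blastn", status = "candidate",
                          parent = "g1")
  out <- repair_model(cand, rc)
  expect_identical(out$status, "complete")
  expect_equal(out$model$start, L - 99L + 1L)  # stop extension, lower coord
  expect_identical(out$log, "stop_shift+9")
})

test_that("transfer requires full single-block coverage with no indels", {
  ref <- make_reference(n_genes = 6, n_contigs = 1, seed = 31)
  m <- ref$models[3, ]
  # 1 bp deletion inside the model span
  seq <- ref$assembly$contigs[[1]]
  delpos <- m$start + 30L
  mut <- paste0(substr(seq, 1, delpos - 1), substr(seq, delpos + 1, nchar(seq)))
  q <- new_assembly(setNames(mut, names(ref$assembly$contigs)), tag = "DEL1")
  s1 <- annotate_step1(q, ref$assembly, ref$models)
  expect_false(m$id %in% s1$models$parent)
  expect_setequal(setdiff(ref$models$id, m$id),
                  s1$models$parent[!is.na(s1$models$parent)])
})

test_that("substitution-only queries transfer exactly the truth set", {
  ref <- make_reference(n_genes = 30, seed = 32)
  q <- make_query(ref$assembly, ref$models, sub_rate = 0.005, indel_rate = 0,
                  seed = 33)
  blocks <- align_genomes(q$assembly, ref$assembly)
  cands <- transfer_models(blocks, ref$models, q$assembly)
  expect_setequal(unique(cands$parent), q$truth$expected_transferable)
})

test_that("transferred proteins may differ by the substituted residues", {
  ref <- make_reference(n_genes = 4, n_contigs = 1, seed = 34)
  m <- ref$models[2, ]
  seq <- ref$assembly$contigs[[1]]
  # one substitution at the first base of codon 2 (transcription order);
  # flipping that base to/from G always changes the amino acid and can
  # never create a stop codon
  p <- if (m$strand == "+") m$start + 3L else m$end - 3L
  base <- substr(seq, p, p)
  new <- if (m$strand == "+") {
    if (base == "G") "A" else "G"
  } else {                      # complemented strand: G in mRNA is C here
    if (base == "C") "T" else "C"
  }
  substr(seq, p, p) <- new
  q <- new_assembly(setNames(seq, names(ref$assembly$contigs)), tag = "SUB1")
  s1 <- annotate_step1(q, ref$assembly, ref$models)
  expect_true(m$id %in% s1$models$parent)
  got <- s1$models[s1$models$parent == m$id, ]
  ref_prot <- translate_cds(model_cds(ref$assembly, m), 1)$protein
  new_prot <- translate_cds(model_cds(q, got[1, ]), got$code_id[1])$protein
  expect_equal(nchar(ref_prot), nchar(new_prot))
  expect_equal(sum(strsplit(ref_prot, "")[[1]] != strsplit(new_prot, "")[[1]]), 1)
})

test_that("masking replaces exactly the model spans and conserves length", {
  asm <- new_assembly(c(c1 = strrep("A", 30)), tag = "M")
  one <- new_gene_models("x", "c1", "+", list(matrix(c(10L, 18L), ncol = 2)))
  masked <- mask_regions(asm, one)
  expect_equal(nchar(masked$contigs[[1]]), 30)
  expect_equal(sum(strsplit(masked$contigs[[1]], "")[[1]] == "N"), 9)
  expect_identical(substr(masked$contigs[[1]], 10, 18), strrep("N", 9))

  two <- new_gene_models(c("x", "y"), c("c1", "c1"), c("+", "+"),
                         list(matrix(c(10L, 18L), ncol = 2),
                              matrix(c(15L, 22L), ncol = 2)))
  masked2 <- mask_regions(asm, two)
  expect_equal(sum(strsplit(masked2$contigs[[1]], "")[[1]] == "N"), 13)

  expect_identical(mask_regions(asm, empty_gene_models()), asm)
})

test_that("step-1 self-annotation reproduces the reference models exactly", {
  ref <- make_reference(n_genes = 30, seed = 35)
  s1 <- annotate_step1(ref$assembly, ref$assembly, ref$models)
  expect_equal(nrow(s1$models), nrow(ref$models))
  expect_setequal(s1$models$parent, ref$models$id)
  got <- s1$models[match(ref$models$id, s1$models$parent), ]
  expect_equal(got$contig, ref$models$contig)
  expect_equal(got$strand, ref$models$strand)
  expect_equal(got$segments, ref$models$segments, ignore_attr = TRUE)
  # every position of every model is masked afterwards
  for (i in seq_len(nrow(ref$models))) {
    sp <- substr(s1$masked$contigs[[ref$models$contig[i]]],
                 ref$models$start[i], ref$models$end[i])
    expect_identical(sp, strrep("N", nchar(sp)))
  }
})

test_that("a duplicated haplotype yields each model at two loci", {
  ref <- make_reference(n_genes = 10, seed = 36)
  q <- make_query(ref$assembly, ref$models, sub_rate = 0, indel_rate = 0,
                  duplicate = TRUE, seed = 37)
  s1 <- annotate_step1(q$assembly, ref$assembly, ref$models)
  per_parent <- table(s1$models$parent)
  expect_true(all(per_parent == 2))
  expect_equal(nrow(s1$models), 2 * nrow(ref$models))
})

test_that("kept models always satisfy the coding-model contract", {
  ref <- make_reference(n_genes = 25, seed = 38)
  q <- make_query(ref$assembly, ref$models, sub_rate = 0.015,
                  indel_rate = 5e-4, n_breaks = 2, seed = 39)
  s1 <- annotate_step1(q$assembly, ref$assembly, ref$models)
  for (i in seq_len(nrow(s1$models))) {
    tr <- translate_cds(model_cds(q$assembly, s1$models[i, ]),
                        s1$models$code_id[i])
    expect_true(tr$stop_terminated)
    expect_false(tr$internal_stop)
  }
  # masking conserves genome size
  expect_equal(genome_size(s1$masked), genome_size(q$assembly))
  # discard log covers every candidate not kept
  expect_setequal(s1$log$status[s1$log$status != "complete"],
                  unique(s1$log$status[!s1$log$id %in% s1$models$id]))
})
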