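#!/usr/bin/env Rscript
# Worked example on the real S288c reference assembly (RefSeq
# GCF_000146045.2). Requires a one-time download (~12 MB compressed):
#
#   base=https://ftp.ncbi.nlm.nih.gov/genomes/all/GCF/000/146/045/GCF_000146045.2_R64
#   curl -L -o s288c/GCF_000146045.2_R64_genomic.fna.gz $base/GCF_000146045.2_R64_genomic.fna.gz
#   curl -L -o s288c/GCF_000146045.2_R64_genomic.gff.gz $base/GCF_000146045.2_R64_genomic.gff.gz
#   gunzip s288c/*.gz
#
# usage: Rscript scripts/s288c_example.R <dir-with-unpacked-files>
#
# Expected values: genome size 12,157,105 bp; 6,002 pseudogene-excluded
# reference models with mean coding length 1,468 bp; step-1 self-annotation
# transfers all 6,002; single-genome family counts near 5,010 (cutoff 50)
# and 5,740 (cutoff 90).

suppressPackageStartupMessages(library(yeastannot))

dir <- commandArgs(trailingOnly = TRUE)[1]
if (is.na(dir)) stop("usage: Rscript scripts/s288c_example.R <data-dir>")
fa <- file.path(dir, "GCF_000146045.2_R64_genomic.fna")
gff <- file.path(dir, "GCF_000146045.2_R64_genomic.gff")

asm <- read_fasta(fa, tag = "S288C", mito = "NC_001224.1")
cat(sprintf("genome size: %d bp\n", genome_size(asm)))

models <- drop_pseudogenes(read_gff(gff, asm))
cat(sprintf("pseudogene-excluded models: %d\n", nrow(models)))
cat(sprintf("mean coding length: %.0f bp\n", mean(model_cds_length(models))))

bm <- run_benchmark(asm, models, mode = "step1")
cat(sprintf("step-1 self-annotation: recall %.1f%%, %d models produced\n",
            bm$recall, bm$n_produced))

prot <- model_proteins(models, asm)
prot$origin <- "reference"
series <- build_scf(prot, cutoffs = c(50, 90))
for (nm in names(series))
  cat(sprintf("%s: %d families\n", nm,
              length(unique(series[[nm]]$members$family))))
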