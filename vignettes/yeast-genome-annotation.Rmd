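---
title: "Methods: reference-guided annotation, gene families, and pangenome statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-guided annotation, gene families, and pangenome statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`yeastannot` implements the computational core of a large-scale
*Saccharomyces cerevisiae* genome annotation effort: a two-step
protein-coding annotation pipeline for draft assemblies, multi-cutoff
single-linkage protein family clustering, a marker-gene framework for
genome completeness and base-quality evaluation, pangenome
classification, and rank-based detection of families whose homolog
numbers differ between strain groups. Everything is testable offline
against a synthetic genome simulator with full ground truth.

# The two-step annotation model

Draft yeast assemblies are typically highly similar to the S288c
reference over most of their length. The pipeline exploits this:

**Step 1 (homology transfer).** The query is aligned to the reference
genome, and every complete reference gene model whose full genomic span
falls inside a single alignment block *with no insertions or deletions
over the span* is copied onto the query through the per-column
correspondence of that block ("blastn-models"). The no-indel rule is the
load-bearing assumption: under it the reading frame of the copied model
is preserved exactly, so only the terminal codons can be wrong. The
transferred candidates are then codon-repaired:

* a mutated stop codon is repaired by scanning downstream, in frame, for
  the first stop codon within a 300 bp window;
* a mutated start codon is repaired by scanning upstream, in frame, for
  the first ATG, aborting at an in-frame stop codon or the contig edge,
  then — if that fails — downstream within the model;
* a model that cannot be repaired is discarded (`discarded_no_codon`);
* a repaired model with an in-frame stop in its interior is treated as a
  pseudogenised copy and discarded (`discarded_pseudo`).

The 300 bp window bounds the distance between the first base of the
original codon and the first base of its replacement. Start codons are
ATG only: the repair literature sometimes admits near-cognate starts,
but ATG-only is the conservative choice for a transfer pipeline whose
candidates already carry a reference-supported ATG; the codon set is an
argument-level constant in `repair_model()` should that ever change.

Regions covered by kept blastn-models are then masked with `N`
(`mask_regions()`), so step 2 only sees sequence that step 1 could not
explain.

**Step 2 (backfill prediction).** On the masked assembly an external
gene predictor can be used through a GFF3 adapter
(`read_external_predictions()`); the package also ships an internal
six-frame ORF caller (`predict_orfs()`) so that the full two-step
architecture runs and is tested without external binaries. The internal
caller reports maximal ATG…stop frames that never overlap an `N`
position, resolving nested ORFs to the longest per stop codon. Models
shorter than 15 aa are removed (`filter_short()`, strict `<`); the
threshold is shared with the ORF caller's minimum so the two stages
agree. Step-1 and step-2 models are pooled without deduplication
(`merge_models()`), and the maker-model ratio (backfilled models over
total) serves downstream as a proxy for dissimilarity to the reference
or poor sequence quality.

Translation uses NCBI table 1, or table 3 on contigs designated
mitochondrial; designation is a per-contig attribute of the assembly
(`new_assembly(mito = ...)`) because mitochondrial status is an input
fact, not something the annotation should re-derive per gene.

## The internal aligner

`align_genomes()` is an anchor aligner: exact k-mers (default k = 13)
unique within a reference contig seed anchors, co-diagonal anchor runs
are chained greedily (gap limit 400 bp, diagonal-shift limit 60 bp),
inter-anchor gaps are aligned globally with Biostrings, and block ends
are extended by ungapped X-drop. Two numerical choices matter:

* an isolated anchor that is incompatible with the current chain is
  *skipped* when the following anchor still continues the chain — a
  chance 13-mer collision must neither break a chain nor poison the
  overlap trimming;
* equal-length inter-anchor gaps of at most 40 bp are treated as
  substitution runs without invoking the aligner; a compensating indel
  pair inside such a short gap would be mapped as mismatches, which is
  the behaviour a transfer pipeline wants (net colinearity), and the
  cost of the general case would be three orders of magnitude more
  alignment calls.

The aligner targets the few-percent-divergence regime of conspecific
assemblies. For distant genomes an external whole-genome aligner can be
substituted through the tabular `read_alignment_blocks()` contract
(per-column `M`/`I`/`D` states, minus-strand query coordinates on the
forward strand); the transfer step is agnostic to the block producer.

Where several blocks cover a reference model at the same query locus,
the highest-identity block wins (ties: longer block, then lexicographic
contig id). A model spanning two abutting blocks is *not* transferred:
chained coverage cannot certify the absence of an indel at the junction,
so the conservative single-block reading of the no-indel rule is used. A
reference model may still be transferred at several distinct query loci
(duplicated regions, phased diploid assemblies).

# Gene families

Families are built per *cluster cutoff* — a single percentage applied
simultaneously to identity and to the alignment coverage of **both**
sequences, all strictly (`>`). Coverage is enforced symmetrically: the
similarity relation then stays symmetric, which single linkage requires
to be well defined; a shorter-sequence-only coverage variant would make
"a covers b" and "b covers a" diverge.

The two-step procedure mirrors how the annotation was produced:

1. reference proteins are single-linkage clustered at the cutoff;
2. blastn proteins join the family of their reference parent model — by
   construction they are near-copies, so re-aligning them would only
   re-derive the parentage;
3. maker proteins with a qualifying reference hit join the family of
   their best hit (highest identity, then coverage, then id);
4. remaining maker proteins are clustered among themselves;
5. initial families whose longest-sequence representatives match above
   `cutoff − 10` (percentage points, strict) are compared
   member-against-member, and families with any member pair qualifying
   at the full cutoff are merged by single linkage over the family
   graph.

Union-find with path halving and sorted edge processing makes every
clustering step deterministic. Family ids are `SCF<cutoff>_<5-digit>`,
assigned in order of each family's smallest member id — deterministic,
though not guaranteed to coincide with ids of any externally produced
table. `build_scf()` computes the all-versus-all similarity search once
and reuses the edge table across cutoffs and merge stages; the search
is the expensive part, the thresholding is not. With the prefilter
disabled, the procedure provably equals connected components of the
thresholded similarity graph, which the test suite checks against an
independent igraph oracle on random protein sets.

# Markers, completeness, base quality

From family series at cutoffs 50–90 restricted to a high-quality genome
subset, a marker family must, in *every* series: (i) be present in all
genomes, (ii) be single-copy in every genome, (iii) have minimum
pairwise global identity ≥ 90%, (iv) have alignment length ≤ 1.05 times
the reference member's length, and (v) have a reference member of
≥ 200 aa. The final marker set is keyed by the reference (S288c)
protein.

The internal alignment backend is a reference-anchored star alignment:
each member is aligned globally to the reference member and insertion
columns are merged. Under this construction the member-to-reference
identities equal the pairwise global identities, and the alignment
length used in criterion (iv) is the reference length plus merged
insertions. Identity is always computed over columns where both
sequences hold a residue (mutually resolved columns) — end gaps from
truncated proteins reduce coverage, not identity, which keeps the
base-quality statistic interpretable for fragmented assemblies.

*Completeness* of a genome is the percentage of marker families with at
least one member from it. *Base quality* is the mean identity of the
genome's marker homologs to their reference counterparts, taking the
best homolog when a family has several members from one genome. Both
means run over families with at least one member: absent families are a
completeness signal and folding them into the identity mean would
conflate the two axes.

Genome subsets follow fixed thresholds: high quality = contig number
< 100, N50 > 500 kb, maker-model ratio < 33.33%, one assembly per
strain; medium-high quality = identity to the reference ≥ 98.72%,
contig number < 600, completeness > 96%. The one-per-strain ranking
(completeness, then N50, then fewest contigs, then lexicographic tag)
is a package choice — any deterministic preference for the better
assembly serves; the comparator is exposed through the report columns.

# Pangenome and group statistics

Families are classified by presence fraction *f* across genomes:
extended core (*f* ≥ 0.95), accessory (*f* ≤ 0.05), character
(otherwise). The boundary value 0.95 satisfies both the core and the
character reading; the core test is applied first, matching the
convention that "present in ≥ 95%" defines the extended core.

For inter-group comparison, per-genome homolog counts (0 for genomes
absent from a family — presence/absence differences must be able to
register) are tested per family with the Kruskal-Wallis H test
(`stats::kruskal.test`; all-identical input short-circuits to H = 0,
p = 1). Families passing the p < 0.05 gate go to Dunn's post hoc z test
(implemented in the package; no Dunn implementation ships with the
pre-installed R stack), and a group pair is significant when its Dunn
p < 0.05 *and* the absolute difference in mean homolog number exceeds
0.5. No multiplicity adjustment is applied by default, mirroring the
stated two-stage gate; Holm or any `p.adjust` method can be switched on
per call. A permutation control (`randomized_control()`) re-labels
genomes uniformly, preserving group sizes, and records flagged-family
counts per replicate.

Marker alignments for phylogeny are concatenated in sorted family order
with one row per genome (best-identity homolog); tree inference itself
is out of scope and left to external tools on the exported FASTA.

# The synthetic data generator

`make_reference()` emits an intronless genome: single-exon ATG…stop
genes with no internal stop, both strands, fixed-length random
intergenic spacers, distributed over a few contigs, optionally with a
mitochondrial contig carrying table-3 genes. Defaults — 200 genes of
mean length 1,470 bp (matching the mean coding length of the S288c
reference models) separated by 300 bp spacers over 4 contigs — give a
~360 kb genome with yeast-like gene density, large enough that anchor
seeding, chaining and repair are all exercised, small enough that the
full pipeline runs in seconds. `make_query()` derives queries by
uniform substitutions, 1–3 bp indels, contig fragmentation, and an
optional second mutated haplotype, recording every edit in reference
coordinates. Indels are capped at 3 bp: enough to violate the no-indel
transfer rule, without turning alignment fixtures into spliced-mapping
problems.

The truth object lists `expected_transferable` — models whose span
contains no indel *and* no fragmentation breakpoint (either one defeats
single-block coverage) — plus models whose substitutions alone disrupt
start, stop, or interior (pseudogene-discard labels), and per-model copy
numbers under duplication.

What the simulator does *not* emulate: realistic mutation spectra,
recombination, transposons, introns, subtelomeric repeat families, and
sequencing-error indel hotspots. Passing tests therefore demonstrate
correctness of the pipeline's logic under its stated assumptions, not
robustness to every artefact of real draft assemblies; the S288c worked
example (`scripts/s288c_example.R`) exists to anchor the pipeline on
real data where a download is possible.

# Conventions and degenerate inputs

* Coordinates are 1-based inclusive throughout (the native GFF3 and
  IRanges convention); segment lists are kept in transcription order,
  so minus-strand models list segments by descending start.
* Sequences are uppercased on input, RNA `U` becomes `T`, and ambiguity
  codes other than `N` are rejected at read time — the codon tests in
  repair and ORF calling assume `{A,C,G,T,N}`.
* Codons containing `N` translate to `X`; in the ORF caller they act as
  barriers, so predictions never overlap masked positions.
* Empty model sets, absent families, and all-identical count vectors
  all have defined behaviour (empty tables, `NaN` means where a mean
  has no support, H = 0/p = 1).
* Every stochastic routine takes an explicit seed; identical seeds give
  byte-identical outputs, which the CLI tests assert on written files.

# Problem sizes in the shipped tests

The suite validates the aligner and liftover on 8–30-gene genomes, the
acceptance benchmark on the 200-gene default, the clustering oracle on
50 random protein sets of up to ~100 proteins against an igraph
oracle, divergence recovery on 200-marker cohorts at 0.2–2% amino-acid
divergence, and the group statistics on 1,000 simulated null families
with 40 genomes. These sizes were chosen so each property is measured
with enough support to be meaningful while the whole suite stays quick
to run during development.

# Known limitations

* The internal aligner is not a general whole-genome aligner: diverged
  (> ~5%) or heavily rearranged genomes need an external backend via
  the block adapter.
* Multi-exon models are carried through the data model and transfer,
  but the no-indel rule is applied over the full genomic span including
  introns (config-free, conservative), and start-codon downstream
  rescue scans only within the first segment.
* The star alignment backend approximates a true multiple alignment;
  criterion (iii) is therefore computed from exact pairwise global
  alignments rather than from star columns.
* `build_scf()` memoises the full all-versus-all search, which is
  quadratic in total protein count; cohorts beyond a few thousand
  proteins should bring an external search backend's edge table.
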