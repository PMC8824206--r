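---
title: "Mining polyphenol utilization proteins and their gene clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining polyphenol utilization proteins and their gene clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupminer)
```

## The problem

Gut bacteria carry polyphenol utilization proteins (PUPs): enzymes that
hydrolyse, reduce, transfer, cleave or isomerise dietary polyphenols into
metabolites the host can absorb. Experimentally characterized PUPs ("seeds")
are scarce — 60 proteins across 26 families in the packaged catalog — so
most of what can be said about polyphenol metabolism in a genome or
metagenome comes from homology: find seed homologs, check whether their
genes cluster on the chromosome the way operons for coordinated catabolism
do, and propagate substrate knowledge from seeds to clusters.

`pupminer` implements that chain as composable stages: domain-hit filtering
and signature-based family annotation, physical gene-cluster detection,
majority-vote substrate inference, similarity-network subfamily calling,
genome-collection profiling, domain enrichment, and read-level metagenome
profiling. This vignette explains the models and the choices behind them.

## The catalog and signature derivation

A PUP family is named by an enzyme-class prefix derived from the first EC
digit — OR (oxidation/reduction), FR (group transfer), HR (hydrolysis),
NCR (nonhydrolytic cleavage), IR (isomerization) — plus UC for two families
whose seeds have no Pfam domain at all. Each non-UC family has a *signature*:
a Pfam domain or an all-required multidomain combination. `derive_signature()`
encodes the selection rules: a single-domain seed contributes its domain;
members sharing an identical multidomain architecture contribute the
combination; members sharing only one domain contribute that domain; and
non-enzymatic accessory domains are removed first. "Enzymatic" is a human
judgment in the source material, so it is operationalized as an explicit
allowlist argument rather than a heuristic.

The packaged table (`pup_catalog_path()`) transcribes the 26 families with
their signatures, seed counts and homolog counts per source database. Its
*substrate* column is deliberately synthetic: the per-seed substrate table
is not part of the transcription, and inventing family–substrate pairs
would contaminate downstream inference. The placeholder labels are clearly
marked in the file header; every substrate-logic test builds a small catalog
in code with real substrate names (daidzin, luteolin, genistein, ...).

UC families carry no signature; their members arrive via iterative
similarity search. The package treats search execution as out of process:
it consumes the final-round hit table and applies the E < 0.001 rule, so no
external database is required to run or test.

## Domain-hit filtering and family assignment

Hits come from the per-domain tabular output of profile-HMM search. Coverage
is defined as the HMM-coordinate span over the HMM length — the alignment
length measured on the model — and the independent per-domain E-value is
used. Thresholds are strict inequalities, matching how they are printed in
the sources that state them: E < 1e-5 with coverage > 0.3 when curating
seeds, > 0.6 when recruiting homologs. A hit at exactly 1e-5 is rejected.

Overlap resolution (needed because profile searches report nested and
overlapping hits) keeps the lower-E-value hit whenever two hits share more
than half of the shorter alignment; ties break by longer alignment, then
lexicographic domain name, so results are deterministic.

Assignment requires the *complete* signature: a protein with only `HpaB`
is not an `HpaB+HpaB_N` family member. Domains need not be adjacent,
ordered, or the protein's best hit — presence is the criterion. A protein
matching several signatures receives every family, flagged `multi_family`,
because no exclusivity rule is stated in the source material and silently
picking one would bias cluster-level substrate votes.

## PGC detection

Genes are read from GFF3 (1-based inclusive coordinates, `CDS` features by
default, via `rtracklayer`), ordered per contig by start. A PUP gene
cluster must satisfy three rules: at least two PUP genes; at most three
non-PUP genes between adjacent PUP genes; every intergenic gap under 1 kb.
Numerical choices:

* The intergenic gap is `max(0, next.start − prev.end − 1)`: the count of
  bases strictly between genes, floored at zero for overlapping or
  book-ended genes.
* The 1 kb rule applies to *every* consecutive gene pair inside the cluster
  span — "all the intergenic lengths" reads as universal, not PUP-to-PUP
  only.
* Clusters are trimmed to start and end at PUP genes, so intervening genes
  are the only non-PUPs inside a cluster; strand is ignored (operons
  motivate the rules but are not asserted).
* Detection is a left-to-right chain over adjacent PUP pairs. Because the
  rules only constrain adjacent PUP pairs and the genes between them, a
  window bounded by PUP genes is valid exactly when every adjacent PUP pair
  inside it is linkable, so maximal valid windows are the maximal runs of
  linkable pairs: the greedy chain is provably equivalent to exhaustive
  window enumeration, and the test suite re-verifies that equivalence
  against a brute-force oracle on 1,000 random layouts.

Substrate inference is a majority vote. Every PUP gene votes once per
distinct substrate across its families (so a gene annotated with two
daidzin families still casts one daidzin vote — the unstated alternative,
double voting, would let multi-family genes dominate). All tied maxima are
returned together: an even split between daidzin and luteolin genes means
the cluster is inferred to target both. Genes whose families carry no
substrates are excluded with a warning rather than silently dropped.

## SSN subfamilies

Similarity edges keep the best E-value per unordered pair, drop self-hits,
and are thresholded strictly below a cutoff. The cutoff is per family and
user-supplied (default 1e-5): family-specific values are tuning data that
live outside the package. "At least 10 well-connected sequences" defines a
subfamily, but "well-connected" was a manual call in the source material;
the package offers two reproducible proxies — connected components
(default) and components of the 2-core, which discards tree-like fringes —
and numbers subfamilies by decreasing size with ties broken by smallest
member, so labels are independent of input order. Lowering the cutoff can
only split, never merge, subfamilies; the suite asserts this monotonicity.

## Profiling and enrichment

Abundance is the percent of a genome's proteins annotated as PUPs (or
located in PGCs); prevalence is the percent of genomes in a phylum or
continent group with at least one such gene. The bubble table reports the
median abundance per phylum × continent cell with competition ranks
(1 = largest median, ties share the minimum rank — deterministic and
conventional). Genomes with unknown continent are excluded from continent
cells but still counted in phylum totals.

Enrichment of a Pfam domain among cluster proteins uses the upper-tail
hypergeometric probability P(X ≥ k) with the cluster proteins as the
foreground (size *n*, *k* carriers) and all proteins of cluster-containing
genomes as the background (size *N*, *K* carriers), computed via
`stats::phyper(k − 1, K, N − K, n, lower.tail = FALSE)`. Counting is per
protein — a protein with two copies of a domain counts once — because the
quantity of interest is how many *proteins* co-occur with PUPs. Results are
ordered by foreground occurrence, mirroring how candidate novel families
are ranked, with BH-adjusted p-values reported alongside the raw ones.

## Metagenome profiling

Percent-reads-mapped counts each read once by its best (lowest-E) hit
against the characterized PUPs, over the sample's total reads; the E-value
cutoff for translated search hits is not stated in the source material, so
it defaults to 1e-5 and is configurable. RPKM is
`count / ((length/1000) × (total_mapped/1e6))`, normalised by the
*sample-wide* mapped library size from the sample sheet — normalising by
reads mapped to the PUP targets alone would cancel exactly the biological
signal being measured. Group comparisons default to Welch's two-sided
*t*-test (robust to unequal variances; a pooled-variance option exists)
with the conventional `***`/`**`/`*`/`n.s.` labels at 0.001/0.01/0.05.

## What the synthetic data emulates

The generators produce every input format the pipeline reads, with truth
manifests, under a single seed each (artifacts carry the seed in their
comment headers; the FASTA, which has no comment syntax, records it in the
manifest only).

* `simulate_genome()` plants clusters that satisfy all three rules with
  margin (2–4 PUP genes, 0–3 intervening genes, intra-cluster gaps
  50–400 bp) and decoys that each violate exactly one rule: a lone PUP
  gene, a pair with four genes between, a pair split by a 1.1–1.6 kb gap.
  Background genes are separated by 1.2–3 kb gaps so they can never join a
  cluster, which is what makes planted precision/recall an exact target of
  1 rather than a soft one. Protein sequences are uniform random strings
  over the 20-letter alphabet and domain-hit tables are written directly —
  no claim of biological realism; passing tests demonstrate the *logic* on
  well-separated layouts, not performance on fragmented assemblies, where
  clusters split across contigs are genuinely missed.
* `simulate_ssn()` plants blocks as rings with random chords (connected,
  and inside their own 2-core) at E = 1e-30, joined by sparse bridges at
  1e-3, so any cutoff between the two levels separates blocks exactly.
* `simulate_metagenome_counts()` draws negative-binomial counts per target
  and sample. Defaults model a strong seasonal diet contrast: per-target
  means 250 (wet season), 100 (dry), 60 (Western controls) at dispersion
  10 and 15 samples per group, which places the wet–dry difference in
  per-sample totals above two pooled standard deviations — an effect chosen
  once to represent the large, visually obvious contrasts this kind of
  case study reports, and then left alone. Real metagenome counts have
  target-specific means, compositional coupling and batch structure that
  the generator does not attempt.

## Problem sizes and checks

The automated checks run at fixed sizes chosen to exercise the mathematics
exhaustively where that is cheap: oracle agreement on 1,000 random contigs
of up to 50 genes; planted recovery on 100 seeded genomes with decoys;
hypergeometric agreement with exact `choose()` enumeration over *every*
(N, K, n, k) with N ≤ 60 (~6×10⁵ cases); 200 replicates each for the power
(≥ 95% at the planted effect, p < 0.01) and size (within 3 points of the
nominal 5%) of the group comparison.

## Known limitations

* Signature-based annotation inherits Pfam's granularity: families defined
  by a single promiscuous domain (e.g. a generic reductase fold) will
  recruit homologs with no polyphenol activity; subfamily membership is the
  sharper, but still computational, filter.
* Cluster detection depends on assembly contiguity; fragmented MAGs lose
  clusters at contig breaks, and the package does not stitch across them.
* Substrate inference propagates seed substrates through family labels; it
  is a hypothesis generator, not a prediction of enzymatic activity.
* Whether the original pipeline trimmed clusters to PUP boundaries, or how
  it treated a signature that is not the protein's best hit, is unstated;
  the package's choices (trim; presence suffices) are recorded above and
  exposed as the only behavior.
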