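---
title: "Methods: cluster-aware ncRNA quantification with snoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cluster-aware ncRNA quantification with snoquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snoquant)
```

## The problem and the model

Small non-coding RNAs are heavily duplicated: a single functional RNA may be
encoded at dozens of near-identical genomic loci. After trimming sequencing
reads to a common 28 nt (which also removes amplification primer sequence
from short inserts), a read sampled from such an RNA typically aligns to
several loci exactly. snoquant treats this at three nested scopes:

* **Cluster.** All loci of one family form a cluster; a read counts once
  for the cluster when at least one of its placements overlaps at least one
  member on the correct strand. Counting reads, not placements, makes the
  count insensitive to copy number.
* **Group.** Within a cluster, the pairwise similarity
  $S_{ij} = |K_i \cap K_j|$ counts distinct 28-mers shared between members
  $i$ and $j$ (set semantics — a 28-mer occurring twice still counts once,
  because what matters is whether a *read* with that sequence is ambiguous).
  Groups are the connected components of the graph with edges where
  $S_{ij} \ge 1$. For perfect-match 28-nt alignment this gives a guarantee,
  not a heuristic: no read can align to members of two different groups, so
  a read whose member-overlapping placements all fall in group $g$ belongs
  to $g$. Reads spanning members of two or more groups (possible only if
  groups were derived at a higher threshold, or alignments are inexact) go
  to an explicit ambiguous bin; group counts plus ambiguous always equal
  the cluster count, and the pipeline aborts if this conservation ever
  fails.
* **Member.** Member-level counting is group counting over singleton
  groups, i.e. member-exclusive reads. It is meaningful exactly when the
  similarity matrix is (near-)diagonal — the member-discriminable case that
  `partition_groups()` flags.

mRNAs are counted with a single-gene rule: a read contributes only if, over
all its placements, it overlaps exactly one gene, and at least one placement
is sense to that gene. Reads inside overlapping gene pairs therefore count
for neither gene, which avoids arbitrary assignment.

### Normalization and uncertainty

Expression is reported as RPKM,
$\mathrm{RPKM} = \dfrac{c}{(L/1000)\,(N/10^6)}$,
with $c$ the unique-read count, $N$ the number of *distinct* aligned reads
in the sample and $L$ an effective length in nt. Counting is modeled as
Poisson, so $\sqrt{c}$ is attached as the uncertainty and normalized
identically; every output row carries $L$ and $N$ so the algebra can be
audited from the table alone.

For a cluster, $L$ is the **median member length**, not the summed length of
all copies. A cluster expresses one RNA species of roughly one member's
length; dividing by the summed length of 40 copies would shrink true
expression 40-fold. This choice also makes the package's worked example
self-consistent: 104,744 reads in a sample of 26.2 M aligned reads over an
81-nt effective length give RPKM $\approx 4.9\times10^4$, the scale at which
highly expressed snoRNA clusters are reported.

Two simple-feature modes exist for single-copy features: full RPKM (tRNA
style) and per-million-only (lincRNA style, where spans vary over orders of
magnitude and length normalization is not wanted). The latter is implemented
as RPKM with a fixed $L = 1000$ nt, so the value equals reads-per-million
while the $\sqrt{c}$ contract still holds on every row.

### Regions

`region_rpm()` reports per-strand unique-read counts and reads-per-million
over any span, with optional binning for coverage export; each counted read
is assigned to the bin of its 5′ end so bins sum exactly to the strand
count. `scan_novel_regions()` tiles chromosomes with fixed windows (default
1000 nt), keeps windows whose strand-specific RPM reaches `min_rpm` in at
least one sample, merges adjacent windows, and flags merged regions that
overlap no annotated locus as novel. Broad unannotated transcription has
been found by inspecting coverage tracks rather than by an algorithm; the
scan is our deliberately simple generalization of that inspection — no
changepoint model, no transcript assembly — and is labeled as such.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `k` / read length | 28 | nt | common trimmed length across mixed 36/50-nt runs; primer-safe |
| group `threshold` | 1 | shared k-mers | any shared 28-mer makes reads ambiguous, so 1 is the read-level guarantee; higher values trade guarantee for coarser groups |
| `unique_mode` | lenient | — | reads also aligning outside a cluster still count for it; merging all copies into the cluster exists precisely to keep such reads countable. `strict` drops them for sensitivity analyses |
| overlap predicate | ≥ 1 nt | — | 28-nt reads against ~81-nt features make partial edge overlaps common; containment would bias against feature edges |
| enrichment threshold | 10 | RPKM | floor below which max-tissue assignment is noise-driven |
| scan `window` / `min_rpm` | 1000 / 50 | nt / RPM | window matches the scale of broad transcription; threshold is data-set dependent and must be chosen relative to background density |

Argmax ties in the tissue-enrichment tally are resolved to the first sample
in a fixed order **and flagged**; silent tie-breaking would fabricate tissue
assignments.

## The synthetic-data generator

`make_genome()` emulates the structures the method must handle: a
multi-copy family with block-structured 28-mer sharing (default study
condition: 29 members in groups of 9, 15 and 5), single-copy mRNAs, and
overlapping mRNA pairs that exercise the single-gene filter. Members derive
from a family ancestor; each group ancestor carries
`between_group_divergence` substitutions (default one per 14 nt, enough to
break every shared 28-mer with high probability) and each member
`within_group_divergence` more (default 2, keeping members of a group
mutually ambiguous). Divergence is injected as random substitutions and the
family is redrawn — bounded retries — until the similarity module itself
verifies the intended partition (zero cross-group sharing, groups internally
connected); an unsatisfiable spec fails loudly rather than emitting a genome
that violates its own truth table. Members alternate strands by default so
strand handling is always exercised.

`simulate_reads()` draws each feature's read count from
Poisson$(\mathrm{RPKM}\cdot(L/1000)(N/10^6))$, places read starts uniformly
within a uniformly chosen member, emits reads on the feature's strand
(minus an optional antisense fraction), fills the sample to exactly $N$
aligned reads with background reads from intergenic gaps, and appends an
optional unalignable fraction of random sequence. `toy_align()` reports
every exact-match placement on both strands. Truth tables record expected
and realized counts so parameter recovery is checkable to the read.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: sequencing errors and quality variation,
mismatch-tolerant alignment (real aligners place reads across groups at low
rate), positional and GC bias, amplification artifacts, rRNA contamination,
and annotation errors. The simulations establish correctness of the
counting and normalization machinery under its stated model, not robustness
to violations of that model.

## Numerical and design choices

* Coordinates are 0-based half-open internally; BED I/O is 0-based,
  browser-style tables are converted on load (`coords = "browser"`).
  Every file interface documents its convention, eliminating off-by-one
  ambiguity.
* Relatedness (which loci share a cluster) is supplied as an explicit
  mapping, never inferred from name suffixes; name heuristics would invent
  curation that should come from the annotation source. Where duplicate
  annotations conflict, precedence is the caller's choice of input rows.
* The RPKM denominator counts distinct aligned reads, all classes included.
  Whether to count alignments instead, or exclude rRNA reads, is exposed by
  simply passing a different `n_aligned`; records always carry the value
  used.
* Group labels are Roman numerals in order of first member appearance along
  the genome — deterministic, so reruns and diffs are stable. The class
  vocabulary is closed and case-normalized on load; unknown classes are
  fatal, as silent typos would corrupt the class filter.
* The region half-sum invariant (RPMs of two halves sum to the whole) holds
  exactly only when no read straddles the cut, since straddlers count in
  both halves under the ≥ 1 nt predicate; fixtures avoid straddlers, and
  real use should treat window-boundary effects as ± one read.
* `run_pipeline()` writes its manifest (all parameters, seed, package
  version) before computing, logs stages, and fails on any conservation
  violation, so every number in the outputs can be traced to a recorded
  configuration.

Deliberately out of scope: EM-style probabilistic rescue of cross-group
ambiguous reads, isoform-level mRNA quantification, mismatch-tolerant
similarity, secondary-structure comparison, and C/D vs H/ACA motif
detection from sequence.

## Problem sizes used in the test suite

Oracle-equivalence tests run at sizes where brute force is exact and fast:
20 members × 200 nt against full set-intersection enumeration, 10⁴ reads ×
100 features against the direct double-loop definition, and a 10⁵-nt genome
against a scan of every position. Parameter recovery simulates 10⁵ aligned
reads over a 29-member three-group family at true group RPKMs
14439 : 635 : 242 and requires each group's recovered RPKM within 3 Poisson
σ of truth — note that at this depth the rare groups expect only ~5 and ~2
reads, so the check is dominated by honest Poisson noise, which is the
point: the uncertainties the package reports are the ones the data imply.
These sizes were chosen so the whole suite completes in well under a minute
on a laptop while leaving no operation tested only at toy scale.

## Known limitations

Exact-match 28-mer logic is both the method's strength (provable group
separation) and its boundary: real aligners tolerate mismatches, which
softens the no-cross-group guarantee and argues for inspecting the reported
ambiguous bin on real data. Effective length as the median member length is
an inference about how cluster expression should be normalized, not a
universal convention; comparisons with externally computed RPKMs should
confirm the length convention first. The novel-region scan has no
statistical calling model — `min_rpm` must be set relative to the data set's
background, and at very shallow or very deep coverage the same threshold
means different things.
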