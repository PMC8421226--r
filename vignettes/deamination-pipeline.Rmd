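---
title: "Tracing binding sites born by CpG deamination: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing binding sites born by CpG deamination: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pregbs)
```

## The inference

Cytosines in CpG dinucleotides are the main substrate of DNA methylation,
and a methylated cytosine deaminates to thymine an order of magnitude
(10–50×) faster than an unmodified one. A deamination on one strand turns
CG into TG; the same event on the opposite strand reads CG→CA. Binding
sites whose modern consensus contains a TpG can therefore descend from a
CpG-containing precursor that was methylatable — for the glucocorticoid
receptor (GR), a "pre-GBS".

The GR core motif `GnACAnnnTGTnC` is its own reverse complement. In a
homolog of a human motif occurrence, a single variant at position 5 or at
position 9 is informative: position 9 on the forward strand is position 5 on
the reverse strand, so both are pooled into the position-5 frame by
complementing a position-9 variant base. A pooled **G** means the homolog
reads `..ACG..` (or its strand mirror) where the human motif reads `..ACA..`
— a retained CpG at exactly the dinucleotide whose deamination yields the
modern consensus. The pooled base is never `A` (the consensus), and a
uniform substitution process predicts C : G : T variants in equal thirds, so
a G excess is the deamination signature. Three statistics accompany the
tallies:

* a chi-square goodness-of-fit of the pooled C/G/T counts against the
  uniform null (df = 2), starred `**` below p = 1e-4 and `*` below 5e-3;
* a one-sided Fisher exact test asking whether regulatory occurrences
  (those overlapping DHS / TF ChIP / conserved-element tracks by ≥1 bp)
  are enriched for pooled-G variants relative to non-regulatory ones;
* a hypergeometric upper tail for the regulatory overlap of the unique
  pre-GBS set: population = all motif occurrences, successes = regulatory
  occurrences, draws = unique pre-GBS sites, observed = regulatory pre-GBS
  sites. The population regulatory count is not a published constant and is
  always computed from the provided tracks.

## Pipeline contracts

Coordinates are 0-based half-open everywhere internally (BED convention);
1-based coordinates appear only in labeled human-readable reports.
Soft-masked (lowercase) sequence is uppercased and scanned: the motif count
is defined on sequence content, and no repeat-mask handling is assumed. Any
window containing a non-ACGT base (including `N`) never matches, wildcard
positions included — wildcards mean "any real base". Because the motif is
palindromic, forward- and reverse-strand scans report the same intervals;
occurrences are deduplicated per genomic interval, which exactly halves the
raw two-strand hit list.

Homolog extraction keeps an occurrence only when a single alignment block
covers it end to end with zero gap columns in either row across the motif's
columns — the positional comparability needed for single-base variant calls.
When redundant blocks fully cover an occurrence, the block with the longest
reference overlap wins, ties broken by (target name, target start); results
are therefore a pure function of the occurrence and the block set. Alignment
input is pairwise MAF only (reference row first, `+` strand, UCSC
`genome.chrom` naming); chained/netted track choice is upstream of the
package and the provided file is taken as-is.

"Unique" pre-GBS deduplication is keyed on the human genomic interval alone:
the same human site supported by several species is one site. Homologs that
match the consensus at positions 5 and 9 but mismatch another fixed position
are `other` and never partially counted. Regulatory overlap uses the 13 bp
occurrence interval itself with a configurable `flank` (default 0) and a
1 bp minimum overlap, the intersection default in standard BED tooling.

## The simulator

`sim_config()` fixes the study conditions. The ancestor is i.i.d. background
at a set GC content (default 0.41, human-like) with non-overlapping planted
motifs: `n_cpg_sites` pre-GBS instances (`GnACGnnnTGTnC`) and `n_tpg_sites`
consensus instances (`GnACAnnnTGTnC`), wildcards drawn uniformly. The
default ratio is 4 consensus sites per CpG site, mirroring the roughly
4-fold depletion of CpG dinucleotides in mammalian genomes relative to other
dinucleotides. Two descendant lineages are evolved independently and the
exact simulation record is emitted as the alignment — no realignment, so
projection errors are attributable to the pipeline, not the aligner.

Substitutions are a single simultaneous Bernoulli pass per lineage (not a
continuous-time matrix): the analysis being tested is count-based, not
phylogenetic, and the one-pass model keeps the generator exact and fast.
Non-CpG sites substitute to a uniformly chosen different base with
probability `mu` (default 0.02 per lineage). Each CpG dinucleotide of the
ancestral sequence instead suffers at most one deamination event, with
probability `1 - exp(-lambda * mu)`, resolving with equal probability to
TpG (forward-strand 5mC) or CpA (reverse-strand 5mC). The saturating form
is deliberate: deamination is one event per methylated dinucleotide, so
even at `lambda * mu >= 1` a fraction `exp(-lambda * mu)` of CpGs survives
and the CG→TG and CG→CA outcomes stay mutually exclusive. Modeling the two
strands as independent `min(1, lambda * mu)` coin flips would, at
saturation, convert every CpG to TA on both lineages and extinguish the
very signal the pipeline measures; under the saturating one-event model the
probability that one lineage converts while the other retains the CpG —
`p(1-p)/2` with `p = 1 - exp(-lambda * mu)` — keeps growing through the
upper end of the 10–50× range. `lambda` defaults to 20, the midpoint of the
published rate range.

Indels are drawn per site at rate `delta` (default 0.001), insertion or
deletion with equal probability and geometric lengths of mean 2; the RNG
streams for substitutions and indels are split per lineage and per
operation, so enabling indels does not perturb the substitution draws. A
planted site is *deamination-derived* when its class is CpG and its
human-lineage copy became an intact consensus motif; the regulatory track
covers such sites with probability `rho` (default 0.9) and all other
planted sites with probability `rho0` (default 0.3), emulating selection
preferentially preserving newly functional sites.

What the simulator does **not** emulate: phylogenies with more than two
taxa, selection on sequence, context-dependent rates beyond CpG, realistic
repeat structure, chromatin-scale correlation of regulatory annotation, or
alignment error. Passing tests therefore demonstrate the pipeline's
correctness and statistical behavior under a controlled neutral-plus-CpG
model, not the field realism of any particular genome pair.

## Binding module

Fluorescence-polarization titrations are fit with the simple one-site
hyperbola `f0 + (fmax - f0) * c / (kd + c)` — the probe is at trace
concentration (10 nM against a 1 nM–50 µM protein series), so ligand
depletion is neglected and the quadratic tight-binding form is unnecessary.
Least squares is performed on the linear signal scale over a log grid of
concentrations, as standard for FP.

The fit uses variable projection: for fixed Kd the model is linear in
(`f0`, `fmax`), so the residual sum of squares is profiled over log-Kd (200
grid points across `min(conc)/1000` to `max(conc)*1000`, then a
golden-section polish to tolerance 1e-12 on the log scale). This one-
dimensional profile is numerically robust: no starting values, no Jacobian
conditioning, and a `converged = FALSE` flag when the estimate hits the
search bounds. Confidence intervals are nonparametric case-resampling
bootstrap percentiles (2.5/97.5, B = 1000, seeded), computed by evaluating
the weighted profile for all resamples on a shared 240-point log-Kd grid
with parabolic refinement of each minimum — a vectorization that makes
hundreds of full bootstrap fits cheap. Percentile bootstrap was chosen over
asymptotic or profile-likelihood intervals because it matches a plain "95%
confidence interval" report without assuming any fitting software's
internals; the resulting intervals are asymmetric, as published affinity
CIs typically are.

## Problem sizes, tolerances and degenerate inputs

The test suite exercises the pipeline at desk scale: genomes of 20–150 kb
for unit tests and one 2 Mb, 500-CpG-site recovery experiment across
`lambda` in {1, 5, 10, 20, 50}; the regulatory-enrichment power study runs
100 replicates at 120 kb with 300 CpG sites; Kd recovery uses 50 seeds per
scenario (73, 131, 206 nM) and 200 seeded runs for CI coverage. These sizes
were chosen so the entire suite completes in minutes while keeping the
variant counts (tens to low hundreds) in the regime where the exact tests
are meaningful.

Numerical and degenerate-input choices worth knowing:

* exact tests are computed in log space from `lchoose`, so genome-scale
  hypergeometric tails (e.g. p ~ 1e-53) do not underflow intermediate
  terms;
* a Fisher table with an empty row or column yields p = 1 by construction
  of the upper tail;
* a chi-square on zero variants is an error; per-species report rows with
  zero variants carry `NA` p-values instead;
* motifs longer than the scanned sequence yield an empty result, not an
  error; windows never span FASTA record boundaries;
* flat titration signals and designs with fewer than 5 distinct
  concentrations are rejected as degenerate rather than fit;
* monotonicity of the recovered G fraction in `lambda` is asserted up to
  binomial sampling noise (a 2.58-standard-error allowance on each
  adjacent pair), since adjacent multipliers in the upper range differ by
  less than the sampling noise of ~100-variant spectra.

## Known limitations

The pooled G fraction at `lambda = 1` sits slightly above 1/3 in
expectation: even at the unmodified-cytosine rate some planted CpG sites
convert in the human lineage while the other lineage retains the CpG, and
those shared-ancestry witnesses are genuine, not an artifact. Similarly,
position-5 A→G substitutions arising at the baseline rate in planted
consensus sites are indistinguishable from deamination witnesses at the
single-pair level; they dilute regulatory-enrichment contrasts, which is
why the Fisher power study detects enrichment in roughly nine of ten
replicates rather than always. Both effects would shrink with longer
alignments, more species, or ancestral-state reconstruction across a tree —
all outside this package's pairwise-descriptive scope, as is any
gene-ontology enrichment of the resulting sites.
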