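---
title: "Methods: models, estimators and design choices in repeatscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in repeatscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: what each
estimator computes, what the synthetic-data generator emulates, which
parameters matter, and why the genuinely open design decisions were
resolved the way they were. Everything quantitative stated here is
computed by the test suite or by `scripts/acceptance.R`; nothing is
asserted from memory.

## The system being modelled

Mouse genomes silence endogenous retroviruses — most actively the IAP
family of ERVK LTR retrotransposons — and imprinting control regions
(ICRs) through DNA methylation, which recruits the corepressor TRIM28 and
O-GlcNAcylated chromatin factors to the repeats' regulatory sequences.
Three measurements probe this system: an immunoprecipitation /
mass-spectrometry screen comparing TRIM28-associated proteins between
methylated and demethylated cells; ChIP-seq of O-GlcNAc and TRIM28
quantified over repeat families and ICRs; and RNA-seq of repeat-family
expression after targeted removal of O-GlcNAc from IAP promoters. The
package implements the quantitative half of each measurement, from
standard file formats to the final statistic.

## Coordinate and counting conventions

All internal coordinates are 0-based half-open; 1-based inclusive
conventions exist only at format boundaries (SAM POS, RepeatMasker
begin/end) and are converted, and tested, at the boundary. Counting is
unstranded: strand is stored and used to orient LTR metaprofiles, but
fragment-to-unit assignment ignores it, because family-level aggregation
of repeat-derived fragments is not strand-resolved. This is a documented
limitation rather than an option.

A *unit* is a repeat subfamily by default (family or class selectable);
its length is the summed length of its genomic copies. Fragment
assignment offers three modes:

* **midpoint** (default): a fragment belongs to the unit containing its
  midpoint, `start + floor((end - start)/2)`. This resolves LTR/internal
  boundary fragments deterministically and assigns each fragment at most
  once.
* **any_overlap**: the unit with maximal overlap, ties broken by smaller
  interval start then instance id, so output is byte-stable.
* **fractional**: overlap-proportional weights; where self-overlapping
  annotation would let intervals double-claim the same fragment base
  pairs, weights are renormalized so each fragment contributes at most
  one fragment of evidence.

In every mode, assigned plus unassigned totals equal the input fragment
count; this conservation identity and equality with a quadratic
brute-force scan are tested on random instances.

## ChIP enrichment

For a unit u and sample j, cpm(u, j) = count × 10⁶ / library size, with
library size the total mapped (and, on real data, deduplicated) fragments.
The enrichment of a treatment group T over a control group C is

E(u) = mean_{j∈T} cpm(u, j) / mean_{j∈C} cpm(u, j).

Replicates are averaged on cpm rather than raw counts so a deep replicate
cannot dominate the mean; the ratio is flagged, not reported as infinite,
when the control mean is zero. The threshold for the boolean "enriched"
flag defaults to τ = 1.5 (dimensionless ratio); τ is a reporting
convention, not a fitted parameter, and the ICR summary can be read at any
τ. ICR occupancy counts fragments whose midpoint falls in the ICR interval
and cross-classifies ICRs by the enrichment flags of two targets
(typically O-GlcNAc and TRIM28), excluding from the denominators any ICR
with a zero control mean.

The LTR metaprofile groups a subfamily's role-labelled copies
(5′LTR / internal / 3′LTR triplets of adjacent intervals), rescales each
segment's per-bp coverage to a fixed number of bins by mean pooling
(20 bins per segment by default), reverses minus-strand copies so bin 0 is
always the element's 5′ end, and averages across copies. The scalar
contrast mean(5′LTR bins) / mean(3′LTR bins) summarizes promoter-proximal
occupancy.

Two choices deserve note. ChIP fragments are counted as read-length
intervals, with no fragment-size extension: extension length is an
aligner/library property the pipeline cannot verify, and the estimators
compare like with like (treatment and control are smoothed identically).
And whether enrichment should be computed on per-bp coverage rather than
per-fragment counts is genuinely underdetermined; counts with cpm
normalization are implemented, and coverage mode would be a
straightforward extension over the same `count_by_unit` surface.

## RNA repeat expression

After removing fragments that overlap rRNA intervals (first priority) or
mRNA intervals (second), per-unit counts are normalized to

FPKM(u, j) = count × 10⁹ / (L_u × N_j)

with L_u the unit length in bp and N_j the retained library size. The
background level B_j is the FPKM of the pooled DNA-transposon units —
classes that are transpositionally and transcriptionally dead, so their
apparent expression measures nonspecific signal. Adjusted values are

adjusted_fpkm = max(FPKM − B_j, 0),  adjusted_cpm = adjusted_fpkm × L_u/1000,

i.e. the rescaling to cpm is the exact inverse of the per-kb step, so
background removal is the only net transformation. Negative differences
are floored at zero; the pooled background unit adjusts to exactly zero by
construction (the implementation uses the same floating-point operation
order as `fpkm()` so this is an identity, not an approximation).
A `mean_of_units` background mode (mean of per-subfamily background
FPKMs) is provided for sensitivity analysis; pooled is the default
because it weights background copies by their length rather than giving
small subfamilies equal votes.

Fold changes between conditions use median-of-ratios size factors
computed on the unit counts (median over units with a nonzero geometric
mean of count / geometric mean across samples, rescaled to geometric mean
one). The normalized cpm of a unit is (count / sf) × 10⁶ / G with G the
geometric mean of library size / sf — a fixed scale that keeps cpm "per
million" while all cross-sample correction comes from the size factors,
which makes depth invariance exact. The fold change is

log2FC(u) = log2((mean_a + p) / (mean_b + p))

on replicate means of normalized adjusted cpm, with pseudocount p = 0.5
cpm. No dispersion shrinkage or significance testing is attempted: the
quantity of interest is the fold change itself. Note one consequence of
median-of-ratios normalization, shared with standard differential
expression tools: a fold change common to *all* units is absorbed as a
size factor, by design — the estimator measures changes against the
stable majority, and the test suite asserts exactly this limit behaviour.

A unit is called *reactivated* when log2FC exceeds 1.0 and its treatment
mean adjusted cpm exceeds 1.0. Background-class units are not candidates:
their adjusted values are, by construction, the residual noise of the
subtraction that defines the baseline, so testing them would be circular
(an override flag exists).

## The interaction screen

With unique-peptide counts n_ref (methylated reference) and n_cmp
(demethylated comparison) and pseudocount c = 1,

R = (n_ref + c) / (n_cmp + c),

finite and positive for all proteins including zero counts. A protein is
*shown* when max(n_ref, n_cmp) ≥ 3 and is a *hit* when
max(n_ref, n_cmp) > 6 and R > 2 (strictly; a protein at exactly 2-fold is
not a hit). The fold filter is evaluated on the pseudocounted ratio for
consistency with the ranking statistic and to avoid division by zero; a
raw-ratio switch exists. The "> 6 unique peptides" requirement is read as
the maximum over the two conditions — the protein must be well detected
somewhere — rather than in the reference only; this is the permissive
reading and is switchable by threshold choice. Ranking is by R descending
with ties broken by n_ref descending then protein id, so output order is
reproducible byte for byte. `top_dependent()` reports the rank-1 shown
protein and its separation R₁/R₂, flagging a clear top at separation ≥ 2.

## The synthetic-data generator

The generator defines the desk-scale study conditions; its defaults are
fixed once and every verification runs against them.

* **Genome and annotation**: one 500 kb contig; an IAP-like LTR-structured
  ERVK subfamily (12 copies × 5 kb, 400 bp LTRs — the real elements are
  ~7 kb with ~330–400 bp LTRs, scaled down), a second LTR family
  (MERVL-like, 8 × 3 kb), a LINE (10 × 6 kb), a SINE (40 × 150 bp) and
  two DNA-transposon subfamilies (20 × 800 bp, 15 × 600 bp) as the
  inactive background; four 2 kb ICRs placed in repeat-free gaps. Copies
  are placed uniformly at random without overlap (bounded rejection
  sampling; total repeat content is required to stay under 80% of the
  genome). Sequence content is uniform random and inert: the pipeline
  consumes alignments, so mappability is deliberately not modelled.
* **ChIP**: fragment start positions are drawn from a piecewise-constant
  intensity proportional to the planted enrichment e(x) — 1 everywhere
  for input/IgG, the per-subfamily factor over targeted repeats (default
  4 for the IAP-like family, 3 for the second LTR family), 3 over ICRs,
  and the 5′-LTR intensity additionally multiplied by the promoter boost
  (default 3). Each sample has exactly `depth` fragments (default 10⁵) of
  fixed length (50 bp, a typical single-end read length); the default
  design is ChIP triplicates against input duplicates.
* **RNA**: counts are simulated at the unit level — expected count
  proportional to L_u/1000 × baseline expression × 2^(planted log2FC),
  scaled to the target depth (default 10⁶) — with negative binomial
  noise. The `dispersion` parameter is the extra-Poisson coefficient of
  variation among replicates (NB size = 1/dispersion²); the default 0.1
  means 10% replicate-to-replicate variability, typical of clonal cell
  lines, giving a per-estimate log2FC standard deviation of about 0.12
  with 3 + 3 replicates. DNA-transposon baselines default to 2.5% of the
  IAP baseline, reflecting elements incapable of transcription. The
  default planted effect is +3 log2 on the IAP-like subfamily in the
  deGlcNAcylation condition.
* **Proteomics**: background proteins (default 300, a typical IP-MS
  identification count after peptide filtering) receive *correlated*
  Poisson counts in the two conditions — count = C + U with shared
  C ~ Pois(ρλ) and condition-specific U ~ Pois((1−ρ)λ), so marginals are
  Poisson(λ = 5) with correlation ρ = 0.9, matching the high
  reproducibility of replicate IP-MS peptide counts. The planted hit
  receives independent Poisson counts at means (20, 2). The correlation
  matters: independent background counts would produce spurious extreme
  ratios from sampling zeros alone, which replicate IP-MS data do not
  show.

Determinism is a contract: every generator is a pure function of
(configuration, seed), and bit-identical reruns are asserted in the test
suite. Per-stage substreams are derived from one global seed so any stage
can be re-run independently with identical randomness.

### What the generator does and does not emulate

It reproduces the *structure* of the real data — family hierarchies with
element roles, replicate designs, enrichment-over-input measurement,
composition effects of fixed sequencing depth, overdispersed counts,
correlated peptide counts — and therefore exercises every estimator's
failure modes around normalization and calibration. It does not emulate
mappability, multimapping ambiguity (each simulated fragment has one
location, mirroring an aligner configured to report a single alignment),
PCR duplication, GC or length biases, strand-specific library chemistry,
or per-spectrum peptide identification. Passing tests therefore validate
the estimators given correctly located fragments and counts; they say
nothing about upstream alignment quality on real data.

### Duplicate removal at desk scale

`deduplicate()` removes positional duplicates — retaining one fragment per
(contig, start, strand) — which on real data removes PCR artifacts.
At the generator's density (10⁵ fragments on 500 kb, up to ~0.8 expected
fragment starts per bp per strand in boosted LTRs), independent fragments
collide at the same position as a matter of course; removing those
collisions truncates the planted intensity and would measure saturation,
not the estimator. The recovery and calibration analyses therefore count
simulated fragments without deduplication, while `deduplicate()` carries
its own exact oracle tests and is applied in the demo pipeline and on any
real data. On a real genome (three orders of magnitude larger at
comparable depth) this saturation regime does not arise.

### Known systematic offsets in recovery

Two visible, well-understood biases are worth naming because the tests
account for them. First, ChIP enrichment ratios are deflated by the
factor Z = genome-average of e(x): a fixed sequencing depth redistributed
toward enriched regions lowers cpm everywhere else. At the default
configuration (targeted families occupying ~17% of the genome) the
deflation is substantial, which is why quantitative recovery of a planted
factor is evaluated at the sparse-occupancy condition (~1% of the genome,
Z ≈ 1.03) where E differs from the planted e by ~3%; the dense default
still orders families correctly and separates targeted from untargeted
families cleanly (monotonicity is tested). Second, the metaprofile
contrast sits slightly below the planted boost because fragment-length
smoothing bleeds intensity across segment edges (≈5% at 50 bp fragments
on 400 bp LTRs).

## Problem sizes and runtime

Verification runs at sizes chosen to make sampling error small relative
to the tolerances while keeping the full suite in minutes on one CPU:
oracle equivalence on ~100 random instances (up to 10⁴ fragments × 10³
intervals and 10³ proteins); null calibration over 100 seeds at depth 10⁵
(ChIP) and the default RNA design; recovery of the log2FC grid {0..4}
with 8 simulations per grid point at depth 10⁶; 200 seeds for the
proteomic rank-1 property; 100 seeds for reactivation specificity. Where
a recovery figure averages several simulations, the reported quantity is
the bias of the estimator (mean estimate minus truth), with the
per-estimate spread documented above.

## Limitations

Family-level counting cannot resolve single-copy expression or splice
structure; enrichment ratios are not peak calls and carry no significance
model; strandedness is ignored at the counting level; the log2FC has no
dispersion shrinkage, so per-unit estimates at low expression are noisy
and are gated by the minimum-cpm call threshold; and the background
adjustment assumes the DNA-transposon signal is a spatially uniform proxy
for nonspecific background, which is an approximation on real data.
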