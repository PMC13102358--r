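---
title: "Methods: simulation-trained deep-learning scans for introgression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation-trained deep-learning scans for introgression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The inference problem

Two recently diverged species that hybridize exchange genomic material by
recurrent backcrossing (introgression). Given phased biallelic SNPs from one
population of each species — here modelled on the Iberian lynx (ILa) paired
with either a Western (ELw) or Southern (ELs) Eurasian lynx population — the
task is to classify every 128-SNP genomic window into one of four scenarios:
introgression into the Iberian side (`ELtoIL`), into the Eurasian side
(`ILtoEL`), both (`BiDir`), or neither (`none`). No admixture-free reference
panel exists for this species pair, and the species phylogeny is unresolved,
which rules out reference-based local-ancestry and in-group/out-group
statistics; the package instead trains a convolutional classifier on
coalescent simulations with known introgression labels and applies it in a
sliding-window genome scan.

## The generative model

### Demography

A two-population piecewise history: two epochs before the population split
and three after. Each epoch carries a duration (generations), start and end
diploid effective sizes per population (equal if constant, differing if
exponential), and per-direction migration rates defined as the probability
that a lineage in the sink descended from the source in the previous
generation — exactly the backward-lineage convention of coalescent engines.
Time is converted with a 5-year generation span; the mutation rate is
6e-9 per bp per generation.

The study's six fitted histories are published only at figure-level
precision, so `lynx_model()` ships *representative* fixtures that honor the
printed magnitudes: divergence near 150 / 600 / 800 ky per model index;
recent diploid sizes around 5,000 (ELw, declining from 10–20k), 10,000
(ELs), and below 3,000 (ILa, declining from 5–7k); migration consistently
higher in the ILa–ELw pair than in ILa–ELs in recent epochs. Acceptance
never asserts equality with the study's (unpublished) parameter vectors,
only these magnitudes. The recombination rate, which the source does not
print, is fixed once at 1e-8 per bp per generation, a typical mammalian
value.

### Scenarios

An introgression scenario adds instantaneous mass-migration pulses to the
demography: the pulse proportion is uniform on [0.05, 0.50] and its time
uniform on [1, 5000] generations before present; `BiDir` draws the two
directions independently. A pulse moving a proportion *p* is implemented
backward in time as each recipient lineage jumping to the donor with
probability *p* — the standard `ms -es`-style event, meaning *p* is the
fraction of the recipient's ancestry replaced at the pulse. Replicates are
re-simulated (bounded at 100 attempts) until at least 128 biallelic
segregating sites exist and, for introgression labels, at least one
*recipient* haplotype demonstrably carries donor ancestry. Donor-tract
presence is read from the engine's migration records rather than literal
resimulation bookkeeping; with background migration in the fixtures, a
pulse-moved lineage can also be ancestral to donor-side samples (the
haplotype simply persists in the donor), so tract labels are restricted to
recipient-population samples.

Ancestral-recombination-graph simulation itself is delegated to msprime
through a batch subprocess bridge (`inst/python/coalesce.py`); everything
above the ARG — demography event lists, pulse draws, acceptance,
error models, encoding, training — is native R.

### Sequencing-error and heterogeneity models

Allelic dropout at low depth: at each heterozygous site of a designated
individual, read depth is `d = max(1, Poisson(lambda))` (minimum one read,
reflecting phased/imputed data with no missingness) and reads fall on the
two alleles with probability 0.5 each; observing a single allele flips the
call to the matching homozygote, and both haplotypes are re-phased to the
called allele, since downstream tensors are haplotype-based. The expected
het-site miscall rate is `E[2 (1/2)^d]`, the brute-force oracle the tests
check at lambda in {2, 4, 6}. Rate heterogeneity multiplies a region's
mutation and recombination rates by a shared Gamma(shape 10, scale 1/10)
factor (mean 1, variance 0.1); training uses fixed baseline rates, and
heterogeneity enters only the "realistic" evaluation sets, since the source
describes it only there.

## Tensor encoding

Windows of 128 SNPs advance in 64-SNP steps; a trailing window with fewer
than 128 SNPs is dropped (the classifier needs a fixed shape). Each window
is polarized jointly across both populations — the majority allele of the
combined sample codes 0, the minority 1, ties keeping the input reference as
major — because a two-layer image needs a single coding per column. Both
populations are upsampled to H = 44 rows (the largest haplotype count in the
study design) by appending uniformly re-drawn copies of observed haplotypes
after the originals; the upsampling seed derives from (chromosome, window),
so a scan is reproducible window by window. The result is a binary
(2, 44, 128) tensor, one population per layer. Polarization is chosen
per window rather than per dataset; both readings are defensible, and the
per-window choice keeps every tensor self-contained.

## The discriminator

The `"paper"` preset is a faithful ResNet-34: 7×7/stride-2 convolution,
batch normalization, ReLU, 3×3/stride-2 max pooling, then four stages of
(3, 4, 6, 3) basic residual blocks at (64, 128, 256, 512) channels with
identity or 1×1-projection shortcuts, global average pooling, and a 4-unit
softmax head. No deep-learning framework exists in this environment for R,
so the engine is implemented directly: convolutions as precomputed im2col
gathers feeding BLAS GEMMs, with `rowsum()` scatter-adds for the backward
pass, all gradient-checked numerically. The `"desk"` preset — one block per
stage at (8, 16, 32, 64) channels — exercises the identical code path at
CPU scale and is what every training test uses; full ResNet-34 training is
not desk-scale and lives in `scripts/full_scale.R`.

Because scenario labels are invariant to reordering haplotype rows within a
population layer, the trainer offers optional within-layer row-permutation
augmentation (`train_config(augment = "permute")`). It is off by default —
the study-scale regime with 144,000 tensors does not need it — but
desk-scale runs use it: with only a few thousand tensors the network
otherwise memorizes the pool (training loss near zero, validation at
chance), while fresh per-minibatch permutations force it onto genuinely
row-order-invariant features and lift validation accuracy well above
chance at identical cost.

Training follows the published configuration: categorical cross-entropy,
Adam (learning rate 0.001, betas 0.9/0.999), batch size 16, at most 100
epochs of 1,500 steps. An epoch draws its step budget by shuffling and
cycling the training pool, since the step count, not the pass count, is
fixed. "Validation loss decreasing" is read as *strictly below the best so
far* — the semantics that make best-weights checkpointing coherent — with
patience 10; the weights from the best-validation epoch are returned.
Stratified validation is 5% per scenario class, rounded up per class so tiny
desk runs keep non-empty splits. No input normalization is applied beyond
the binary encoding.

## Calling and merging

The softmax output feeds a summed decision rule: a window is `ELtoIL` when
p(ELtoIL) + p(BiDir) exceeds the threshold P (default 0.9), `ILtoEL`
symmetrically, `BiDir` when both sums do. Because introgressed haplotypes
stretch across windows, none-windows immediately adjacent (previous/next in
the 64-SNP-step sequence on the same chromosome) to a primary call are
re-evaluated at the relaxed threshold 0.7. This relaxation is a *single
non-iterative pass*: newly extended calls do not seed further extension —
the source describes only "windows next to introgressed ones", and a
fixpoint cascade would extend calls arbitrarily far beyond anything it
describes. Consecutive same-class calls merge into regions whose bp span is
the union of first-to-last SNP positions (half-open); genome fractions
flatten each class to its bp union before summing, and cross-scan accounting
partitions two scans' regions into exclusive and shared interval sets whose
fractions add up exactly.

## Evaluation

Precision is true positives over all windows called as a class; recall is
true positives over all windows simulated under it. Presence metrics
collapse the three introgression classes against `none`; directionality
metrics are computed only over windows whose presence call is correct. An
empty denominator yields an absent value (NA), never 0 or 1 — silently
scoring an uncalled class would distort threshold sweeps. Precision
monotonicity in P is an empirical observation, not a theorem, and is
treated as such.

The joint SFS machinery mirrors the named conventions of demographic
inference tooling: a Poisson composite log-likelihood with the model
spectrum rescaled by the optimal factor (sum of data over sum of model), and
the two fixed corners masked. Observed windows have no outgroup, so their
spectra fold by the joint major allele, consistent with the tensor coding;
simulated alignments come derived-coded from the engine, and SFS comparisons
against simulations use that unfolded scale. One empirical caveat found
during development: under the representative fixtures (which carry
background migration), mass-migration pulses *homogenize* the pair, so the
corner-cell "opposite-frequency" statistic decreases rather than increases
with introgression; the robust correctly-signed signature in this world is
the excess of variants segregating in both populations, and the property
suite asserts that signal. `opposite_frequency_mass()` remains available
and faithful to the corner-cell description.

## Synthetic cohorts and what a green test establishes

`generate_cohort()` builds a fully self-contained two-species cohort: every
chromosome is simulated under the demographic model with a scenario drawn
from a configurable mix, donor-ancestry tracts are recorded as ground truth,
and the standard artifact set is written — phased VCF 4.2 (with FS/MQ/QD
site annotations and uniform per-genotype missingness injected into the VCF
only; analysis tensors are built from imputed data, mirroring a
phase-then-impute workflow), gene and repeat BEDs, a chromosome-length
table, and per-individual 10-kbp depth profiles with occasional
collapsed-paralog tiles (depth multiplied across all individuals) to
exercise the 1.5×-mode depth filter. Defaults mirror the study design:
22 + 20 diploids (or 22 + 12), 18 autosomes on a descending 20→3 Mbp ladder
so chromosome-length regressions have spread, ~3% missing calls, and a mix
of ~25× and ~5× individuals. Internally all coordinates are 0-based
half-open; the VCF layer converts to and from its 1-based dialect, and BED
is native.

Two subtleties of the truth annotation deserve emphasis. First, fixture
migration magnitudes are trickle-level (4Nm well below 1): during
development, higher invented rates (around 1e-4 per generation) produced a
world in which windows without a pulse routinely contained *recent
continuous migrants* with near-identical cross-species haplotypes, making
"none" windows indistinguishable from introgressed ones in principle —
flatly contradicting the >90% precision and recall the published
classifiers achieve. The published separability itself thus constrains the
plausible migration magnitudes, and the fixtures honor that constraint.
Second, even trickle migration leaves some post-divergence donor ancestry
in most windows when accumulated over tens of thousands of generations and
84 sampled haplotypes. The generator therefore records
continuous-migration ("background") tracts separately from pulse tracts:
a scan window rich in background-migrant haplotypes that gets called
introgressed is a correct detection of real gene flow, not a false
positive, and the end-to-end tests define "truth-free" windows as carrying
no pulse tract and under 5% haplotype-bp of background ancestry.

The generator emulates the *statistical* structure the pipeline assumes —
coalescent genealogies with recombination, known tracts, plausible
site-quality and depth marginals. It does not emulate alignment artifacts,
repeat-driven miscalling, phasing switch errors, or selection. A green
end-to-end test therefore establishes that the pipeline recovers simulated
introgression under its own generative assumptions; it cannot certify
performance on real sequencing data.

## Filters

Site-level rules reproduce the published thresholds: drop non-biallelic
records, repeat-masked positions, FS ≥ 60, MQ ≤ 40, and QD < 6 (stricter
than the tool-suggested 2), with absent annotations treated permissively.
Missingness is filtered per population at ≥ 15%. The collapsed-paralog rule
excludes 10-kbp tiles whose per-population depth sum exceeds 1.5× the mode
of the tile-sum distribution; the mode estimator is unspecified in the
source, so sums are rounded to integers and ties break to the smallest
modal value (deterministic, and conservative in that it excludes more).
The source also does not say whether the tiles are shared or
population-specific; tiles are shared and the sums population-specific.
Demography-prep thinning is the greedy left-to-right ≥ 50 kb scan (the
vcftools convention: spacing exactly at the threshold is kept), and genic
SNP removal honors half-open intervals.

## Landscape statistics

Per-window nucleotide diversity uses the unbiased per-site heterozygosity
`sum 2 p (1-p) n/(n-1)` divided by the window span; telomere distance is the
bp distance to the nearer chromosome end (a recombination proxy); gene
overlap intersects the window with the union of gene intervals. The null
model re-places the observed region-length multiset at random genome
locations 100 times (chromosome chosen proportional to length, start
uniform; windows may overlap anything, the literal reading of random
placement). Group comparisons log-transform both sides — zeros are floored
at half the smallest positive pooled value, a deterministic standard choice
the source leaves open — then apply a two-tailed Welch t-test (group sizes
and variances differ by construction) and Cohen's d with pooled SD (the
convention of the effect-size package the study cites). Null values are
pooled across replicates rather than summarized per replicate; the source
is silent, and pooling uses every placed window. Chromosome-level
introgression fractions are related to chromosome length by Pearson
correlation with the t-distribution p-value.

## Numerical and engineering choices

* All randomness flows from one master seed through named, hashed
  sub-streams (per chromosome, per window, per batch); rerunning any stage
  with the same configuration is bit-reproducible, including byte-identical
  VCFs and checkpoint-restored predictions.
* The tensor store is a flat one-byte-per-entry binary container plus a
  JSON manifest; the trainer keeps it as raw bytes and converts per
  minibatch, so study-scale stores do not balloon in memory.
* Batch normalization uses per-channel batch statistics during training and
  running means (momentum 0.1) at inference; epsilon 1e-5.
* Desk-scale test budgets: every simulation-backed test states its reduced
  replicate counts and region lengths inline. Reductions were chosen once
  for CPU budget, not tuned to outcomes.

## Known limitations

* Fixture demographies are representative magnitudes, not the fitted
  parameter vectors; quantities that depend on fine demographic detail
  (absolute precision/recall levels, SFS shapes) will differ from the
  study's.
* The desk preset trained on thousands (not 144,000) of tensors yields a
  usable but weaker classifier; acceptance asserts enrichment of calls on
  truth tracts and threshold-ordering of precision, not study-level scores.
* GADMA-style demographic re-fitting, GO-term enrichment, phasing, and read
  alignment are out of scope; models are consumed as fixtures and synthetic
  data are born phased.
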