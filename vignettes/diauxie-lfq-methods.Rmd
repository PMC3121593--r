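---
title: "Label-free quantitation across the diauxic shift: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free quantitation across the diauxic shift: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`diauxielfq` implements a label-free LC-MS quantitation pipeline for
time-course proteomics of the *E. coli* glucose-lactose diauxic shift,
together with a synthetic-data generator that emulates the experiment so
that every stage can be validated against known ground truth. This
vignette explains the models behind each stage, the tunable parameters
and their defaults, what the generator does and does not emulate, and the
design decisions taken where the problem was genuinely open.

# The experiment being modelled

A culture grows on a glucose/lactose mixture. Glucose is consumed first;
when it runs out, growth pauses for 20-30 minutes while the lactose
catabolism machinery (the *lac* operon, most visibly beta-galactosidase)
is induced, then growth resumes on lactose until that too is exhausted.
Samples drawn every 30 minutes during balanced growth and every 10
minutes around the shift are measured by LC-MS; identified peptides are
quantified by their extracted ion intensities, rolled up to proteins, and
followed through time.

# The growth model

`simulate_growth_curve()` uses a three-phase kinetic skeleton:
exponential growth at rate $\mu_1$ on glucose, a plateau of fixed
duration, exponential growth at rate $\mu_2$ on lactose, then stationary
phase. Biomass and sugar are coupled through a single yield $Y$ (OD600
gained per g/L consumed, taken equal on both sugars), so

$$\frac{\mathrm{OD}_{\text{onset}}}{\mathrm{OD}_{\text{final}}}
  \approx \frac{g_0}{g_0 + l_0} = \frac{0.5}{0.5 + 1.5} = 0.25$$

with the standard 0.5 g/L glucose + 1.5 g/L lactose medium: the culture
reaches the shift at one quarter of its final density. Defaults --
inoculum OD 0.01, $Y = 1.145$, $\mu_1 = \ln 2 / 40\,\text{min}^{-1}$,
$\mu_2 = 0.007\,\text{min}^{-1}$, 25-min plateau -- place the onset near
235 min at OD $\approx 0.58$, give a final OD of 2.30, and exhaust
lactose roughly 220 min after onset; all within the ranges a bioreactor
run of this experiment produces. OD measurement noise is multiplicative
with log-scale SD 0.01 (about 1%, typical of OD600 readings).

# Expression trajectories

Each protein belongs to one of three classes -- upregulated,
downregulated or flat -- with relative abundance

$$a(t) = 1 + (F - 1)\,\sigma\!\left(\frac{t - t_{\text{onset}} - L}{s}\right)$$

where $F$ is the fold change, $L$ the expression lag and $\sigma$ the
logistic function with time scale $s = 10$ min. The logistic shape is a
modelling choice: published figures of the shift show smooth sigmoidal
transitions but do not parameterize them. The 10-min scale concentrates
the response in the ~40 minutes after onset, matching the observed
window of most protein change. The designated lacZ analogue is induced
16-fold with a 10-min lag -- the strong beta-galactosidase induction that
anchors the pipeline's headline recovery check. Other up/down proteins
draw fold changes as $2^{\pm U(1,4)}$ and lags from $U(2, 20)$ min;
mRNA trajectories share class and fold but respond with zero lag, so
protein always trails transcript.

One generator choice matters downstream: the protein with the largest
baseline-times-length product is assigned to the flat class and boosted
so that its summed peptide intensity dominates every sample. This
emulates the dominance of constitutive proteins (EF-Tu and other
translation machinery) in *E. coli* lysates and gives the
"most abundant protein" normalization a stable, biologically sensible
reference -- as it implicitly had in the real experiment.

# From proteome to feature maps

Proteins (random sequences with *E. coli* residue frequencies, lengths
$\mathcal{N}(300, 80)$ truncated at 50) are digested in silico with the
trypsin rule (cleave after K/R except before P; peptides of 6-30
residues kept). Each peptide receives a true retention time uniform on
the 2-88 min window of a 90-min gradient, a chromatographic width of
0.3-1.0 min (a free choice; peak widths are not reported for this
platform), and a theoretical m/z at charge 2+ (charge states are never
stated; a 2/3+ mixture is available as an option).

Each run -- one per replicate and time point -- observes these peptides
through:

* a monotone quadratic RT distortion $r(t) = a + bt + ct^2$ with
  $a \sim U(-3, 3)$, $b \sim U(0.95, 1.05)$,
  $c \sim U(-5, 5)\times 10^{-4}$, invertible over the gradient window
  (the master run keeps the identity -- it *defines* the time base);
* m/z perturbed by Gaussian ppm-scale error (SD 1 ppm, FTICR-grade);
* intensity = baseline $\times$ trajectory $\times$ lognormal noise with
  mean 1 and CV 0.2;
* uniform feature dropout at rate 0.1 (no intensity-dependent
  missingness -- real data would have some, which is a known limitation).

Identification lists per run contain true identifications (each peptide
identified with probability 0.6, ion scores from Gamma(shape 4, scale
12)), decoys (reversed sequences under `DECOY_` accessions) and an equal
number of false target identifications (shuffled sequences attributed to
a random protein), both scored from Gamma(shape 2, scale 8) with random
retention times. The paired construction is deliberate: the decoy count
is then an unbiased estimate of the number of false targets at any score
cut, which is exactly what the decoy FDR estimator assumes, and gives
the estimator a true quantity to be calibrated against. The score
distributions are arbitrary but fixed so that the score-25 filter
retains ~80% of true and ~18% of false identifications.

# Identification processing

`filter_by_score()` keeps records with ion score $\geq 25$ (boundary
included). `estimate_fdr()` returns the concatenated-search estimator
$D/T$; the symmetric estimator $2D/(T+D)$ is a one-line swap but $D/T$
is the conservative choice when the reporting convention is unknown.
The pipeline reports FDR both before and after the score filter, since
it cannot be determined at which stage the original rate was quoted.
`merge_identifications()` collapses to one record per (peptide, charge):
maximum score over runs, score-weighted mean retention time (a consensus
rule had to be chosen; score weighting favours the better-determined
observations), unioned accession lists. Peptides matching both target
and decoy proteins count as targets (rare, conservative).

# Retention-time alignment

Runs are aligned pairwise onto a designated master run using shared
identified peptides as anchors. The warp is strictly monotone
piecewise-linear with 5 equally spaced knots, fitted by least squares
with slopes constrained positive (solved as nonnegative least squares on
segment slopes with the intercept profiled out), after iterative
rejection of anchors beyond 3 residual SDs (at most 5 rounds) -- without
this, a handful of mis-identified anchors would wreck the fit. Outside
the anchor range the terminal segments extrapolate linearly, covering
the full gradient. Five knots resolve the gentle quadratic distortions
of a stable LC system while keeping ~10+ anchors per segment at typical
anchor counts; the tests require median absolute residual error below
0.15 min under 0.1-min anchor noise, which this fit meets with margin.
No claim is made that this reproduces any published alignment tool's
internals; it is a functional substitute specified by its observable
behaviour.

# Quantitation

For each merged identification and each aligned feature map,
`extract_peptide_intensity()` takes the **maximum intensity** among
features within 5 ppm in m/z and 1.0 min in retention time, recording
the matched feature's chromatographic span as the integration bounds.
The windowed-maximum rule and the peak-integral description are two
readings present in the source workflow's own description; the maximum
is implemented as the matching rule and the feature's single intensity
is treated as the apex/area surrogate. The window half-widths are
declared defaults, not recovered values -- the original widths are
nowhere stated. Ties on intensity break by RT proximity, then m/z error,
then m/z, giving a total order so results cannot depend on file order.
Missing cells stay missing; nothing is imputed anywhere in the pipeline.

# Protein rollup and normalization

Only peptides attributable to a single protein contribute
(`assign_unique_peptides()`); protein abundance is the **sum** of its
present unique-peptide intensities. Normalization follows the rule
"against the most abundant protein and the earliest time point":

1. per sample, divide by the reference protein's intensity in that
   sample -- by default the single protein with the largest total
   intensity (the sentence also admits a per-sample maximum; both
   readings are implemented, `reference = "global"` being the default
   because it keeps one scale across samples);
2. per protein and replicate, divide by the value at that replicate's
   earliest time point -- replicates are separate cultures, so "earliest
   time point" is read per replicate.

Every retained profile therefore starts at exactly 1; log2 transforms
follow. Proteins missing at a replicate's earliest point are dropped and
reported, not imputed.

# Onset detection, clustering, mRNA comparison

`detect_onset()` finds the earliest sampled time where the specific
growth rate (centred differences of log OD after a 3-point median
filter) drops below 25% of its pre-shift maximum while glucose is below
5% of its initial concentration. Both thresholds are invented -- the
original onset calls were visual -- and config-exposed; the 5% glucose
gate makes the call robust to transient rate dips, and the rate gate
ties it to the visible plateau. The call is invariant to uniform OD
rescaling by construction.

`cluster_profiles()` is CLARA-style k-medoids with k = 3: PAM (build +
swap, via `cluster::pam`) on random subsamples, keeping the medoid set
with least total dissimilarity over all profiles. The subsampling driver
is implemented here rather than calling `cluster::clara` directly
because profiles contain missing cells: distances are Euclidean over
shared-present time points (the `stats::dist` NA convention), which
`clara` does not support. `clara` on complete data serves as an
independent cross-check in the tests. Profiles under 80% presence are
excluded. Clusters are anonymous; they receive the semantic names
up/down/flat by the end-minus-start slope of their medoid. Defaults: 5
subsamples of `min(n, 40 + 2k)` rows, seed 42 (clustering is the one
stage whose randomness is not data-driven, so its seed is an explicit
argument).

`compare_with_mrna()` standardizes both series, interpolates the mRNA
profile onto shifted protein times, and scans shifts on a 10-second grid
over [0, 30] min for the correlation maximum. The scan is restricted to
non-negative lags because in this model (and in the biology) protein
accumulation cannot precede transcription.

# KEGG color export

Mean post-onset log2 ratios map to colors by two-segment linear
interpolation in RGB: +2.5 is pure green `#00FF00`, 0 is yellow
`#FFFF00`, -2.5 is pure red `#FF0000`, with clamping outside [-2.5, 2.5]
and round-half-up channel arithmetic (the three anchor codes pin the
transform; the interpolation rule and rounding between them had to be
fixed). The output file is the `entry bg,fg` line format the KEGG
pathway mapper accepts, with a black foreground. The accession-to-KEGG
mapping is a user-supplied table; no live queries, so everything is
deterministic and testable offline.

# Problem sizes and numerical choices

The default study-scale configuration is 1,000 proteins (20% up, 20%
down), 3 replicates, 27 time points (81 runs, ~16,000 tryptic peptides,
~1.2 million features), which the full pipeline processes in well under
a minute; unit tests use 8-40 proteins and 2 replicates, which preserve
every code path at a fraction of the cost. Warp fitting enforces
strictly positive slopes via a $10^{-6}$ min/min floor; degenerate
anchor sets (zero RT spread) are an error rather than a repair.
Validation throughout rejects rather than repairs: parsers report the
offending line, stage transitions of the protein matrix are enforced
(raw to normalized to log2, with `normalize()` idempotent at the
normalized stage), and zero/negative values reaching the log are an
error naming the cell.

# What passing tests do and do not show

The generator provides exactly the statistical structure the analysis
assumes: monotone RT distortions, unbiased multiplicative noise, uniform
missingness, score distributions with known contamination. Passing
recovery tests therefore shows the pipeline is *correct under its own
assumptions* -- it does not show robustness to what real LC-MS data adds:
intensity-dependent missingness, correlated peptide interference,
isotope envelope overlap, charge-state heterogeneity, retention drift
within a run, or saturation. Those are deliberately out of the
generator's scope (it fabricates apex-level feature maps, not spectra),
and conclusions about real-data performance need real data.

# Known limitations

* Shared peptides are excluded, never apportioned; proteins with no
  unique peptide are unquantifiable.
* The windowed-maximum extraction can capture a co-eluting isobaric
  neighbour when two peptides fall within 5 ppm and 1 min of each other.
* The FDR estimator is peptide-level only; no protein-level FDR or
  posterior error probabilities.
* One global plateau duration and one yield for both sugars; real
  diauxie kinetics vary more.
* The mRNA comparison assumes profiles on a common absolute time axis;
  aligning an external expression dataset to a different culture's clock
  is acknowledged to be imperfect and is sidestepped by generating mRNA
  profiles on the same clock.
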