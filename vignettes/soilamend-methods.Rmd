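---
title: "Methods and design notes for soilamend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for soilamend}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(soilamend)
```

soilamend implements the downstream analysis chain of acid-soil
amendment field trials: four amendment doses (a control plus three
application rates, here 0/6/9/15 t·ha⁻¹ of an alkaline mineral
conditioner), four replicate plots, and three successive crops. This
vignette records the models, the tunable constants, and the design
choices that were genuinely open, in the order the pipeline runs them.

## Aggregate stability indices

Wet sieving yields masses retained on a descending aperture stack
(2, 1, 0.5, 0.25, 0.106 mm) plus the pan. Each fraction is represented
by the arithmetic mean of its bounding apertures; the coarsest fraction
is bounded above by `assumed_max_diameter` (default 5 mm, because dry
pre-sieving removes coarser material; configurable).

* `r025()` is the mass fraction of aggregates above 0.25 mm. It
  requires 0.25 mm in the stack — re-binning silently would invent
  data, so the function refuses instead.
* `mwd()` weights fraction mean diameters by **mass fractions**, not
  raw masses. The weighting symbol in the field's formula is sometimes
  printed as a mass; taken literally that gives units of g·mm, so the
  dimensionally consistent mass-fraction convention is used.
* `gmd()` is the mass-weighted geometric mean; zero-mass fractions
  contribute nothing.
* `fractal_dimension()` fits ln of the cumulative mass fraction finer
  than each fraction's mean diameter against ln of that diameter over
  Rmax. The cumulative fraction at the coarsest point is 1 by
  construction (zero log), carries no information about the exponent,
  and is excluded. The fit uses a free intercept by default — on noisy
  data a forced-origin fit transfers all measurement error at the
  anchor point into the slope — with `force_origin = TRUE` available.
  D = 3 − slope. Whether the representative diameter should be the
  fraction mean or the upper aperture is not standardised across the
  literature; the mean diameter (the same xᵢ as in MWD) is the default
  here and the choice only shifts the log-axis labels, not the fitted
  exponent on exact power-law data.

## Soil quality index

Scoring uses linear min–max curves (`score_indicator()`): the fewest
free parameters of any scoring family, needing only a polarity flag per
indicator. Exchangeable acidity and its components (EA, ExH, ExAl),
bulk density (BD) and the fractal dimension (D) default to
less-is-better; everything else to more-is-better; all overridable. A
sigmoidal curve is available behind `method = "sigmoid"` for users who
want soft saturation at the extremes.

The minimum data set follows the standard PCA procedure: retain
components with eigenvalue ≥ 1 (with a 1e-9 numerical tolerance at the
boundary, so indicators that are exactly orthogonal — unit eigenvalues
up to rounding — are retained deterministically); within each retained
component, candidates are indicators whose |loading| is within 10% of
that component's maximum; candidates correlated at ≥ 0.5 collapse to
the one with the largest norm value
sqrt(Σ loading² × eigenvalue over retained components). All four
constants (`eigen_min`, `loading_window`, `corr_redundancy`, and the
scoring curve) are arguments.

Weights are the variance shares of each MDS indicator's source
component, renormalised over the selected set; SQI = Σ Wᵢ Sᵢ.

SQI is computed **within each crop season** by default (scoring ranges
and PCA per season): group differences are reported per season, and a
global scoring range would let one season's extremes compress another
season's scores. `by_season = FALSE` switches to a global analysis.

A caveat the synthetic demonstration makes visible: when one gradient
(amendment dose) drives nearly every indicator, the correlation matrix
is close to rank one, a single component passes the eigenvalue
threshold, and redundancy elimination legitimately reduces the MDS to
one or two indicators. Real trials with more independent sources of
variation retain more. Relatedly, min–max scoring pins the worst plot
of each season near score 0, so percent changes of SQI against a
control sitting at the floor can be very large; the absolute group
means are reported alongside.

## Community statistics

Rarefaction subsamples each sample without replacement to the lowest
sample total (`depth = "min"`), the normalisation convention for
read-depth-heterogeneous amplicon tables; explicit depths drop
shallower samples with a warning. Chao1 uses the bias-corrected form
S_obs + F1(F1−1)/(2(F2+1)), defined even without doubletons; Shannon
uses natural logs. Bray–Curtis, PCoA (double-centring, eigenvalues
reported including negative ones, no correction), one-way PERMANOVA,
ANOSIM and Mantel tests are implemented directly with an explicit
permutation contract: 999 permutations by default, p = (1 + exceed) /
(1 + n_perm), and an integer seed that fully determines the result
while leaving the caller's RNG stream untouched. The two-factor design
is handled by running tests within crop season; a multi-factor
PERMANOVA decomposition is out of scope.

## Co-occurrence networks

Counts are converted to relative abundance per sample; taxa present in
fewer than 4 of 16 samples are dropped (prevalence filters suppress
correlations driven by shared zeros; the cutoff is an argument).
Spearman correlation is the default — rank methods are the standard
compromise for compositional count data — with Pearson behind a flag.
Edge criteria are |r| > 0.7 and raw p < 0.05; the absolute value
matters because negative co-occurrences are biologically meaningful and
the positive/negative edge ratio is a reported topology metric.
Benjamini–Hochberg adjustment is available but off by default to match
the raw-p convention of the field. P-values use the t approximation for
the rank correlation, the same approximation the Hmisc ecosystem uses.

Modules come from fast-greedy modularity maximisation on the unsigned,
unweighted graph, with the dendrogram cut at maximal modularity and
ties resolved toward the coarsest partition (so a complete graph is one
module). Zi is the within-module degree z-score with **population**
standard deviation (the original role-cartography formulation); Pi is
the participation coefficient 1 − Σ (k_it/k_i)². Roles partition the
plane at Zi = 2.5 and Pi = 0.62; module hubs, network hubs and
connectors together form the keystone set. Module eigengenes are first
principal components of the standardised member-abundance matrix,
sign-oriented toward the module's mean profile.

With four replicates per treatment, a per-treatment network (four
samples) cannot support correlation inference — the pairwise
correlation routine requires at least five samples — so the pipeline
builds one pooled 16-sample network. Per-group networks remain
available for designs with more replicates. Pooling across a strong
treatment gradient couples taxa through the shared dose response, which
lowers modularity relative to within-group networks; this is a property
of the design, not of the estimator.

## PLS path modeling

`fit_plspm()` estimates reflective (mode A) latent blocks with the
centroid inner scheme — the defaults of the classical PLS-PM software
family — iterating outer weights (covariances with the inner proxy) and
inner proxies (sign-weighted sums of adjacent latent scores) until the
largest change in normalised outer weights falls below 1e-7, capped at
300 iterations. Standardisation uses population variance so latent
scores have exactly unit variance. Path coefficients are OLS
coefficients among latent scores; loadings are indicator–latent
correlations; GOF = sqrt(mean squared loading × mean R²), with
0.40 < GOF ≤ 1.00 the conventional acceptance band (strict at 0.40).
Indicators with |loading| < 0.5 are pruned (strictly below; 0.5 is
retained) and the model refitted. Significance is assessed by row
bootstrap with percentile intervals — the resampling scheme is this
package's choice, as path-model significance conventions vary.

The shipped inner structure follows the trial's causal narrative:
amendment dose → {physical, chemical, biological} soil properties
(chemical → biological), all three → soil quality → yield; any acyclic
user structure is accepted.

## Group comparison

Two-way ANOVA is balanced-only with interaction; unbalanced layouts are
rejected rather than silently reweighted. Duncan's multiple range test
computes critical ranges from studentized-range quantiles at the
protection levels α_p = 1 − (1−α)^(p−1) and applies the classical
multiple-range protection rule: a pair differs only if every enclosing
range of sorted means is itself significant. Letters are assembled with
the insert-and-absorb algorithm; ties in means break by group label,
making the display deterministic. Letter panels are computed within
crop season, matching how such trials annotate their figures.

## The synthetic study generator

The generator is first-class, tested code; its defaults are the study
conditions everything else is exercised under.

* **Design**: 4 treatments × 4 replicates × 3 seasons (48 plot-season
  rows). Indicator baselines use the trial's pre-experiment topsoil
  values where published (pH 4.67, EA 3.31 cmol·kg⁻¹, SOM 26.67
  g·kg⁻¹, AN 145.25, AP 24.44, AK 309.50 mg·kg⁻¹, and the four
  exchangeable base cations); indicators without a published baseline
  (ExH, ExAl, CEC, TN, TP, TK, CAT, UE, BD) carry plausible values for
  an upland red soil and are flagged as synthetic in the truth record.
  Dose–response slopes are linear (e.g. +0.07 pH units per t·ha⁻¹,
  giving about +1 pH unit at the highest dose) with small Gaussian
  noise; TEB is derived exactly as ExK + ExNa + ExCa + ExMg.
* **Sieve masses** are differenced from the exact cumulative power law
  at a planted D (2.6 at dose 0, falling slightly with dose) and
  multiplied by lognormal noise (sd 0.05), so the fitting code can be
  validated against closed-form truth.
* **Communities** follow a latent Gaussian block-factor model: three
  modules per kingdom whose members share a factor at correlation 0.9,
  half of the taxa left as unstructured background, counts drawn
  multinomially at a lognormally jittered depth (20,000 ± 20%). The
  background fraction matters: in a fully structured community,
  closure (relative abundances summing to one) makes distinct blocks
  strongly anti-correlated, and unsigned modularity would merge them —
  unstructured taxa buffer the denominator, as they do in real ASV
  tables. The treatment shift on block means (2.5 units per
  standardised dose) produces the pronounced treatment separation such
  trials report (ANOSIM R around 0.8–0.95 at this design size); one
  planted hub per module straddles two block factors. What the
  generator does **not** emulate: sequencing error, taxonomic
  structure, overdispersion beyond the multinomial, or genuinely
  compositional (log-ratio) covariance — conclusions about real data
  should lean on the closed-form and oracle tests, not on resemblance
  of the synthetic communities to any particular habitat.
* **Structural data**: a linear-Gaussian chain dose → chemical →
  quality → yield with paths 0.7/0.6/0.3 and three indicators per
  latent at loading 0.97. The high loading is deliberate: PLS composite
  scores attenuate paths by roughly the squared composite–latent
  correlation, and 0.97 keeps that bias below 0.02 so parameter
  recovery is meaningful at the simulated sizes (n = 1000 by default).

All generators derive their streams from one master seed and restore
the caller's RNG state, so a pipeline run is reproducible end to end
(`run_pipeline()` writes a manifest with a config hash; identical
config and seed reproduce every artifact byte for byte).

## Numerical choices and degenerate inputs

* Constant indicators cannot be scored (error) and are dropped from
  per-season PCA when a season renders them constant.
* PERMANOVA/ANOSIM refuse groups of size 1; correlation networks
  refuse fewer than 5 samples; PCoA refuses fewer than 3.
* An empty network (no pair passes the thresholds) is a valid result:
  a 0-node GraphML file is written and topology metrics carry
  undefined flags.
* Zi is defined as 0 in modules whose within-degree is constant;
  isolated taxa never reach the Zi–Pi stage because thresholding drops
  them.
* Rarefaction at a sample's exact total reproduces the sample
  (exhaustive draw), a useful identity for testing.
* Problem sizes in the test suite (e.g. 500 null simulations at 999
  permutations for the PERMANOVA calibration, 200 random datasets for
  the Duncan oracle, n = 1000 for path recovery) were chosen to give
  stable estimates of the quantities checked while keeping a full run
  comfortably fast on a laptop.

## Known limitations

* UniFrac-type phylogenetic distances are not implemented (no trees in
  scope); Bray–Curtis is the distance throughout.
* PERMANOVA is one-way; multi-factor designs are analysed per stratum.
* The random-forest screen some trials use to shortlist SQI drivers is
  intentionally out of scope; any external learner can be run on the
  SQI table and its selections passed to `plspm_spec()`.
* Formative (mode B) blocks, factorial/path inner schemes and
  higher-order latents are not supported.
* Heavy-metal safety assessment of amendment materials is outside the
  package's remit.
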