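---
title: "Methods: isotope routing, label quantification, and the companion expression screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isotope routing, label quantification, and the companion expression screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoroute)
```

# Scope

`isoroute` implements the computational chain behind a pulsed stable
isotope-resolved metabolomics (pSIRM) experiment on central carbon
metabolism — from simulated or measured GC-MS isotopologue intensities to
pathway-level statements about how carbon reaches citrate — together with
the two transcriptome statistics such a study typically pairs with it: a
resampling-FDR gene-selection procedure over replicated knock-down
experiments, and a hypergeometric co-occurrence/mutual-exclusivity screen
over binarized expression calls. Every input the pipeline consumes can be
generated synthetically with planted ground truth, which is how the
package validates itself.

# The citrate forward model

## Per-carbon bookkeeping

Citrate has six carbons. In a single TCA turn they derive from two
sources: two from acetyl-CoA and four from oxaloacetate (OAA), one of the
OAA four being a carboxyl carbon that, in carboxylation reactions, comes
from CO2. We index positions 1–6 with 1–2 acetyl-derived, 3–5 the
non-carboxyl OAA carbons, and 6 the OAA-carboxyl / carboxylation-derived
carbon. Each routing pathway deposits tracer label at fixed positions:

| route | tracer | labelled positions | full-molecule shift | C5-fragment shift |
|---|---|---|---|---|
| oxidative, glucose acetyl-CoA (`f_ox_glc`) | U-13C6-glucose | 1,2 | m+2 | m+2 |
| oxidative glutamine (`f_ox_gln`) | U-13C5-glutamine | 3,4,5,6 | m+4 | m+3 |
| reductive carboxylation (`f_red_gln`) | U-13C5-glutamine | 1–5 | m+5 | m+5 |
| pyruvate carboxylase (`f_pc`) | U-13C6-glucose | 3,4,5 | m+3 | m+3 |
| CO2 fixation (`f_fix`) | 13C-bicarbonate | 6 | m+1 | m+0 |
| unlabelled (`f_unlab`) | — | none | m+0 | m+0 |

The five route fractions live on the probability simplex; `f_fix` is
orthogonal, modelling the probability that position 6 carries a
bicarbonate-derived 13C under the bicarbonate tracer. The positional
(not shift-only) bookkeeping is essential: the contrast between the C5
fragment (273 m/z, MSTFA) and the full-molecule fragments (375 m/z MSTFA,
459 m/z MBTSTFA) is what separates reductive carboxylation (C5 keeps all
five labels) from oxidative glutamine metabolism (C5 drops one), and what
makes CO2 fixation visible as an m+1 shift present in full fragments but
absent from the C5 fragment.

Which citrate carbon the 273 m/z fragment loses is not directly
observable from nominal masses; we model it as the
carboxylation-derived/OAA-carboxyl position because that single choice
reproduces all three printed fragment contrasts simultaneously (reductive
m+5 retained, oxidative m+4 dropping to m+3, bicarbonate m+1 vanishing in
the C5 fragment). It is an inference, exposed in the fragment catalogue
(`lost_carbon_position`) so alternative assignments can be tested.

Only one TCA turn is modelled. Multi-turn scrambling (the m+2/m+3
mixtures produced by repeated cycling) is deliberately out of scope: the
diagnostic readouts used here are interpretable at the first turn, and a
multi-turn model would require flux assumptions the data cannot
constrain.

## Natural abundance and measurement

`convolve_natural_abundance()` folds the tracer MID with a binomial
envelope over all carbons of the derivatized fragment (metabolite carbons
retained plus derivatization-reagent carbons) at `p13c = 0.0107` by
default. Only carbon isotopes enter the envelope; Si/H/O/N isotopes of
the derivatization groups are ignored because the downstream correction
path is empirical-reference-based, not theoretical. `p13c = 0` is exactly
the identity.

`generate_intensity_table()` emits the wide peak-area schema
(`metabolite`, `fragment_mz`, `mass_shift`, one column per sample)
including a cinnamic-acid internal-standard row. Noise is log-normal
multiplicative (mean-one, given CV) plus a uniform additive floor, both
seeded; with both turned off the table is exactly the scaled convolution,
which the quantification chain's round-trip tests rely on.

# The pSIRM quantification chain

Technical duplicates are averaged on the intensity scale first. Relative
metabolite quantities are each metabolite's quantifier-fragment total
(summed over shifts) divided by the sample's cinnamic-acid intensity —
invariant to per-sample scale. The quantifier is the fragment retaining
the most metabolite carbons, a catalogue-level choice.

Label incorporation is estimated against a measured unlabelled reference
spectrum (an identification standard reflecting natural 13C abundance):
the reference pattern is scaled to the sample's shift-0 mass, mass above
that prediction at shifts ≥ 1 is tracer-derived excess, and

$$\mathrm{incorporation} = \frac{\sum_{j\ge1} e_j}{s_0 + \sum_{j\ge1} e_j},
\qquad e_j = \max(s_j - s_0\, r_j / r_0,\, 0).$$

Negative excesses (noise pushing measured below expected) are clipped to
zero and their magnitude reported as a QC metric (`clipped_mass`). A
theoretical binomial reference is available as a fallback when no
standard was run, and doubles as the independent oracle in tests.

One property of this estimator is worth stating explicitly: its
denominator is the sample's shift-0 mass plus the excess, which excludes
the natural-abundance satellites of the unlabelled component. With a
non-degenerate reference the estimator therefore returns
$g / ((1-g)\,r_0 + g)$ for a true labelled fraction $g$ — a slight,
reference-dependent inflation (the worked example in
`?label_incorporation` shows 0.5128 for a half-labelled sample against a
[0.95, 0.05] reference). The estimator is exact when $r_0 = 1$; the
package's round-trip validation accordingly runs at `p13c = 0`, where the
forward model and estimator agree to numerical precision on the whole
grid $g \in \{0, 0.1, \dots, 1\}$. On real data the quantity is used
comparatively across conditions, where the common inflation cancels.

The labelled quantity — incorporation times internal-standard-normalized
quantity — is the per-metabolite activity readout; it can never exceed
the normalized quantity, with equality only at full incorporation.

# Routing inference

`extract_routing_evidence()` reads the diagnostic shifts directly
(glucose m+2; glutamine m+4 full / m+3 C5; glutamine m+5; bicarbonate m+1
C6 vs C5) and reports the fixation score — the C6-minus-C5 difference in
m+1 excess, which is 1 for a pure fixation species and invariant to the
unlabelled fraction since both fragments dilute equally.

`fit_routing_fractions()` makes the qualitative contrast quantitative:
it minimizes the summed squared difference between simulated and
observed MIDs across all supplied (tracer, fragment) observations. The
forward model is exactly linear in the six parameters (under the
bicarbonate tracer the fixation term is route-independent), so the
problem is a convex quadratic over the simplex with a box on `f_fix`. It
is solved exactly by enumerating the active sets of the KKT conditions —
at most 96 small linear solves — rather than by an iterative projected
method; ties are broken by the minimum-norm solution. With at most six
unknowns this is both faster and more trustworthy than generic QP
iterations, and it makes the noise-free fit exactly zero-residual for any
simplex point, which the tests assert at 1e-9.

Identifiability is checked up front: the free columns plus the simplex
constraint must have full rank, otherwise the error names the tracers
whose absence makes routes indistinguishable (glucose-only data cannot
separate the two glutamine routes from the unlabelled pool). `f_fix` is
fitted only when bicarbonate-tracer observations are present.

Uncertainty uses a residual bootstrap in its sign-flip (wild) variant
with leverage-standardized residuals, and basic (reflected-percentile)
intervals clipped to the parameter range. The variant matters here:
multiplicative measurement noise concentrates at the few high-mass MID
positions, so permuting residuals across positions dilutes the noise
where it matters and produces severely anti-conservative intervals,
while raw residuals understate the error at exactly the high-leverage
diagnostic positions the fit uses. With the standardized sign-flip
scheme, interval coverage on 1%-noise synthetic data is at the nominal
level within Monte-Carlo error (checked at ≥ 80% pooled coverage in the
test suite). Default 200 replicates, seeded.

`compare_conditions()` applies two-sided unpaired Student's t-tests
(equal variance; Welch behind a flag) per measure and condition pair,
with no multiple-testing correction — matching how small-n (n = 3)
tracer experiments are conventionally reported. Degenerate inputs
(both groups constant and equal) return t = 0, p = 1 rather than an
error.

# Expression selection and the resampling FDR

The experiment unit is a *set* of independent experiments, each
contributing one control and one sample log2 vector over a shared gene
universe (probe sets are intersected). Genes consistently below the
per-sample median in *every* sample of every experiment are discarded —
rising above the median anywhere retains a gene. Whether that filter
should act per sample or per dataset is ambiguous in common usage; the
per-sample reading is implemented because it is the stricter notion of
"consistent", and the behaviour is pinned by tests.

The z-transformation divides each gene's log2 fold change by an
intensity-dependent spread estimate: genes are ranked by mean expression
and sigma is the rolling 1.4826-scaled median absolute deviation of the
fold changes in a 200-gene window (edges extend the first/last complete
window). The window default balances locality against estimator noise —
at 200 points the MAD has ~7% relative error, small against the
intensity trends it tracks. Any other error model can be supplied as a
`sigma(a, fc)` function, making the rest of the chain reusable verbatim.
Zero fold changes map to z = 0 even where the local spread estimate is
zero.

Selection takes, per experiment, the (1 − q) type-7 quantile of |z| as
the threshold (default q = 0.10, i.e. the top decile) and keeps genes at
or above threshold in *every* experiment with one consistent, nonzero
sign. Ties at the boundary are selected (≥, not >). The procedure is
invariant to rescaling any single experiment's z values and monotone in
q, both asserted as properties.

The FDR of this selection is estimated by resampling: each of 1000
default draws rebuilds, for every experiment independently, a null z
vector by sampling that experiment's z values with replacement — three
independent draws per null dataset, destroying the gene linkage across
experiments while preserving each experiment's marginal z distribution,
which the decile thresholds depend on. The estimate is the mean null
selection count over the observed count, clipped to [0, 1]. A
sign-permutation null would preserve linkage of |z| and test only sign
consistency; the chosen null tests the full selection event and is the
default. On planted-signal synthetic data the estimate tracks the
label-derived truth (within ±0.05 at 2000 genes across 20 seeds in the
acceptance checks); on pure-null data it reports ≈ 1, as every discovery
is then false. When nothing is selected the FDR is reported as
undefined, not zero.

# The exclusivity screen

Expression is binarized by one of two recorded rules: strictly above the
gene's mean plus one SD (n−1 denominator) — the rule suited to large
tumor panels — or strictly above the gene's median profile, the rule
suited to cell-line panels. Thresholds are retained for audit; boundary
samples are never high; constant genes yield all-false calls with a
warning under the mean+SD rule.

For a gene pair the joint-high count under fixed margins is
hypergeometric; the upper tail is the co-occurrence p-value and the lower
tail the exclusivity p-value, and the two overlap in exactly P[X = k].
The odds ratio uses the exact cell counts, with the Haldane–Anscombe 0.5
correction added to every cell only when some cell is zero — keeping
uncorrected exact ratios where they are defined. Classification bands
default to OR < 0.1 (mutually exclusive) and OR > 2 (co-occurring),
configurable. Venn partitioning reports every region count plus, for a
designated pair, the expressor-union size and the percentage of union
members high for exactly one gene. Clustering z-scores each gene across
samples, uses Euclidean distance with average linkage (flag-switchable),
and pairwise Pearson correlations carry two-sided t-based tests of zero
correlation; pairs involving constant genes are reported as missing.

# What the generators emulate — and what they do not

The intensity-table generator reproduces the *structure* of a GC-MS
peak-area export: isotopologue intensities that are a tracer MID times a
natural-abundance envelope times quantity, multiplicative log-normal
noise, an additive floor, and an internal-standard channel. It does not
simulate chromatography or spectra: no retention times, no co-eluting
interferences, no detector saturation, no multi-element isotope fine
structure. Passing round-trip tests therefore demonstrates correctness
of the quantification arithmetic, not robustness to peak-picking or
deconvolution errors, which are upstream of this package's scope.

The expression generator plants a fixed fraction of regulated genes with
a consistent signed log2 effect across experiments and
intensity-dependent Gaussian noise (spread inflated up to ~5-fold at the
low-intensity end, mimicking array behaviour). It does not emulate probe
cross-hybridization, batch effects, or correlated gene modules — so the
FDR calibration results speak to the estimator's behaviour under
independent noise, and real-data FDRs can differ where genes are
co-regulated.

The association generator constructs exact 2×2 cell probabilities
preserving the requested marginals while depleting or enriching the
joint-high cell; `strength = 1` gives hard exclusivity (zero joint highs)
or maximal nesting.

# Numerical choices and problem sizes

MIDs must sum to one within 1e-9 and are clipped at zero after
renormalization. The routing fit treats constraints as active below
1e-9 slack and renormalizes the returned simplex point. Quantiles are
type 7 throughout. Seeds are explicit arguments on every stochastic
operation; the demo pipeline derives per-stage seeds deterministically
from one global seed.

The validation suite exercises: the incorporation round trip on an
11-point grid; routing recovery over 100 random simplex draws at 1%
multiplicative MID noise (median absolute error per fraction < 0.03
observed at ~0.002); selection-versus-oracle agreement over 165 random
small tables; FDR calibration at 2000 genes, 5% regulated, 20 seeds with
200 draws each; and exact hypergeometric enumeration for all margins up
to n = 12. These sizes were chosen so the full suite characterizes each
estimator's behaviour while remaining a routine desk-scale run.

# Known limitations

- Single-turn TCA model; no EMU/cumomer network, hence no whole-network
  flux estimates — the scope is the citrate-centred routing question.
- The label-incorporation estimator's mild reference-dependent inflation
  (above) is inherent to its definition; comparative use across
  conditions is unaffected.
- The C5-fragment lost-carbon assignment is an inference from printed
  fragment contrasts, not from fragmentation chemistry.
- The bootstrap quantifies measurement noise given the model; it does not
  propagate uncertainty in the fragment catalogue or natural-abundance
  correction.
- Real-data replication of published cell-line panel counts depends on
  the expressor-rule interpretation; both rules are exposed and recorded
  in output metadata so either reading can be reproduced.
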