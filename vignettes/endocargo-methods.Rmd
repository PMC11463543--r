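---
title: "Models and methods behind endocargo"
author: "endocargo maintainers"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`endocargo` re-implements, over synthetic data with known ground truth, the
computational arc of an organelle-immunoprecipitation proteomics study of
endosomes and lysosomes in stem cells and induced neurons: differential
enrichment of tagged-organelle IPs over untagged controls, compartment and
overlap summaries, trajectory clustering across differentiation, candidate
endocytic-cargo classification, and sorting-motif discovery with a
structure-prediction-score screen. This vignette records the models, the
parameters that matter, and the design decisions taken where the published
analysis left the method open.

## The quantitative substrate

The pipeline starts at protein-level reporter intensities from multiplexed
isobaric labelling (TMT): a protein-by-channel matrix paired with a design
table mapping channels to tagged/control condition, IP type (endosomal via
EEA1 or lysosomal via TMEM192), cell state and replicate. Upstream spectral
processing is out of scope. Zero or negative intensities are recorded as
missing on input, never imputed: every statistic downstream works on the
log2 scale, where zero has no meaning, and imputation would manufacture
precision the data does not carry. Proteins without at least two finite
observations per group are reported untested rather than guessed at.

## Normalization

Channels are log2-transformed and median-centred to the grand median of the
channel medians. A constant per-channel scale factor (pipetting, labelling
efficiency) cancels exactly. One property deserves emphasis: median
centring assumes the median protein is unchanged between tagged and
control channels. In an organelle IP a sizeable minority of proteins is
genuinely enriched, which raises the tagged-channel medians and shifts
every fold change down by that amount (about 0.2–0.3 log2 units at the
default simulation composition). The calls are robust to this — the
fold-change cutoff of 1.0 sits far above the shifted null — but exact
fold-change recovery against simulation truth is only available on the
uncentred scale, which `normalize_log2(center = FALSE)` exposes.

## Moderated enrichment statistics

With three or four replicates per condition, per-protein variance estimates
are unstable; the standard remedy is empirical-Bayes moderation. The model
is the scaled-F/inverse-chi-square hierarchy familiar from moderated
t-statistics: per-protein pooled two-group variances $s^2_g$ on $d_g$
degrees of freedom are shrunk toward a prior $(d_0, s_0^2)$, giving

$$ s^2_{post} = \frac{d_0 s_0^2 + d_g s^2_g}{d_0 + d_g}, \qquad
   t = \frac{\overline{x}_{tag} - \overline{x}_{ctl}}
            {\sqrt{s^2_{post}(1/n_t + 1/n_c)}} $$

with $t$ referred to a t distribution on $d_0 + d_g$ degrees of freedom
(normal when $d_0 = \infty$). The prior is estimated by moment matching on
the log scale: under the model, $E[\log s^2_g]$ and
$\mathrm{Var}[\log s^2_g]$ have closed forms in the digamma and trigamma
functions, and $d_0$ is recovered by Newton inversion of the trigamma
identity. Two limits are exact and tested: $d_0 = 0$ reproduces the
ordinary pooled-variance two-sample t, and $d_0 = \infty$ fixes the
variance at $s_0^2$. When the observed variances carry no spread at all
the prior is a point mass at the common variance. With fewer than 20
usable proteins the fit falls back to $d_0 = \infty$ with
$s_0^2 = \mathrm{median}(s^2)$ and warns, since the trigamma inversion is
then unreliable.

Multiple testing uses step-up Benjamini–Hochberg with enforced
monotonicity, implemented directly (and tested against an $O(n^2)$
brute-force oracle as well as an independent reference implementation). A
protein is called enriched when $\log_2 FC \ge 1.0$ **and** $q \le 0.01$ —
the cutoffs the study draws on its volcano plots — both exposed in
`run_config()`. Two-sided p-values are used; the one-sided biological
reading (enrichment, not depletion) enters through the positive
fold-change cutoff. Strata (IP type × cell state) are analysed
independently, with no cross-stratum variance sharing, mirroring the
separate published analyses.

## What the simulator emulates — and what it does not

`simulate_ip_experiment()` generates
$\log_2 y_{ic} = b_i + \beta_i\,[c\ \mathrm{tagged}] + \varepsilon_{ic}$
with baselines $b_i \sim N(20, 2^2)$ and noise
$\varepsilon \sim N(0, 0.35^2)$ log2 units — a spread typical of
well-behaved TMT reporter data. Compartment structure drives the effects:
proteins of the IP's target compartment carry $\beta = 2.5$; a shared
endolysosomal core (15% of endosomal/lysosomal proteins) cross-captures
into the other IP at $\beta = 1.5$, giving the Endo∩Lyso overlap planted
truth; and 30% of plasma-membrane proteins are "captured" into the Endo-IP
at the full effect — these are the planted endocytic cargo, the 30%
matching the study's headline cargo fraction. Effect sizes were chosen so
that volcano-plot separation at the 1.0 fold-change cutoff is achievable
but not trivial at triplicate scale. The default compartment mix (8%
lysosome, 8% endosome, 14% plasma membrane, 12% mitochondrion, 12% ER, 6%
Golgi, 40% cytosol) is a rounded caricature of a deep cell-line proteome.

Deliberately not modelled: reporter-ion ratio compression and isotopic
impurity (no interference data to calibrate against), peptide-level
roll-up, plex bridging and batch effects, and any state-specific baseline
difference between hESC and iNeuron (both states share one biological
truth, so state-selective calls in the synthetic study arise from noise
alone — the state-selectivity classifier is exercised on explicit ratio
tables instead). Passing tests therefore demonstrate statistical
correctness and calibration of the machinery, not robustness to every
artefact of real TMT data.

Sequence simulation draws residues i.i.d. uniform over the 20-letter
alphabet — deliberately not proteome-weighted, so the background motif
match probability has the closed form used in tests (for the SNX27 grammar
$(2/20) \cdot (8/20) = 0.04$ per sequence). Planted SNX27 motifs occupy
the final three residues; planted SNX17 motifs sit at least 10 residues
from either terminus. Accidental background matches are detected post hoc
with the package's own scanners and recorded in the truth table, so
scanner sensitivity and specificity are measured against complete truth.
All generators draw from named substreams of one base seed: adding a
generator never perturbs another's output.

## Trajectory clustering

Differentiation profiles are linearly interpolated over missing
timepoints (boundary gaps carried from the nearest observation), z-scored
per protein with the population standard deviation, and clustered with
k-means (20 restarts per k, fixed seed) over k = 2..10; k is chosen by
maximum mean Euclidean silhouette. The published analysis names no
clustering method; k-means with silhouette selection was adopted as a
deterministic, standard, testable stand-in. Clusters are renumbered by
centroid peak day (earliest first) so labels are reproducible and
row-order invariant. The three default trajectory templates — monotone
up, monotone down, transient mid-course peak — are the minimal shape set
that exercises the ordering logic.

## Cargo classification

A candidate endocytic cargo is an enriched protein with at least one
transmembrane segment that is annotated as cell-membrane localized — the
rule exactly as published, on a boolean annotation column; mapping
location vocabularies onto that boolean is the data producer's job. Cargo
fractions are reported unrounded, to one decimal, and rounded half-up to
the integer percent used for headline reporting (the published counts
152/504 and 70/347 give 30% and 20%). Whether the published 241-candidate
count was computed against enriched-only or enriched-plus-identified
proteins is ambiguous in the text; `select_candidate_cargo()` takes
whichever protein set the caller means, making both readings available.

## Motif grammars and the screen

The SNX27 PDZ grammar is C-terminal [S/T]-x-Φ; the SNX17 FERM grammar is
Φ-x-N-x-x-[Y/F] at any start position (overlapping windows allowed). The
hydrophobic set Φ = {A, V, L, I, M, F, W, Y} is the Kyte–Doolittle-positive
eight and is a parameter, since "hydrophobic" has no single canonical
definition. The published "and related motifs" for SNX17 is *not*
expanded: the implemented grammar is exactly what is printed, and variant
grammars stay off by default to avoid silent grammar creep. Upstream
acidity (D/E in positions −4..−8) is counted and reported for SNX27 hits
because it enhances PDZ binding, but it is never used as a filter — the
study treats it the same way. SNX17 scans can be restricted to the region
after the last transmembrane span when a topology is supplied; the default
scans the full sequence and flags the fallback, since topology is rarely
available.

Peptide queries are 15-mers: the exact C-terminal suffix for SNX27 (as
screened in the study), and for SNX17 — whose window length the study does
not state — a motif-anchored 15-mer (4 upstream + motif + 5 downstream,
shifted inward at termini) chosen to mirror the SNX27 window length.
Controls for the SNX27 screen are the C-termini of proteins carrying an
SNX17 motif but no SNX27 motif, the published control construction. The
ipTM threshold is strictly greater than 0.6; a score of exactly 0.6 fails.
A protein passes when any of its windows passes, keeping motif-level and
protein-level tallies distinct. No structure prediction is performed:
`run_screen()` ingests externally computed scores keyed by (protein,
peptide, motif type), and `mock_predictor()` is a deterministic,
truth-informed test double (planted ~N(0.8, 0.1), background ~N(0.3, 0.1),
clamped to [0, 1], hashed per query) for exercising the screen logic.

Motif logos are position frequency matrices with pseudocounts (default
0.5 per residue) against a uniform background; information content is
$IC_j = \log_2 20 - H_j$ bits. SNX27 windows are right-aligned with gap
padding excluded from counts; top/bottom-N selection ranks the whole
screened pool (candidates and controls) by ipTM with ties broken by
protein identifier. Ranking candidates alone cannot separate
motif-position information content — every candidate carries the motif by
construction — which is why the pool includes controls. Note that the Φ
position constrains 8 of 20 residues, so its single-position IC is a weak
signal at N = 10; the [S/T] anchor (2 of 20) is the discriminating
position.

## Numerical choices and degenerate inputs

* Quartiles use the linear order-statistic interpolation that R calls
  type 7; tests check them against a from-scratch sort-based oracle.
* BH propagates missing p-values as missing; they do not count toward the
  number of tests.
* `overlap_sets()` is restricted to 2–3 sets, the diagram sizes the study
  uses; region counts are tested to partition the union exactly.
* The hypergeometric over-representation p is $P[X \ge k]$, tested against
  exhaustive enumeration of all $\binom{N}{n}$ draws for $N \le 12$; the
  test universe defaults to the quantified stratum, not the whole
  proteome, to avoid detection-bias inflation.
* The state-selectivity threshold (|log2 ratio| ≥ 1 for higher/lower) is
  not printed in the study; it adopts the study's own fold-change
  convention elsewhere and is exposed as `tau`.
* Zero-variance profiles, all-missing channels, empty control sets, short
  peptides and out-of-bounds hit coordinates all have defined behaviour
  (drop-and-report, fatal, warn-and-empty, flag, fatal respectively)
  exercised in the test suite.

## Problem sizes

The shipped analysis scripts and acceptance checks run at desk scale,
chosen to estimate each quantity stably: 1,500 proteins per simulated IP;
50 null runs of 200 proteins for type-I calibration; 10 planted-effect
runs of 300 proteins for sensitivity/FDR; 10,000 random 20-mers for the
motif background rate; 300 sequences for the screen; 300 profiles for
clustering. All are parameters, not limits.

## Known limitations

Single log-normal noise term; no missing-not-at-random structure; uniform
residue background; flat gene sets (no ontology-graph propagation); no
real structure predictor (score ingestion only); identical biological
truth across cell states. Conclusions about real organelle-IP data should
rest on the statistical properties demonstrated here plus domain judgment
about the artefacts listed above.
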