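---
title: "Models and methods: enterotype stratification, pedigree REML, and simulated holobiont selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistical machinery it
implements: the models, their assumptions, the tunable parameters and their
defaults, the numerical choices inside the REML engine, what the synthetic
generators do and do not emulate, and the known limitations. Nothing here
states an empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## 1. Abundance tables and transforms

Genus tables are samples × taxa matrices of counts or percent relative
abundances. The pre-processing chain mirrors standard 16S practice:

* **Rarefaction** subsamples each sample without replacement to a common
  depth (default 7,000 counts, the depth the downstream defaults assume).
  Samples below the depth are dropped, never scaled up, and the dropped ids
  are attached to the result — scaling would understate the sampling
  variance of rare taxa. The subsampling is delegated to
  `vegan::rrarefy()` under a caller-supplied seed.
* **Alpha diversity** is richness (taxa with nonzero count) and the Shannon
  index in nats. The log base is a convention choice; nats match the JSD
  computation below so the two share one entropy definition.
* **Log transform**: relative abundances on the percent scale are
  normalised as `log(x + 0.01)`. The pseudo-count is interpreted on the
  abundance (percent) scale, not as a centred log-ratio, because that is
  where zeros are removed; a CLR variant can be layered on top by the user
  if compositional effects are a concern.
* **Filters**: taxa are kept when their mean relative abundance across
  samples exceeds 0.1% (strict), and optionally when their zero fraction is
  strictly below 50%. The mean-abundance reading of "more than 0.1% of the
  total" is equivalent to the taxon-total/grand-total reading whenever all
  samples have equal depth (as they do after rarefaction). The 0.1% filter
  is applied before the zero filter by default; the order is configurable
  and immaterial for equal-depth tables in practice. `filter_genera()` is
  idempotent.
* **Selection-criterion aggregation** sums the SILVA sub-genus labels
  (three Prevotella labels, four Ruminococcus labels) into the composite
  traits the breeding rules rank on; absent members contribute zero and are
  reported.

## 2. Enterotype stratification

Pairwise sample distances are `sqrt(JSD)` — the square root of the
Jensen–Shannon divergence of the samples' genus proportions — which is a
bounded metric (≤ √ln 2). Zeros are replaced by a 1e-12 pseudo-count and
rows renormalised; the perturbation is orders of magnitude below the
distances it protects.

Clustering is partitioning around medoids on that distance. The medoid
initialisation is drawn at random under a seed and refined by the standard
swap phase (`cluster::pam`); the optimal cluster number is the maximiser of
the distance-based Calinski–Harabasz index

`CH(k) = ((SST − SSW)/(k−1)) / (SSW/(n−k))`,

with `SST`/`SSW` the total and within-cluster average squared distances.
The silhouette criterion would be an alternative; CH is the convention of
the enterotyping literature this follows.

The **stability filter** repeats the k = 2 clustering (default 100 times),
varying the PAM initialisation seed per repeat — the minimal stochastic
element of the procedure; re-drawing the rarefaction each repeat is
available through the pipeline but not claimed as the original procedure,
which does not specify the source of variation. Each repeat's clusters are
labelled PM or RT by the mean relative abundance of the PM anchor taxa
(the Prevotella group plus *Mitsuokella*; higher mean → PM, ties toward
cluster 1). A sample's stability is the fraction of repeats agreeing with
its modal label; any sample that ever switches (`stability < 1`) is
reported as `"unstable"`, reproducing the practice of keeping only animals
that never change group. Ordination for display is classical PCoA
(Gower-centred double-centring, eigendecomposition), with negative
eigenvalues reported rather than hidden.

## 3. The animal model and its REML engine

`animal_reml()` fits, for one or two traits,

y = Xb + u_a + u_c + e,  with  var(u_a) = Σ_A ⊗ A,  var(u_c) = Σ_C ⊗ I_litters,  var(e) = Σ_E ⊗ I_n,

where `A` is the numerator relationship matrix built by the tabular
recursion (`a_ii = 1 + a_{s,d}/2`, `a_ij = (a_{j,s} + a_{j,d})/2`; unknown
parents are unrelated founders) over **all** pedigree ancestors, and the
fixed effects default to sex and batch. Each animal carries one record, so
`Z_a A Z_a'` is a submatrix of `A` and the variance matrix `V` is assembled
densely; at the study scale (1,067 records, ~1,130 pedigree animals) one
Cholesky of `V` costs a fraction of a second, which makes the direct dense
formulation both simpler and more robust than mixed-model-equation
manipulations at this size. This is a deliberate design bound: the engine
targets designs up to a few thousand records, not national evaluations.

Each iteration computes the REML log-likelihood
`-2 logL = log|V| + log|X'V⁻¹X| + y'Py`, the analytic scores
`∂logL/∂θ_i = -(tr(P V̇_i) − y'P V̇_i P y)/2`, and the average-information
matrix `AI_ij = (Py)' V̇_i P V̇_j (Py) / 2`. The update is Newton-like with
several safeguards, in order:

1. **Active set**: a variance at its floor (1e-10) with an outward score,
   or a covariance pinned at |correlation| ≥ 0.999, is frozen for the step
   so the AI curvature describes only free directions.
2. **Marquardt damping**: the step solves `(AI + λ·diag(AI))Δ = s` for the
   first λ in {0, 1e-4, …, 1e6} that increases the likelihood.
3. **Trust cap**: no variance may shrink by more than 75% or grow by more
   than 3× (plus a small absolute allowance) in one step — wild early AI
   steps otherwise jump into boundary basins.
4. **EM fallback**: if no damping level helps, the expectation-maximisation
   update `Σ_g ← Σ_g + Σ_g (Q_g − T_g) Σ_g / q_g` is taken.

Convergence requires a log-likelihood change below 1e-8 together with a
relative parameter change below 1e-6; three consecutive stalled likelihood
changes, or a gain below 1e-3 over ten iterations, are treated as
convergence on a constraint boundary or likelihood ridge and flagged
(`boundary`), because the components there are determined only up to a
flatness the reported standard errors make visible. Past 200 iterations the
fit errors with its likelihood trace. Standard errors come from the inverse
AI matrix; `h²`, `c²` and `r_G` get delta-method errors. Estimated genetic
correlations are hard-bounded in [−1, 1] with a clipped flag.

The engine is verified three independent ways in the test suite: exact
agreement with the closed-form ANOVA sire-model estimator on a balanced
half-sib design; agreement of the maximised likelihood and components with
a separately coded direct likelihood optimised by Nelder–Mead (uni- and
bivariate); and numerical-gradient checks of the analytic scores.

Two properties of the estimator on study-sized designs are worth knowing
and are visible in the recovery runs rather than hidden: (i) variance
ratios recover their truth on average, but near-zero components truncate at
the boundary, which inflates small-`h²` means on small designs; (ii) the
genetic-correlation estimate is attenuated toward zero by a few hundredths
at n ≈ 1,000 — the likelihood probe in the development tests confirms the
optimizer sits at the exact REML maximum, so this is finite-sample
behaviour of the estimator itself, not an optimisation artefact.

**Binary enterotype.** The PM/RT label is analysed as a 0/1 trait on the
observed scale — matching how such a binary enterotype value is treated as
an ordinary trait — with the Dempster–Lerner liability conversion
`h²_liab = h²_obs · p(1−p)/z²` reported alongside.

## 4. The breeding-scheme simulator

The simulator reproduces the printed design exactly: founders 30 × 30 (316
G0 piglets in 30 litters), then per line and generation 6 sires, 30 dams,
30 litters, with recorded offspring 133/139 (G1), 114/114 (G2), 126/125
(G3) — 1,067 phenotyped animals. Offspring counts are distributed over the
30 litters as a multinomial with equal probabilities (a Poisson litter-size
model conditioned on the printed totals, which the source reports instead
of litter-size distributions). Sexes are Bernoulli(½). Farrowing batches
(3 per generation, shared by both lines) carry N(0, 0.3²) fixed effects on
every trait; sex adds 0.15 SD. Both magnitudes are unreported nuisance
parameters chosen at realistic scale; they are estimated out by the fixed
effects in every analysis.

Six traits are simulated on the phenotypic-SD scale: the four
selection-target taxa, post-weaning average daily gain, and the enterotype
liability. Defaults: `h² = 0.3` for the taxa and the liability, `0.2` for
gain; `c² = 0.05` throughout. The genetic correlation matrix is a
single-factor model `R = LL' + diag(1 − L²)` over an "enterotype axis":
loadings 0.95/0.8 for the PM taxa, −0.95/−0.8 for the RT taxa, 0.5 for
gain, 1.0 for the liability. This encodes the reported structure — very
high correlations (|r_G| > 0.9) between the directly selected genera of
opposite enterotypes, moderate 0.32–0.52 correlations of the taxa with
growth (positive on the PM side, negative on the RT side) — and makes the
liability the community axis itself, the strongest coupling the factor
model admits. The construction is positive semidefinite by design; an
explicit `rG` matrix can replace it and is checked for PSD.

Breeding values propagate as midparent plus a Mendelian deviation with
covariance `Σ_A/2 · (1 − (F_s + F_d)/2)` (inbreeding from the accumulated
relationship matrix); litter deviations are shared by littermates and
independent across traits; residuals are independent across traits. The
enterotype is PM when the liability *phenotype* exceeds the G0 median —
fixing the threshold at the base population makes later prevalences
directly comparable across generations, and leaves the observed base split
as sampling noise around 50/50.

Selection follows the published rules verbatim (two-stage intra-sire
ranking of boars on batch-precorrected phenotypes, one boar per sire;
litter-capped ranking of sows out of G0, free ranking later; balanced
matings avoiding any shared parent, found by most-constrained-first
backtracking). When a sire family happens to have no sons, the open slots
are filled with the best remaining males regardless of family — the only
departure from "one boar per sire", forced by small simulated litters.

**What the simulator will and will not reproduce.** Feeding its
random-mating output back through `animal_reml()` recovers the configured
`h²`, `c²` and `r_G` — the package's principal end-to-end test. Under
selection, the expected HPM-line PM prevalence rises to roughly 79% by G3
at 50-replicate scale, with the RT line mirrored. The realized experiment
reported 87% and 70% — a single realization, asymmetric between lines,
that the symmetric genetics-only model does not reach even with the
liability fully loaded on the community axis: with liability `h² = 0.3`
and the printed selection intensities (one boar per sire chosen largely
within family, half the sows kept), the cumulative genetic shift is
bounded near 0.85 phenotypic SD (≈ 80% prevalence). Mechanisms outside the
model — vertical dam-to-litter microbiota transmission above all — would
amplify a real response beyond this bound; simulating them is explicitly
out of scope. A per-line selection-accuracy multiplier is the natural knob
for exploring the asymmetry but no value is asserted for it.

## 5. Response contrasts

Per feature, an ordinary least-squares fit of
`value ~ sex + generation + generation:batch + generation:line` (batch
recoded within generation, i.e. nested) on variables standardized to unit
variance yields the HPM−HRT least-squares-mean difference within each
generation, its unadjusted t-test p-value, and a Tukey studentized-range
p-value adjusted over all pairwise line × generation cell comparisons
(`emmeans`). Standardized, centred-standardized and rank-transformed
variants are selectable; differences are reported in SD units and features
are ordered by their G3 difference for the response figure. The
fixed-effects formulation (no litter term) matches the response analysis
it reproduces; contrast degrees of freedom are the OLS residual df.

## 6. Shotgun layer

Gene counts are divided by gene length in kilobases; no library-size
rescaling is built in because the downstream tests are rank-based within
sample-normalised ("relative") mode, which is exposed alongside the raw
normalisation. A metagenomic species' abundance is the mean of its marker
genes' normalised abundances with zeros included — excluding them would
defeat the companion rule that an MGS with fewer than 10% of markers
detected (nonzero raw count; no deeper detection threshold is defined) is
set to zero in that sample. Taxon and KO abundances are plain sums.
Differential abundance uses the two-sided Wilcoxon–Mann–Whitney test
(exact for group sizes ≤ 8 without ties, otherwise the tie- and
continuity-corrected normal approximation), Benjamini–Hochberg q-values
computed separately per feature family (MGS vs KO), Cliff's Delta as the
effect size, and the reporting thresholds q < 0.1, |CD| > 0.7. Pathway
over-representation is the hypergeometric upper tail with the tested KOs
as background, reported below p = 0.05.

## 7. Synthetic-data generators

The genus generator draws, per sample, a logistic-normal composition: each
taxon's mean percent abundance is multiplied by a mean-one lognormal
deviate whose log-SD is back-computed from the reported between-animal SDs
(`sdlog² = log(1 + CV²)`), the vector is renormalised, and counts are
multinomial at a lognormal sequencing depth (mean 20,000). Enterotype mean
profiles default to the reported shotgun group means (Prevotella 44.9 vs
25.7%, Mitsuokella 1.2/0.4, Ruminococcus 0.5/1.3, Treponema 1.2/8.7,
Rikenellaceae RC9 1.8/5.0); the remaining mass is spread over 120
background genera with a power-law profile whose exponent is flatter for
RT (0.7 vs 1.1), which — together with RT's larger background mass —
realises the higher alpha diversity of RT animals. Taxa are independent on
the log scale: the generator reproduces marginal means, dispersions and
the diversity gap, but not the co-abundance network structure of real
communities, so passing tests certify the pipeline's statistics, not
ecological realism.

The shotgun generator plants PM- and RT-enriched species at a configurable
fold-change (default 4×, 12 + 12 planted among 40 species, 15 samples per
group — the shotgun subset's size), with Poisson marker counts and
per-gene dropout, and concentrates the planted species' KOs into dedicated
toy pathways so that the enrichment chain has a recoverable truth.

`generate_study_phenotypes()` is the simulator with selection disabled:
random mating on the printed design, known architecture, injected sex and
batch effects — the input for every parameter-recovery study. Generators
are bit-reproducible under a seed.

## 8. Problem sizes and runtime

The default test suite and the acceptance script are sized for a single
CPU: heritability recovery uses 20 replicates of the 1,067-animal design
(≈ 5 s per two univariate fits), the genetic-correlation study 30
bivariate replicates (≈ 9 s each), the selection surface 50 scheme
replicates (< 1 s each), and the generator checks 500 samples per
enterotype. These sizes put the Monte-Carlo error of each recovered mean
well inside the tolerances asserted for it; larger runs only shrink error
bars that are already dominated by the estimator's own finite-sample
behaviour.

## 9. Known limitations

* The REML engine is dense: fine to a few thousand records, wrong tool
  beyond.
* Unknown-parent groups, repeated records, maternal genetic effects and
  genomic relationship matrices are not implemented.
* Bivariate fits are pairwise; there is no > 2-trait mode, matching how
  the genetic-correlation surface it reproduces was assembled.
* The enterotype liability is a statistical device: it reproduces
  prevalence dynamics through its genetic correlation with the selected
  taxa, not through any mechanistic community model, and no vertical
  microbiota transmission is simulated.
* The 100-repeat stability filter varies PAM initialisation only by
  default; whether the original procedure also re-drew the rarefaction is
  not determinable, and both modes are provided without claiming either.
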