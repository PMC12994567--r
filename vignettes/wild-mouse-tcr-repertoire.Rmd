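---
title: "Methods: TCR repertoire richness, diversity, power laws and sharing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TCR repertoire richness, diversity, power laws and sharing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(wildtcr)
```

# The analysis

A bulk TCR-seq experiment on a cohort of mice yields, for each animal,
four clonotype tables: alpha and beta chains of CD4+ and CD8+ T cells
(the four *receptor types*). Each table row is a clone — an exact CDR3
nucleotide sequence with its V and J gene labels — and a molecule count
(UMI-corrected upstream, so counts estimate transcript numbers).
`wildtcr` implements the cohort-level analysis of such data: how broad
and how even each repertoire is, whether clone sizes follow a power
law, how much any two mice's repertoires overlap, and how all of these
relate to the mice's sex, age and trapping site.

## Clonotype definitions

The unit of analysis is the **amino-acid clonotype**: the triple
(V label, translated CDR3, J label). Distinct nucleotide sequences that
encode the same amino-acid CDR3 under the same V/J are merged, with
counts summed (`collapse_to_aa()`). We deliberately key clonotypes by
the triple rather than by a literal translated V+J+CDR3 concatenation:
with fixed germline references the two are in bijection, and the triple
avoids bundling a germline sequence database into the package.

Records are excluded (`apply_record_filters()`) when the CDR3 is
missing, its length is not a multiple of three, or its frame-0
translation contains a stop codon — a productive-CDR3 reading of
"contains no CDR3". Exclusions are counted per reason so the filter is
auditable. Translation uses the standard genetic code
(`Biostrings::GENETIC_CODE`); no initiator-codon special-casing, since
a CDR3 is an internal fragment.

## Quality control

Receptor-type data for a mouse enter the analysis only if deep enough:
if either chain of a subset has fewer than 5000 molecules, **both**
chains of that subset are dropped (`qc_exclude()`, `qc_cohort()`). The
rule is a strict less-than: exactly 5000 molecules is kept. The paired
drop reflects that downstream comparisons (e.g. alpha vs beta richness
within CD4+) need both chains of a subset to be comparable.

## Richness, down-sampling, diversity

*Repertoire size* `N` is the sum of clone counts; the *unique count*
`U` is the number of distinct clonotypes; *richness* is `U/N`, breadth
normalised for sequencing depth. Because richness is already a
per-molecule proportion, it is computed on the full repertoire (a flag
`richness_on_downsampled` exposes the alternative).

Diversity indices, by contrast, are depth-sensitive, so each mouse is
first **down-sampled without replacement** to the smallest repertoire
size of its receptor type. The procedure is the literal one: replicate
every clonotype by its count, sample the molecule list without
replacement to the target, re-tally. `downsample()` realises this
distribution exactly — a multivariate hypergeometric draw — by sampling
`target` distinct molecule positions from `1:N` and mapping them back
to clones through the cumulative counts, never materialising the
expanded list. The naive expansion sampler survives in the test suite
as the distributional oracle (chi-squared comparison on toy
repertoires, plus the exact hypergeometric marginals).

On the down-sampled repertoire, with `p_i` the proportional abundance
of clonotype *i*:

* Shannon's index `H = −Σ p_i ln p_i` (nats), in `[0, ln U]`;
* Simpson's index `λ = Σ p_i²`, reported as `ln(1/λ)` so that larger
  values mean higher diversity for both indices.

The summations run over unique clonotypes — the only reading under
which `Σ p_i = 1` and the formulas are well defined. Natural logarithms
throughout. Down-sampling is repeated independently for the two
indices, and every draw uses a sub-seed derived deterministically from
(master seed, mouse id, receptor type, index name), so adding or
removing a mouse never perturbs the other mice's draws (provided the
down-sampling target is unchanged; the target is the cohort minimum, a
cohort property by construction).

## Power-law goodness of fit

Clone-size frequency distributions are fitted with the discrete
power law `P(k) ∝ k^(−α)`, `k ≥ xmin`
(`fit_discrete_powerlaw()`), using the standard discrete estimator:
`α` by zeta-function maximum likelihood (the normaliser is the Hurwitz
zeta `ζ(α, xmin)`, computed by direct summation plus an Euler–Maclaurin
tail, accurate to ~1e-10 over the fitting range), and `xmin` chosen to
minimise the Kolmogorov–Smirnov distance between the empirical tail and
the fitted law. The KS distance is evaluated on the discrete support,
comparing the empirical CDF at and just below each observed value.
Whether the original analysis estimated `xmin` or fixed it at 1 is not
recorded; we estimate it by default and expose `xmin` as an argument.

Goodness of fit (`gof_pvalue()`) is the semi-parametric bootstrap: each
replicate draws `n` observations that are, in expectation, a
`n_tail/n` mixture of fitted-law draws and resampled sub-`xmin` data,
then refits from scratch — including `xmin` re-selection — and records
its KS distance. The p-value is the proportion of replicate distances
at least as large as the observed one (500 replicates by default).
Repertoires are classified as `fits` (p > 0.1), `borderline`
(0.05 < p ≤ 0.1) or `does_not_fit` (p ≤ 0.05); the stated intervals are
open, so boundary values are assigned to the lower category — a
measure-zero choice, made explicit in `classify_fit()`.

## Sharing, public clonotypes, ordination

For one receptor type, all QC-passing mice are down-sampled to the
cohort minimum, reduced to unique clonotype key sets, and intersected
pairwise (`pairwise_shared()`); the diagonal holds each mouse's
down-sampled unique count. A clonotype is **public** when present in at
least `ceiling(0.75 · n)` of the `n` mice (`public_clonotypes()`).
`sharing_percent()` reports mean off-diagonal sharing as a percentage
of the mean down-sampled unique count — one concrete choice of
denominator, made explicit because percentage sharing is otherwise
ambiguous.

The dissimilarity used for ordination is `d = max(S) − S` off the
diagonal — the minimal construction giving the most similar pair a
dissimilarity of exactly 0. The alternative `1 − S/max(S)` is available
behind a flag. Dendrograms use average linkage (UPGMA) on this matrix;
no linkage was prescribed, and UPGMA is the conventional choice for
similarity-ordered heatmaps. PCoA (`repertoire_pcoa()`) is classical
Gower double-centering via `vegan::wcmdscale`; the weight vector of the
"weighted" PCoA is unspecified in the source analysis, so weights
default to uniform — which *is* classical PCoA — and can be supplied.
Negative eigenvalues (non-Euclidean `d`) are retained and reported
rather than corrected.

## Covariate models

Three model families, all fitted with `stats::glm`:

* **Richness**: Gamma family. The response is strictly positive and
  right-skewed; the link is log — the family's standard multiplicative
  choice (the source analysis names only the family). Design:
  `receptor_type + site + age + sex + age:sex`.
* **Shannon / log-inverse-Simpson**: Gaussian, identity link, same
  design.
* **Pairwise sharing**: Gaussian on shared counts with exactly the
  six stated terms: `receptor_type + same_sex + age_diff + age_sum +
  age_diff:receptor_type + age_sum:receptor_type`, optionally
  restricted to one trapping site to remove between-site structure.

Pair rows are not independent (each mouse occurs in many pairs). The
model is nevertheless fitted as stated; a permutation option
(`permutations > 0` shuffles ages across mice and rebuilds the pair
covariates) provides dependence-robust p-values and is off by default
to match the original analysis.

Post-hoc comparisons use estimated marginal means implemented in the
package (`emm_contrasts()`): predictions on a reference grid averaging
factor levels with equal weight and holding covariates at their means,
all pairwise contrasts, and Tukey studentised-range adjustment (the
multiplicity correction is unnamed in the source; Tukey is the
standard for all-pairs contrasts). Degrees of freedom are the residual
df for all families — exact for Gaussian, a conventional finite-sample
stand-in for the Gamma model's asymptotic z. `emm_slopes()` gives the
model-implied slope of a covariate within each factor level (the
analogue of marginal trends), used to ask how sharing changes with
pair age within each receptor type.

Single-level factors (e.g. one trapping site in a small cohort) are
dropped from the design with a warning; a zero-variance continuous
covariate or a constant response is an error; a rank-deficient design
errors naming the aliased terms.

# The synthetic cohort generator

`simulate_cohort()` exists so that the entire pipeline is testable with
no sequencing data. It emulates exactly the structure the analysis
assumes, and nothing more:

* **Clone sizes** are i.i.d. discrete power-law draws (exact inverse-CDF
  up to 1e6, rounded continuous approximation beyond). Default exponent
  2.5 per chain, `xmin = 1`: inside the 2–3 range reported for TCR
  clone-size distributions and heavy-tailed enough that a few large
  clones dominate, as in real repertoires.
* **Repertoire scale**: 1000 unique clonotypes per repertoire
  (~2000 molecules). Real repertoires are 10–100× larger; this scale
  keeps 50-replicate cohort experiments inside desk/CI time budgets,
  and every statistic used downstream is well defined at it.
* **Public pool**: each chain has a pool of candidate-public
  clonotypes; a mouse draws `public_fraction · n_unique` of its
  clonotypes from the pool with 1/rank (Zipf) weights, the rest
  private. Top-ranked pool keys therefore recur in nearly every mouse
  and form a detectable ≥75% public set, while lower ranks produce
  graded sharing. Default public fractions: alpha 0.06, beta 0.025,
  mirroring the observed ordering (alpha chains shared roughly twice
  as much as beta) without claiming the exact percentages.
* **Ages and metadata**: sex Bernoulli(1/2); ages uniform on 2–49
  weeks (the span observed in wild-caught animals); two sites at
  94%/6% weights (one dominant site, as in the field data).
* **Age/sex effect**: a designated 1% "chronic" subset of each
  repertoire's clonotypes — drawn from the private clones by default,
  since chronic responses are idiosyncratic — has its counts multiplied
  by `exp(β · age · s)`, with `β = age_effect_beta` per week and
  `s = sex_effect` (default 1.5) for females. Counts are then rounded
  *up*, so every clone keeps a count ≥ 1 and the unique-clonotype count
  is untouched by construction. This is the mechanism implied by
  "older mice have more highly abundant clones": diversity falls with
  age while the number of distinct clonotypes does not. The default
  `β = 0.02`/week (~2.6-fold expansion over the age range in males,
  ~4.3-fold in females) was chosen once as a realistic chronic-response
  magnitude; effect sizes are placeholders for experiments, not
  estimates of any wild population, and tests set them explicitly
  (the effect-recovery experiment uses `β = 0.05`, at which the
  Shannon decline is unambiguous at n = 60 mice).
* **Sequences**: CDR3 amino-acid sequences are uniform over the 20
  residues with lengths uniform on 9–17; a nucleotide CDR3 is generated
  by uniform reverse translation (stop-free by construction), so the
  written AIRR tables exercise the full ingest path
  (read → translate → filter → collapse).

**What it does not emulate:** V(D)J recombination statistics and
generation probabilities, thymic selection, sequence similarity
structure among CDR3s, chain pairing, or depth variation driven by
library preparation. A green test on synthetic cohorts establishes
that the *pipeline logic* recovers the structure it assumes — not that
wild-mouse data have that structure.

**One known coupling:** because the expansion multiplies counts, it
also inflates total repertoire size, so *measured* richness `U/N`
acquires a mild downward age trend in expansion cohorts even though
`U` is exactly constant. Real sequencing depth is set by the assay,
not by clonal expansion, so this is an artifact of the generator's
stated mechanism. The test suite therefore checks richness constancy
where it holds exactly (the unique count, in every simulated mouse)
and checks the richness *model's* nominal null behaviour (age/sex
intervals covering zero) on cohorts with the effect switched off.

# Numerical and reproducibility choices

* All randomness flows from one master seed through deterministic
  sub-seeds: a polynomial string hash of (seed, mouse id, receptor
  type, stage) modulo 2³¹−1, so stage order and cohort composition do
  not silently change draws, and every emitted table records the
  sub-seed it used.
* `zeta_hurwitz()` uses 64 direct terms plus a 4-term Euler–Maclaurin
  tail; the `xmin` search considers observed values with a tail of at
  least 8 observations (at most 100 candidates, quantile-thinned).
* The power-law sampler inverts the exact CDF up to 1e6 and uses the
  rounded continuous approximation beyond — only relevant for
  astronomically large draws.
* Down-sampling at `target = N` is the identity; `target` outside
  `[1, N]` errors.
* Boundary p-values 0.05 and 0.1 classify downward (`does_not_fit`,
  `borderline` respectively).
* Pipeline outputs are plain TSV/JSON written deterministically;
  re-running a configuration reproduces byte-identical files (tested
  via checksums).

# Limitations

* The Gamma-model EMM degrees of freedom are a finite-sample
  convention; at extreme dispersions the Tukey adjustment is
  approximate.
* The sharing model inherits the stated design's treatment of pairs as
  independent observations; use the permutation option when inference
  matters.
* The KS bootstrap refits `xmin` per replicate, which is the costly
  step; `gof_n_sim` trades accuracy of the p-value for time (the
  default 500 matches the original analysis).
* Public-clonotype detection is exact-match sharing; similar-but-not-
  identical CDR3s are out of scope.
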