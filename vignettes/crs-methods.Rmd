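---
title: "Methods: the circadian rhythm score and its statistical machinery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the circadian rhythm score and its statistical machinery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crscore)
```

# The score

Circadian transcription is organised in two gene classes: the
*core-clock* genes of the primary transcription–translation feedback
loop (CLOCK, BMAL1/ARNTL, the PERs and CRYs, their kinases and
stability factors) and the *clock-control* genes of the stabilising and
output loops (REV-ERBs, RORs, the D-box factors DBP/TEF/HLF, NFIL3). In
tumors these classes move in opposite directions — core-clock genes are
typically up-regulated while clock-control genes are down-regulated —
and the circadian rhythm score (CRS) quantifies that imbalance per
sample:

$$\mathrm{CRS}_j \;=\; ES_j(\text{clock-control}) \;-\; ES_j(\text{core-clock}),$$

where $ES_j(S)$ is the single-sample gene-set enrichment (ssGSEA) score
of set $S$ in sample $j$. Ranking genes within a sample by expression
($r_i$, highest expression $= N$) and walking positions $k = 1..N$ in
decreasing rank order,

$$P_{hit}(k) = \frac{\sum_{i \in S,\; pos(i) \le k} r_i^{\alpha}}
                   {\sum_{i \in S} r_i^{\alpha}}, \qquad
  P_{miss}(k) = \frac{|\{i \notin S: pos(i) \le k\}|}{N - |S|}, \qquad
  ES = \sum_k \big(P_{hit}(k) - P_{miss}(k)\big).$$

Because the statistic depends on expression only through within-sample
ranks it is invariant to any strictly monotone per-sample transform —
FPKM, TPM and log2 inputs give identical scores — which is what makes a
cross-platform score defensible.

## Parameters that matter

* **`alpha` (default 0.25).** The canonical ssGSEA rank-weight
  exponent. `alpha = 0` weights all in-set genes equally and admits
  clean closed-form checks (the package's hand-derived fixtures use
  it); 0.25 is the default for analysis.
* **`normalize` (default `FALSE`).** When on, every score of one call
  is divided by the joint max–min range of that call's full score
  matrix. Whether the original analyses normalised is unknowable from
  the outside; both paths are exposed and the flag travels with every
  output. The two sets of a pair are always scored in *one* call so a
  single constant applies and the subtraction stays on one scale.
* **`sign_convention` (default `control_minus_core`).** The literal
  definition is control minus core, yet the direction language used
  around knockout validations ("-CRS" axes) suggests the field
  sometimes plots the negation. We follow the literal definition,
  expose `core_minus_control`, and stamp the convention into the output
  attributes rather than guessing intent. Consequence to keep in mind:
  under the literal convention, tumors (core up, control down) score
  *lower* than normals.
* **Ties** get average (fractional) ranks; walk-order ties resolve by
  row order, so repeated runs are identical.
* **Set genes absent from a matrix** are dropped with a warning naming
  them — treating them as zero-expression would fabricate data.

# Survival machinery

All survival statistics are implemented from first principles (the
`survival` package serves only as an independent cross-check in the
test suite):

* **Kaplan–Meier**: product-limit $S(t) = \prod_{t_i \le t} (1 - d_i/n_i)$
  over distinct event times; censored-only times shrink the risk set
  without stepping $S$.
* **Log-rank**: $\chi^2 = (O_1 - E_1)^2 / V$ with hypergeometric
  variance summed over distinct event times.
* **Optimal cutpoint** (maximally selected rank statistic): every
  observed marker value whose `> cutpoint` split leaves at least
  `minprop` (default 0.1) of samples on each side is a candidate; the
  candidate maximising the absolute standardised log-rank statistic
  wins, ties toward the smaller value. The statistic at the selected
  cutpoint is *selection-biased*; downstream p-values carry an explicit
  `selection_biased` flag and no Lausen–Schumacher-style correction is
  applied (out of scope). Group naming follows the marker: values above
  the cutpoint are "high".
* **Univariate Cox**: Newton–Raphson on the Breslow partial likelihood
  from $\beta = 0$, convergence $|\Delta\beta| < 10^{-8}$ within 50
  iterations, SE from the observed information. Breslow rather than
  Efron ties because it is simpler and exactly testable; at the tie
  rates of the synthetic cohorts the difference is negligible and the
  choice is recorded in the result (`ties = "breslow"`). Monotone
  likelihoods (perfect separation, $|\beta|$ diverging) and
  non-convergence return flagged results, never silent estimates. The
  score test at $\beta = 0$ on a binary covariate reproduces the
  log-rank chi-square (without ties, exactly) — tested.

# Genomics conventions

* **DEG calls**: Welch's t on log2 values (linear units get a +1
  pseudocount first) with BH adjustment. A gene is `up` when fold
  change > 2 *and* p < 0.05; `down` symmetric. The gate uses raw p —
  the source convention defines DEGs on p — while q is always reported
  so users can re-gate on FDR. The moderated-t empirical-Bayes prior of
  limma-style pipelines is deliberately not reproduced; the test is a
  plain two-sample test and outputs say so.
* **CNV categories**: focal scores $> 0.3 \to +1$, $< -0.3 \to -1$,
  boundaries inclusive to 0. The published threshold sentence reads
  "less than 0.3" for deletions, which would leave the neutral class
  empty; it is read as $-0.3$.
* **Mutation frequency**: distinct mutated samples / cohort size. A
  sample hit more than once in a gene counts once and its class
  collapses to `multi_hit`; exact duplicate rows are idempotent. A
  display filter at overall proportion > 10% is exposed as an option,
  not a default.
* **CNV–expression coupling**: Spearman on raw (uncategorised) focal
  scores; constant-CNV genes are reported missing, not as $\rho = 0$.

# Immune and compound screens

Fraction matrices (e.g. 22-type leukocyte panels) are *inputs*;
deconvolution itself is external IP and out of scope. Group contrasts
use the Wilcoxon rank-sum test, CRS–feature screens use Spearman
(Pearson is exposed as an option for the checkpoint screen because the
source literature alternates; the default follows the methods usage).
The stromal/immune signature scores are unnormalised ssGSEA of two
signatures in one call with `estimate = stromal + immune` by
definition; the bundled signatures are synthetic placeholders and the
tumor-purity cosine transform (constants from the original ESTIMATE
publication) is opt-in because its constants are only meaningful on
ESTIMATE's own scale.

The compound screen follows the classic bidirectional KS connectivity
statistic: for tag positions $V(1..t)$ in a ranking of $n$ genes,
$a = \max_j (j/t - V(j)/n)$, $b = \max_j (V(j)/n - (j-1)/t)$,
$ks = a$ if $a > b$ else $-b$ (the tie $a = b$ resolves to $-b$, a
strict reading locked by tests), and $s = ks(up) - ks(down)$, zeroed
when both tails drift to the same end. Scores are scaled per cohort to
$[-100, 100]$ by dividing by the extremal positive/negative raw scores
— a deterministic alternative to the permutation-based tau
normalisation of the online service, chosen because thresholded
enrichment scores (not tau percentiles) are what the screen consumes.
Hits need $|score| > 90$ in at least 10 cancer types. Two discrete-KS
facts the tests document: the extreme construction gives exactly
$ks(up) = 1 - t/n$ and $ks(down) = -(1-(t-1)/n)$, and reversal of a
ranking negates $s$ only up to $O(1/t + 1/n)$ discretisation offsets —
swapping the up/down query lists, by contrast, negates exactly.

# The synthetic cohorts

The generator produces every input the pipeline consumes, with the
structure the analysis assumes; its defaults are the study conditions
and are not tuned per test:

* **Cohort**: 1000 background genes plus 13 clock-control and 35
  core-clock genes (the published class sizes); 100 tumor / 50 normal
  samples; log2 expression $\mathcal{N}(\mu_g, 0.5)$ with gene means
  drawn once; tumor shifts $+1$ (core) and $-1$ (control) log2 — the
  qualitative direction reported pan-cancer, at an effect size a
  two-fold change convention makes natural. The *true score* is the
  noise-free control-minus-core mean, standardised over tumors.
* **Survival**: exponential proportional hazards,
  $\lambda_i = \lambda_0 e^{\beta z_i}$ with $\lambda_0 = 0.002$/day
  (median OS around a year at the null) and $\beta = 0.8$ per SD of
  true score; independent uniform censoring $C \sim U(0, \tau)$ with
  $\tau$ solved numerically so the expected censored fraction is the
  requested 30%. The minimal PH-consistent design: Cox and log-rank
  recovery become parameter-recovery tests with known truth.
* **Knockouts** multiply target-gene expression on the *linear* scale
  (a factor of 0 must be representable; log2 of 0 is not finite), so
  knockout matrices are linear-unit.
* **Time courses**: circadian genes oscillate
  $A \sin(2\pi t/\text{period} + \phi_g)$; clock-control phases jitter
  around 0 and core-clock phases around $\pi$ — the antiphase relation
  of the stabilising loop to the CLOCK:BMAL1 limb — so the CRS itself
  oscillates and a deregulation treatment (smaller $A$) flattens it.
* **Genomics**: Bernoulli mutations at 0.0101 per gene × sample, which
  across a 48-gene panel yields ≈38.6% of samples carrying at least one
  mutation — the burden reported for pan-cancer circadian panels.
  CNV = 0-centred noise (sd 0.1) mixed with signed events beyond
  $|0.3|$; expression shifts by `coupling` × category. Note that
  Spearman coupling saturates with the event rate: samples without an
  event contribute pure noise ranks, so at a 20% event rate $\rho$
  cannot exceed ≈0.5 no matter the coupling strength.
* **Fractions**: Dirichlet columns with concentrations
  $\alpha_{0c} e^{link_c \cdot score_s}$ — compositional by
  construction, log-linearly linked where requested.
* **Compound libraries**: decoys are uniform random permutations;
  planted mimics put the query's up-tail on top and down-tail at the
  bottom (reverts mirrored).

Randomness uses per-stage derived seeds from one master seed, so adding
a stage never perturbs another stage's draws and identical parameters
give byte-identical outputs.

**What the generator does not emulate** — and therefore what green
tests do *not* establish about real data: negative-binomial count
noise, batch and platform effects, tumor purity confounding, correlated
gene–gene structure beyond the two class shifts, informative censoring,
and realistic compound-signature correlation structure. The generator
validates the *machinery* (estimators recover planted truth; screens
recover planted signal with controlled false positives), not the
biological claims.

# Problem sizes and reproducibility

The packaged checks run at deliberately modest sizes chosen to make the
Monte-Carlo properties sharp while keeping a full run interactive:
ssGSEA oracle equivalence on 200 random instances ($N \le 100$),
cutpoint-vs-exhaustive-scan agreement on 100 instances ($n \le 40$),
Cox recovery over 100 replicates of 300-patient cohorts, null coverage
over 200 replicates, survival separation over 50 default cohorts, and a
compound screen of 1000 decoys + 2 planted compounds across 18
synthetic cancers. `scripts/acceptance.R --seed <s> --out <json>`
recomputes all of them from scratch against the installed package.

# Known limitations

Single-threaded by design (determinism over speed); no Efron ties, no
multivariable Cox, no cutpoint-selection p-value correction, no
deconvolution, no tau normalisation, no cosinor rhythm regression. The
bundled circadian and checkpoint gene lists are curated synthetic
reconstructions matching the published class sizes (13 + 35 = 48, 60) —
users reproducing a specific study should supply that study's GMTs.
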