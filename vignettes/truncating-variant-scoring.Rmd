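---
title: "Scoring truncating variants: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring truncating variants: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(truncpath)
```

## The problem

Frameshift and nonsense mutations truncate a protein at a position $k$,
destroying everything C-terminal of it. Most such variants segregating in a
genome are neutral; a few disable an essential or disease-relevant function.
`truncpath` scores a truncating variant's probability of disease association
from features of the protein and of the truncation point, and calibrates
those scores into p-values against a neutral null. Both variant classes are
treated identically throughout: what matters to the model is *where* the
protein is cut, not the mutational mechanism that cut it.

## Features

For a variant at position $k$ of a protein with $N_r$ residues the default
(46-slot) schema concatenates:

* **Wild-type residue** — one-hot over the 20 amino acids (20 slots).
* **Contact composition** — the amino-acid composition $q(a) = N(a) / \sum_b
  N(b)$ of all residues whose C$_\alpha$ lies within 12 Å of position $k$'s
  C$_\alpha$ in the structural model (20 slots). The position itself is
  excluded; sequence neighbours are included — they are physically inside
  the radius and their types carry signal. A contact-free position (only
  possible for degenerate models) yields an all-zero block with a warning
  rather than a failure; the trees handle a zero block.
* **Sequence entropy** — $S_r(k) = S(k) - \langle S \rangle$, the Shannon
  entropy $S = -\sum_l f_l \ln f_l$ of the position's amino-acid frequency
  profile, centred by the protein-wide mean (1 slot). Conserved positions
  score negative.
* **Fraction of structure lost** — $(N_r - k) / N_r$ (1 slot).
* **Essentiality** of the gene, 0/1 (1 slot).
* **Missense pathogenicity of the lost part** — for each position $j > k$,
  the fraction of its 19 possible substitutions whose precomputed missense
  score reaches 0.45, averaged over the lost positions (1 slot). The
  truncated position itself is counted as still present: a nonsense codon
  replaces residue $k$, and it is the downstream residues that are lost.
  Truncation at $k = N_r$ loses nothing and scores 0.
* **Disease involvement** — a single 0/1/2 integer summing the two
  annotation sources. The additive encoding (rather than two binaries)
  keeps the count of gene/variant-level features at five, so the candidate
  and final schemas have 66 and 46 slots.
* **Protein-protein interaction count** — used raw; tree splits are
  invariant to monotone transforms, so a log transform would change
  nothing.

The 66-slot candidate schema additionally carries the **domain
composition** (20 slots): the amino-acid composition of the annotated
domain interval containing $k$, falling back to the whole-protein
composition when no interval covers $k$. This group is the one eliminated
by the feature-reduction procedure, which is why the default schema omits
it.

Missing inputs are handled by severity: an absent annotation row degrades
to zeros with a warning, while an absent structure, profile or missense
matrix makes the variant's features uncomputable and is reported as a
per-variant failure — those features cannot be imputed honestly.

## The scorer

The scorer is a from-scratch gradient-boosted regression-tree ensemble,

$$ f(x) = \sum_{m=1}^{N_\mathrm{tree}} \varepsilon\, T_m(x), $$

fitted by least squares on 0/1 targets (1 = disease-associated) with
$f_0 = 0$: each round fits a depth-limited regression tree to the current
residuals $y - f$ and adds it with shrinkage $\varepsilon$. Reference
hyperparameters are $\varepsilon = 0.005$, $N_\mathrm{tree} = 2000$ and
depth 8; they are deliberately plain and were never tuned. Trees use exact
greedy search: every midpoint between consecutive distinct feature values
is scored by its summed-squared-error reduction, leaves carry mean
residuals, and no split is made unless it genuinely reduces the SSE or if a
child would fall under `min_leaf` samples.

Two numerical choices make fits bit-reproducible. Gains below a relative
$10^{-12}$ of the node's $\sum y^2$ are treated as zero (otherwise floating
noise manufactures splits on constant residuals), and gains equal to a
relative $10^{-9}$ are treated as tied, with ties resolved toward the
lowest feature index, then the lowest threshold. The tie tolerance matters
because two different features can induce the *same* sample partition —
mathematically the same gain — while cumulative sums taken in different
sort orders differ in the last bits.

Because pathogenic records outnumber neutral ones roughly two to one in the
kind of training cohort this model targets, training uses a **dual balanced
pair**: the pathogenic set is split at random into halves
($\lceil n/2 \rceil$ and $\lfloor n/2 \rfloor$), each half is trained with
*all* neutral variants, and a variant's score is the average of the two
models, clipped to $[0, 1]$ for reporting (the ensemble sum itself is not
intrinsically bounded; the clip is a reporting convention, applied nowhere
else). Calls are inclusive: score $\ge$ cutoff (default 0.5) is
disease-associated.

```{r quick-model}
set.seed(1)
X <- matrix(rnorm(300 * 3), 300)
colnames(X) <- c("a", "b", "c")
y <- as.integer(X[, 1] + 0.5 * X[, 2] > 0)
fit <- truncpath(X, y, ntree = 100, shrinkage = 0.05, seed = 1)
summary(fit)
```

## Evaluation without homology leakage

Proteins sharing detectable homology must never straddle a
training/evaluation split, or the model is graded on memorised relatives.
Sequences are clustered by single-linkage at 35% pairwise identity
(Needleman–Wunsch global alignment, match +1 / mismatch 0 / gap open and
extension −1; identity = identical aligned positions divided by the
*shorter* length — the conservative denominator for leakage control) and
whole clusters are dealt to folds, shuffled by seed and round-robin by
descending size. Cross-validation trains a balanced pair per fold and pools
all held-out scores; setting $k$ to the number of clusters gives
leave-one-cluster-out (LOOCV).

Metrics are the standard confusion-matrix set — MCC, sensitivity,
specificity, F-score, false positive rate, false discovery rate — with
degenerate denominators defined explicitly (MCC 0 when a factor is zero,
F-score 0 when TP = 0, FDR 0 when nothing is called).

**Feature reduction** clusters the training proteins, merges the smallest
clusters until 10 remain, and runs LOOCV once per feature group: remove the
group, re-run, and discard it iff the MCC at cutoff 0.5 *strictly* improves
over the all-groups baseline. The pass is single — one elimination round
against a fixed baseline, not iterative re-baselining — mirroring a
procedure whose outcome was the removal of exactly one group (domain
composition).

## Score significance and exome-level FDR

Neutral scores pile up near 0 with a long right tail; among two-parameter
location-scale laws the extreme-value (Gumbel) family fits that shape, and
its survival function supplies the p-value of a score $x$:

$$ p(x) = 1 - \exp\!\left[-\exp\!\left(\frac{\mu - x}{\sigma}\right)\right]. $$

This reading of the formula is pinned down by consistency: with the
reference parameters $(\mu, \sigma) = (0.0706, 0.1331)$ it returns
$p(0.5) = 0.039$, and with the comparator's $(0.1371, 0.1583)$ it returns
$0.096$ — both reproduced to three decimals in the test suite.

```{r pvals}
round(evd_pvalue(0.5, evd_params(0.0706, 0.1331)), 3)
round(evd_pvalue(0.5, evd_params(0.1371, 0.1583)), 3)
```

Fitting minimises the RMSD between the Gumbel density and a
density-normalised histogram of neutral scores (bin width 0.02 on a
0-anchored grid spanning the data; the width is exposed as an argument),
via Nelder–Mead over $(\mu, \log\sigma)$ from the moment start
$\hat\mu = \bar x - \gamma\hat\sigma$, $\hat\sigma = \sqrt{6\,s^2}/\pi$
($\gamma$ the Euler–Mascheroni constant), relative tolerance $10^{-8}$.
Density — not counts — is matched, consistent with an area-normalised
score histogram. Note the p-value comes from the fitted null, not from an
empirical false-positive rate; the two can disagree by a factor of two on
small test sets.

For a whole-exome screen with unknown ground truth, the number of false
calls at cutoff $c$ is approximated by $p(c) \cdot N_\mathrm{total}$, so

$$ \widehat{\mathrm{FDR}}(c) = \frac{p(c)\, N_\mathrm{total}}{N_\mathrm{pred}(c)} \wedge 1 .$$

```{r fdr}
p <- evd_pvalue(0.5, evd_params(0.0706, 0.1331))
round(estimate_exome_fdr(p, n_total = 274, n_pred = 40), 3)
```

The curve of $\widehat{\mathrm{FDR}}$ against the cutoff is typically
non-monotone: past an interior minimum, $N_\mathrm{pred}$ falls faster than
the p-value does and the estimate climbs again.

## The synthetic cohort generator

Every procedure above is exercised end-to-end on generated cohorts, because
the real training resources (variant databases, predicted structures,
alignment profiles, annotation databases) cannot ship with a package.
`generate_cohort()` emulates the *statistical structure* the classifier
assumes, not the biology:

* sequences uniform over the 20 residues; C$_\alpha$ traces from a
  self-avoiding random walk with 3.8 Å steps and a 4 Å exclusion radius —
  enough to give every position a non-degenerate 12 Å neighbourhood,
  without pretending to be a fold;
* per-position conservation weights $w \sim \mathrm{Beta}(0.8, 0.8)$;
  profiles mix a point mass on the wild type (weight $w$) with a random
  background, so conserved positions have low entropy; missense score
  matrices drawn with per-position means increasing in $w$, so conserved
  positions also look missense-pathogenic;
* annotations at realistic rates (30% essential, 40% / 20% on the two
  disease sources, geometric PPI counts with mean 20), two domains for
  half the proteins;
* labels drawn from a logistic model over the planted directions —
  conservation ($\beta = 8$), fraction lost ($\beta = 12$), annotation
  score ($\beta = 6$), all mean-centred on $[0,1]$-range inputs — with the
  intercept solved so the expected pathogenic fraction is 2/3. The strong
  defaults make labels nearly deterministic given the features (a planted
  signal a recovery test can actually recover), and the 2:1 class ratio is
  the regime the dual balanced-half protocol is designed for. Setting all
  three effects to zero yields an exact null in which labels are
  independent of every feature.

What passing tests on these cohorts shows is that the machinery — feature
extraction, training, homology-clustered evaluation, reduction,
calibration — recovers structure that is genuinely present. What it cannot
show is performance on real proteomes: real conservation is phylogenetic,
real structures are folds, real annotation errors are systematic, and real
effect sizes are far smaller and heterogeneous.

## Desk-scale configuration

The reference operating point ($N_\mathrm{tree} = 2000$,
$\varepsilon = 0.005$, depth 8, `min_leaf` 1) is sized for cohorts of
$\sim 10^4$ variants. The package's own validation runs use cohorts of 400
variants (40 proteins) for cross-validation and 900 variants for the
reduction experiment, and scale the learner accordingly while preserving
its geometry:

* $N_\mathrm{tree} = 200$ with $\varepsilon = 0.05$, keeping the
  cumulative shrinkage budget $\varepsilon N_\mathrm{tree} = 10$ — and
  hence the score ceiling $1 - (1 - \varepsilon)^{N_\mathrm{tree}}$ —
  equal to the reference's. At the reference $\varepsilon$ with only 200
  trees the ceiling would be 0.63 and the fixed 0.5 cutoff would sit in
  the score distribution's shoulder.
* `min_leaf` 10 for cross-validation: a depth-8 tree has up to 256 leaves
  and would memorise a 400-row training table; at the reference scale
  memorisation is impossible and `min_leaf` 1 is harmless.

These choices live in the tests and examples, not in the defaults; the
exported defaults remain the reference values.

## Known limitations

* One full-length C$_\alpha$ model per protein is assumed; multi-domain
  proteins with only per-domain models, multiple isoforms, and
  genomic-to-protein coordinate mapping are out of scope.
* Contact counting is unweighted (no distance weighting, no occupancy);
  profiles are consumed as given (rows off by more than $10^{-3}$ from
  unit mass are rejected, smaller deviations renormalised).
* The identity computation is pluggable in principle but fixed in
  implementation; BLAST-style identities would shift cluster boundaries
  slightly.
* The reduction procedure's strict-improvement rule compares two
  cross-validated estimates; on small cohorts its decisions on genuinely
  uninformative groups carry the CV estimate's sampling noise.
* The extreme-value null is the only family implemented — the selection
  among candidate families happened upstream of this package and is not
  re-run here.
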