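---
title: "Moment-based gene set tests: model, approximations, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moment-based gene set tests: model, approximations, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(mbgst)
```

## The testing problem

Given a genes-by-samples expression matrix $X$ and a phenotype $Y$ (a
treatment label, a disease indicator, or a continuous trait), a gene set
test asks whether a prespecified set $G$ of genes is jointly associated
with $Y$. `mbgst` tests the *self-contained* null hypothesis: $Y$ is
independent of $(X_g; g \in G)$. The natural nonparametric reference for
this null is the permutation distribution obtained by shuffling the
phenotype labels, but permutation p-values have three costs: computing
time, Monte Carlo randomness, and granularity — with $M$ sampled
permutations no p-value below $1/(M+1)$ can be reported, and with tied
phenotypes no p-value below the data granularity
$\varepsilon = \prod_k n_k!/n!$ exists at all. In modern collections with
thousands of sets and multiple-testing adjustment, the interesting
p-values are exactly the tiny ones that permutation cannot resolve.

`mbgst` instead computes *exact* low-order moments of the permutation
distribution in closed form and matches a continuous reference
distribution to them. The p-values are deterministic, continuous, and
cost roughly as much as a handful of permutations per set.

## Statistics and their exact permutation moments

All data are centered; by default each gene row is also scaled to unit
mean square ($\sum_i X_{gi}^2 = n$), so the per-gene coefficient
$\hat\beta_g = \frac1n \sum_i X_{gi} Y_i$ is, up to the scale of $Y$, the
sample correlation. Scaling of $Y$ is never needed: under the default
gene scaling it cancels from every p-value. Two set-level statistics are
offered:

* linear, $\widehat T_{G,w} = \sum_{g\in G} w_g \hat\beta_g$ — sensitive
  when the associated genes move coherently (weights can encode expected
  signs or importance);
* quadratic, $\widehat C_{G,w} = \sum_{g\in G} w_g \hat\beta_g^2$ —
  sensitive to association of mixed sign; weights must be non-negative so
  that evidence cannot cancel.

Under uniform random permutation of $Y$ (data held fixed), with
$\mu_2, \mu_4$ the second and fourth moments of $Y$ and
$\bar X_{gh} = \frac1n\sum_i X_{gi}X_{hi}$:

* $\mathrm{E}(\widetilde T) = 0$ and
  $\mathrm{cov}(\tilde\beta_g, \tilde\beta_h) = \mu_2\bar X_{gh}/(n-1)$,
  so $\mathrm{var}(\widetilde T) = \mu_2 \bar X_{GG}/(n-1)$ for the
  pseudo-gene profile $X_{Gi} = \sum_g w_g X_{gi}$ (an $O(n|G|)$
  computation);
* fourth moments follow from a five-case combinatorial expansion (four of
  a kind, three of a kind, two pair, one pair, no repeats) that reduces to
  a $2\times2$ matrix `moment_matrices(n)$ATB` acting on
  $(\mu_2^2, \mu_4)$ and two cheap cross-moments of $X$;
* $\mathrm{E}(\widetilde C)$ and $\mathrm{var}(\widetilde C)$ aggregate
  the pairwise second and fourth moments through three sums
  $S_1 = (\sum_g \bar X_{gg})^2$,
  $S_2 = \frac1n\sum_i (\sum_g X_{gi}^2)^2$, and
  $S_3 = \sum_{g,h} \bar X_{gh}^2$; the first two are $O(np)$, while
  $S_3$ is computed through the $p\times p$ Gram matrix when $p \le n$
  and through the $n \times n$ Gram matrix otherwise, so the cost is
  $O(np\min(n,p))$.

In assembling $\mathrm{var}(\widetilde C)$, the sum $S_1 + 2S_3$ enters
with normalization $1/n^2$ (it aggregates the per-pair terms
$\bar X^*_{gghh}/n^2$) and $S_2$ with $1/n^3$. This normalization is
fixed by the exhaustive-enumeration oracle: for every $n \le 8$ fixture
the assembled variance agrees with brute force over all $n!$ permutations
to $10^{-10}$, which is also this package's standing regression test.

Every closed form above is validated against `exhaustive_moments()`,
which recomputes statistics under all $n!$ permutations. Enumeration is
capped at $n \le 8$ (40,320 permutations) — large enough to exercise all
five index patterns, small enough to run in seconds.

## Reference distributions

**Gaussian (linear).** $N(0, \mathrm{var}\,\widetilde T)$; the left-tail
p-value is $\Phi(\widehat T/\mathrm{sd})$, with right and central
versions defined in the usual way and the two-sided p capped at 1.

**Scaled beta (linear, default).** $\widetilde T$ is bounded; its exact
attainable range $[A, B]$ follows from the rearrangement inequality by
co-sorting $X_G$ against $Y$ ($B$: both ascending; $A$: opposed). A
scaled beta $A + (B-A)\,\mathrm{beta}(\alpha,\beta)$ matches min, max,
mean 0 and the exact variance:
$$\alpha = \frac{A}{B-A}\Big(\frac{AB}{\sigma^2}+1\Big), \qquad
  \beta = \frac{-B}{B-A}\Big(\frac{AB}{\sigma^2}+1\Big).$$
Both shapes are positive because $AB < 0$ and, by the Bhatia–Davis
inequality, $\sigma^2 \le -AB$ with equality only when $\widetilde T$
takes one or two values (then `beta_fit()` refuses with an explanatory
error). Anchoring the support at the exact range guarantees the observed
statistic never falls outside the reference's support — a failure mode of
four-moment Pearson-family fits, which is why that family is not offered.

A $t$ reference is deliberately not offered either: the exact fourth
moment shows the permutation distribution of $\widetilde T$ usually has
*negative* excess kurtosis (`kurtosis_excess()`), and $t$ distributions
can only add tail weight to the normal.

**Scaled chi-squared (quadratic).** $\sigma^2\chi^2_{(\nu)}$ with
$\nu = 2\,\mathrm{E}(\widetilde C)^2/\mathrm{var}(\widetilde C)$ and
$\sigma^2 = \mathrm{E}(\widetilde C)/\nu$ (a gamma distribution; $\nu$
need not be an integer). The reported p-value is the upper tail at
$\widehat C$.

**Granularity adjustment.** The beta reference can return exactly 0 or 1
at the support endpoints. With
$\tilde p_L = \varepsilon + (1 - 2\varepsilon)p_L$, where $\varepsilon$
is the data granularity of the observed phenotype, the smallest
reportable value becomes $\varepsilon$ — precisely what an exhaustive
permutation test could claim. The adjustment is monotone, so
Benjamini–Hochberg ordering downstream is unaffected; it is applied by
default only to the bounded beta reference (the Gaussian and chi-squared
references are unbounded and never return 0), and `epsilon_adjust = FALSE`
switches it off. Adjusted p-values are the ones passed to BH: a policy
choice, made once, reported in the `epsilon_used` column.

**Degenerate sets** (e.g. an all-zero pseudo-gene, or a constant
quadratic statistic) report $p = 1$ with a `degenerate` flag rather than
failing a batch run.

## Experimental-design utilities

`granularity()` and `design_summary()` give the exact number of distinct
phenotype arrangements and $\varepsilon$; counts are exact up to
$2^{53}$ and tracked in log space beyond (no overflow for any $n$). A
warning is issued when fewer than 100,000 distinct permutations exist,
where a permutation test would be visibly coarse. Tie groups are defined
by exact floating-point equality; a continuous phenotype is all-distinct.

`min_k_for_power()` answers "how many permutations would I have needed?":
running $M = k/\varepsilon - 1$ permutations, one can claim
$p \le \varepsilon$ when at most $k-1$ draws are as extreme as the
observed value, with power $\Pr(\mathrm{Bin}(M, p) \le k-1)$ at true
p-value $p$. By exact binomial summation (with a Poisson-limit
cross-check), 80% power requires $k = 19$ at $p = 0.8\varepsilon$ and
$k = 3$ at $p = 0.5\varepsilon$, essentially independently of
$\varepsilon$ — e.g. nineteen million permutations per set for
$\varepsilon = 10^{-6}$, which is the cost the moment method avoids.

```{r design}
granularity(c(5, 5))
min_k_for_power(1e-6, true_p_fraction = 0.8, target_power = 0.8)
```

## Resampling oracles

The package carries its own ground-truth machinery, used by the test
suite and available for spot checks:

* `perm_draws()` / `perm_pvalues()` — Monte Carlo permutation with the
  +1 convention (the observed statistic counts as one permutation, making
  the null p-value distribution uniform on $\{1/(M{+}1),\dots,1\}$);
  sampling is with replacement (independent uniform permutations);
* `exhaustive_moments()` — full enumeration for $n \le 8$;
* `contrast_matrix()` / `rotation_beta_draws()` — mean-preserving
  rotation sampling $\widetilde Y = W Q^* W^\top Y$ with $Q^*$ sampled
  Haar-uniformly (QR of a Gaussian matrix with the signs of $R$'s
  diagonal folded into $Q$). Rotation shares
  $\mathrm{E}(\widetilde T)$, $\mathrm{var}(\widetilde T)$ and
  $\mathrm{E}(\widetilde C)$ with permutation for every valid contrast
  matrix, and the suite verifies this by Monte Carlo against the closed
  forms, along with the exact fourth moments of Haar rotation matrices.

One subtlety discovered while validating: under Haar-uniform $Q^*$ the
rotated phenotype is uniform on the centered sphere *whatever* contrast
matrix $W$ is used ($W$ is an isometry from $\mathbb{R}^{n-1}$ onto the
centered hyperplane), so the whole rotation distribution — including
$\mathrm{var}(\widetilde C)$ — is invariant to the choice of $W$, even
though individual terms of its expansion (such as
$\sum_i (W^\top Y)_i^4$) do depend on $W$ and cancellation is not obvious
term by term. What rotation does *not* share with permutation is
$\mathrm{var}(\widetilde C)$ itself; the suite demonstrates both facts by
Monte Carlo. Rotation here is a verification oracle only; p-value
production from rotations (as in full rotation-test frameworks) is out of
scope.

## The synthetic-data generator

`synth_dataset()` emulates the inputs the method expects: Gaussian
expression with optional within-block gene–gene correlation
($X_g = \sqrt\rho\, Z_{b(g)} + \sqrt{1-\rho}\,\epsilon_g$), a continuous
(standard normal) or binary phenotype, random gene sets, and an optional
phenotype-linked mean shift of size $\delta$ added to the genes of
designated signal sets. Defaults ($n = 20$ samples, 200 genes, sets of
5–20 genes, $\delta = 0$) describe a small null study of the size where
moment approximations are most stressed. Everything derives from one
seed.

What it does not emulate: heavy-tailed or count-valued expression,
outliers, batch effects, and realistic pathway overlap structure. Null
calibration and power results on these fixtures therefore demonstrate
correctness of the mathematics under the stated sampling model, not
robustness to real microarray or RNA-seq artifacts; the rank transform
(`rank = TRUE`) is the package's concession to heavy tails.

## Worked example

```{r example}
sim <- synth_dataset(n_samples = 20, n_genes = 100, n_sets = 10,
                     n_signal_sets = 2, effect_size = 0.5, seed = 42)
fit <- moment_gsea(sim$x, sim$y, sim$sets, stat = "quadratic")
fit
sim$signal_sets
```

The two designed signal sets rank first with continuous p-values far
below the $\sim 4\times10^{-7}$ floor that even a million-permutation run
could report.

## Validation, measured accuracy, and limitations

The test suite recomputes every closed-form moment against exhaustive
enumeration (all fixtures with $n = 4,\dots,7$ and 3–5 genes agree to
$10^{-10}$), checks rotation moments against their closed forms at
$n = 8$ with 200,000 draws (4 Monte Carlo standard errors), verifies null
calibration of the two-sided normal and chi-squared p-values at
$\alpha = 0.05$ over 2,000 replicates, and compares moment p-values with
$M = 49{,}999$-permutation p-values across 200 null sets at $n = 20$.

In that comparison, rank agreement is excellent for all three references
(Spearman correlation above 0.97). Pointwise agreement is tighter for the
four-feature beta fit than for the two-moment fits: at $n = 20$ the
normal reference (which ignores the negative excess kurtosis) and the
chi-squared reference on small sets (which ignores the third-moment
mismatch) can deviate from the permutation p-value by slightly more than
0.01 in the mid-range, while the beta reference stays within the Monte
Carlo noise of the permutation reference itself. Deviations of this kind
shrink with $n$; users with very small samples who need pointwise (rather
than rank) agreement with permutation p-values should prefer the beta
reference for linear statistics and can spot-check any set with
`plot()`'s histogram-versus-fit diagnostic or a modest `perm_draws()`
run.

Other numerical choices: tiny negative assembled variances (relative
magnitude below $10^{-10}$, floating-point cancellation) are clipped to
zero, anything larger raises an error; weight defaults are $w_g = 1$
(for the linear statistic any common rescaling of weights cancels from
the p-value, so 1 vs $1/|G|$ is immaterial); sets with fewer than two
matched genes are dropped with a warning; missing values are rejected
rather than imputed, since the moment formulas assume complete data.
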