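---
title: "Modelling cis and trans QTL distance regimes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cis and trans QTL distance regimes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cistrans)
```

## The problem

A molecular-QTL study reports, for each measured trait (a protein,
transcript or metabolite), the lead variant associated with it and the
trait's cognate gene. Variants acting *in cis* influence the cognate gene
directly and therefore sit close to its transcription start site (TSS);
variants acting *in trans* work through an intermediate gene, so their
position relative to the cognate gene carries no information beyond the
physical constraint of sharing a chromosome. Studies conventionally split
the two classes at an arbitrary window (250 kb to 1 Mb). `cistrans`
derives the boundary from the data instead, by giving each regime an
explicit probability model and asking where one takes over from the other.

## The two component models

**Trans: random intrachromosomal pairs.** If a variant tells us nothing
about where its cognate gene is, the variant-TSS distance behaves like the
distance between two positions drawn uniformly at random on the same
chromosome. On a chromosome of length $N$ there are $2(N-d)$ ordered
position pairs at distance $d$ (for $0 < d < N$) out of $N^2$, and a random
intrachromosomal pair lands on chromosome $i$ with probability
$N_i^2 / \sum_j N_j^2$, so

$$f_T(d) \;=\; \frac{\sum_i 2\,(N_i - d)\,[d < N_i]}{\sum_i N_i^2}.$$

This model has **no free parameters** once the chromosome lengths are
fixed. The package embeds GRCh38 lengths for the 22 autosomes plus X
(23 chromosomes) as the default; any recent build changes the results by
far less than the fit uncertainties, and a `chromosome_set` or a
two-column TSV / `.fai` file can override it. The density as printed sums
(discretely) to $\sum_i N_i(N_i-1)/\sum_i N_i^2$, a deficit of order
$1/N_i$; we renormalize so it is an exact probability distribution, which
keeps mixture weights interpretable. The distribution function is
implemented with the exact discrete pair count
$\sum_i (N_i-k)(N_i-k-1) / \sum_i N_i(N_i-1)$, $k=\lfloor q \rfloor$, so
that it agrees with brute-force pair enumeration to machine precision on
toy genomes; at genome scale the discrete/continuous distinction is
below $10^{-8}$. Distances of exactly zero (variant on the TSS) are
excluded by construction. A consequence worth stating numerically:

```{r trans-tail}
ptrans(1e6, trans_model(), lower.tail = FALSE)
```

about 99% of random same-chromosome pairs are more than 1 Mb apart, which
is what makes the two regimes separable at all.

**Cis: a Weibull on log10 distance.** The short-range peak is modelled by
a two-parameter Weibull density on $\ell = \log_{10}(d)$:

$$f_W(\ell) \;=\; \frac{\kappa}{\lambda}
  \left(\frac{\ell}{\lambda}\right)^{\kappa-1}
  e^{-(\ell/\lambda)^\kappa},$$

with shape $\kappa$ (dimensionless) and scale $\lambda$ (log10-bp). All
logarithms in the package are base 10. The support is $\ell \ge 0$
(distances of at least 1 bp): observed minimum distances in real QTL
tables are single base pairs, and a 1 bp distance maps to $\ell = 0$
where the density vanishes for $\kappa > 1$ — harmless, because the
likelihood is only ever evaluated through binned counts and CDFs, never
pointwise at single records. A location-shifted (three-parameter) Weibull
is deliberately out of scope. A Gaussian in $\ell$ (mean, sd) is carried
along as the alternative cis family purely for model comparison.

## Binning

Distances are binned at 0.25 log10 units — four bins per order of
magnitude. Bin $k$ covers $[0.25k,\, 0.25(k+1))$ with integer $k \ge 0$:
edges lie on multiples of the width, intervals are half-open so a distance
that is an exact power of $10^{0.25}$ is counted exactly once, and a bin
is labelled by its **left edge** (so $10^4$ bp starts, and labels, its own
bin). A bin-centre labelling is available behind a flag, but the left-edge
convention is the one consistent with the tallest published pQTL bin being
labelled 4.0. Distances below 1 bp are rejected with a warning and
counted. Model-expected counts per bin are exact CDF differences,
$n\,[w\,\Delta F_W + (1-w)\,\Delta F_T]$, **not** midpoint densities: the
midpoint rule errs by several percent on the steep right flank of the
Weibull, which would bias the fit exactly where the two components meet.

## The two-stage fit

The combined model has three parameters: $\kappa$, $\lambda$ and the cis
(Weibull) fraction $w$.

1. **Initial cis-only fit.** The trough of the histogram between the two
   regime peaks is located (`suggest_cutoff()`: the minimum-count bin
   between the two dominant local maxima, ties broken toward larger
   $\ell$; since sampling noise can create several local maxima inside one
   peak, the second peak must be at least one order of magnitude — 4
   bins — away from the first). A Weibull with $w$ pinned at 1 is fit to
   the bins entirely below the cutoff, and the initial fraction is the
   share of records below the cutoff.
2. **Combined fit.** All three parameters are freed and fit to *all*
   bins, starting from the stage-1 values.

Both stages minimize weighted least squares on the binned counts with
weights $1/\max(c_k, 1)$ (approximate Poisson weighting; ordinary least
squares behind `weighted = FALSE`), using bounded Levenberg-Marquardt
(`minpack.lm`), with box constraints $\kappa \in (0.1, 50)$,
$\lambda \in (0.5, 10)$, $w \in [0, 1]$. Zero-count bins inside the
occupied span stay in the objective — they are observations of absence.
Defining stage 1 as "the stage-2 objective restricted to sub-cutoff bins
with $w$ fixed at 1" makes the two stages exactly consistent: rerunning
the combined fit on only the sub-cutoff bins with the fraction fixed
reproduces the initial estimates to numerical precision. A fraction that
converges onto a bound is reported with a warning rather than silently
accepted. Standard errors come from the Jacobian-based covariance at the
optimum scaled by the residual variance — the standard nonlinear
curve-fit convention — and no standard error is attached to a fraction
held fixed at 1. The whole estimation is deterministic: there is no
randomness anywhere in the fit.

For studies that only test variants inside a fixed window around the gene
(a common eQTL design), `truncate_at` fits the cis component alone below
the window edge and reports the fraction as 1 with no standard error.

**Goodness of fit.** A one-sample Kolmogorov–Smirnov test compares the
*unbinned* log10 distances with the fitted mixture CDF
$w F_W + (1-w) F_T$, and the same protocol is run with the Gaussian cis
family so both p-values are always available. Because the parameters are
estimated from the same data, these p-values are anti-conservative; they
are reported as published-style model-comparison numbers, not calibrated
significance, and no correction is applied.

## The cross-over distance

The empirical cis/trans boundary is the root of

$$w\, f_W(\ell) \;=\; (1 - w)\, f_T(\ell)$$

between the Weibull mode and the trans mode (where the difference changes
sign exactly once; multiple crossings would be flagged and resolved to the
largest root below the trans mode). Root-finding is bracketed bisection /
interpolation to $10^{-10}$ in $\ell$, polished until the density
difference is below $10^{-12}$. Under the equal-prior convention the
unweighted densities are compared ($w$ treated as 1/2 on both sides).
With the fitted cis fraction around 0.8 the boundary sits near 940 kbp;
treating the regimes as a priori equally likely pulls it in to about
650 kbp — the prior convention, not the data, accounts for that
difference, so both are always reported.

Confidence intervals are parametric bootstrap: parameter vectors are drawn
from the multivariate normal at the optimum with the fit covariance, the
cross-over is recomputed per draw (default 10,000 draws, fixed seed), and
the percentile interval is returned. Draws outside the parameter domain or
without a density crossing are rejected; more than 5% failures is an
error. The bootstrap was chosen because it is reproducible and
assumption-light, and because the interval is strongly asymmetric in bp;
where only printed standard errors (no covariance) are available, a
diagonal covariance is an explicit, documented approximation.
`classify_qtl()` operationalizes the boundary: a record is labelled cis
below the cross-over, and its posterior cis probability
$w f_W / (w f_W + (1-w) f_T)$ is exactly 1/2 at the boundary.

## Preprocessing filters

The distance list is built from study tables by rules that mirror common
QTL-study reporting conventions, each returning its rejected rows with
reason codes so that records are conserved and every filter is idempotent:

- **pQTL**: keep the primary association per locus (the `rank` flag when
  present, else the strongest by `strength`), drop variant-gene pairs on
  different chromosomes, and drop traits whose cognate gene is ambiguous —
  more than one candidate gene on the variant's chromosome.
- **eQTL**: keep $|Z| \ge 5.4485$ (inclusive; the conventional $5\times
  10^{-8}$ genome-wide threshold expressed as a Z-score), then the single
  largest-$|Z|$ record per gene.
- **metabolite QTL**: for each (metabolite, chromosome) with exactly one
  interacting gene in the supplied map, the strongest association on that
  chromosome, requiring $p$ strictly below $5\times 10^{-8}$.

Coordinates are 1-based; distances are strand-agnostic absolute
differences; precomputed distance columns pass through untouched.
Genome-build harmonization and identifier rescue are upstream curation,
out of scope: the readers assume pre-harmonized coordinates. Column
mapping is driven by a small YAML schema, so new study layouts need no
code change.

## The synthetic-data generator

`simulate_qtl_distances()` draws each trait cis with probability $w$
(chromosome proportional to length — gene placement follows length; log10
distance from the Weibull; redrawn in the rare case the draw exceeds the
chromosome) and trans otherwise (chromosome proportional to length
squared; absolute difference of two uniform positions, zero differences
redrawn). Distances are emitted as integers $\ge 1$ bp with the latent
cis/trans truth label attached. Defaults ($n$ free, $\kappa = 6.78$,
$\lambda = 4.48$, $w = 0.799$) are the published pQTL-scale conditions, so
a default simulation of ~2,000 traits looks like a real large pQTL study:
two peaks, a trough near $\ell = 6$, about 80% of records below 1 Mb.

What the generator deliberately does *not* emulate: linkage
disequilibrium between lead variants, winner's-curse selection of lead
SNPs, gene-density and annotation structure along chromosomes, missense
clustering, or the error in assigning cognate genes. Passing recovery
tests on synthetic data therefore demonstrates the estimator is correct
*under the model's own assumptions* — it cannot certify those assumptions
for any particular real study; the KS comparison against the data is what
speaks to that.

## Numerical and design choices

- Problem sizes in the test suite were chosen to mirror the real studies
  (fits at $n \approx 2{,}000$, samplers checked at $10^5$ draws,
  bootstrap intervals at 1,500–10,000 draws) while keeping the whole
  suite around a minute.
- Fit starting values for stage 1 come from moment inversion of the
  sub-cutoff bin mids (coefficient-of-variation rule for the Weibull), so
  stage 1 needs no user input; stage 2 always starts from stage 1, never
  from user guesses.
- Boundary conventions: KS ties warnings from integer distances are
  muffled (ties are real but physically meaningless at genome scale);
  the binning nudges $\ell/w$ by $10^{-9}$ before `floor()` so exact
  powers of $10^{0.25}$ land deterministically in their own bin despite
  floating-point representation.
- The cross-over is reported in bp with full precision in JSON; printed
  output rounds to the nearest kbp.
- All pipeline outputs embed the package version, configuration hash and
  seed, and contain no timestamps, so byte-identical reruns are part of
  the tested contract.

## Known limitations

- The least-squares weighting ($1/\max(c,1)$) is a pragmatic stand-in for
  a full Poisson likelihood; a maximum-likelihood or Bayesian fit is a
  natural extension and deliberately not included.
- KS p-values are anti-conservative (parameters fit on the same data),
  as noted above.
- Only intrachromosomal trans effects are modelled; interchromosomal
  trans-QTLs are excluded upstream by the filters.
- The single strongest association per trait biases the variant set in
  ways the model does not attempt to correct; secondary signals are out
  of scope.
- With only printed standard errors, bootstrap intervals ignore parameter
  correlations (shape and scale estimates are correlated in practice), so
  such intervals are approximate by construction.
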