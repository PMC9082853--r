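# cistrans

Empirical cis/trans classification of molecular QTLs from variant-TSS
distances.

## The problem

Molecular-QTL studies (pQTL, eQTL, metabolite QTL) associate a lead
genetic variant with the abundance of a trait whose cognate gene is known.
Whether that variant acts **in cis** (directly on the cognate gene) or
**in trans** (through an intermediate gene) is usually decided by an
arbitrary distance window — 250 kb here, 1 Mb there. `cistrans` replaces
the convention with an estimate: it models the observed intrachromosomal
variant-to-TSS distances as a mixture of two regimes and computes the
distance at which one regime hands over to the other.

## The model

Distances `d` (in bp) are log-transformed, `lx = log10(d)`, and binned at
0.25 log10 units. The mixture has three parameters:

- **cis component** — a Weibull density on log10 distance,
  `f_W(lx) = (κ/λ)(lx/λ)^(κ−1) exp(−(lx/λ)^κ)`, with shape `κ` and scale
  `λ` (log10-bp);
- **trans component** — the parameter-free distribution of the distance
  between two random positions on the same chromosome, marginalized over
  chromosomes with weights `N_i²/ΣN_j²`:
  `f_T(d) = Σ_i 2(N_i − d)[d < N_i] / Σ_i N_i²` (GRCh38 chr1-22+X lengths
  built in, overridable);
- **cis fraction** `w` — the mixture weight of the Weibull component.

Fitting is two-stage weighted nonlinear least squares on the binned
counts (cis-only below the histogram trough, then all three parameters on
all bins), with Jacobian-based standard errors and one-sample
Kolmogorov–Smirnov goodness-of-fit against the unbinned log distances —
for both the Weibull and a Gaussian cis alternative. The **cross-over
distance**, the empirical cis/trans boundary, is the root of
`w f_W(lx) = (1−w) f_T(lx)`, with a parametric-bootstrap confidence
interval; an equal-prior convention (`w` treated as 1/2) is also
reported. See `vignettes/cistrans-methods.Rmd` for assumptions, numerical
choices and limitations.

## Worked example

```r
library(cistrans)

# a pQTL-scale dataset with the generator's default (published) parameters
qtl <- simulate_qtl_distances(2051, seed = 1)
fit <- cistrans_fit(qtl)
summary(fit)
#> Cis/trans mixture fit (weibull cis component) on 2051 distances
#>   shape = 6.737 (0.131), scale = 4.488 (0.017), fraction = 0.7993 (0.00853)
#>   initial cutoff lx = 6.25
#>   KS p (weibull cis): 0.792
#>   KS p (gaussian cis): 0.185
#>   initial (cis-only) fit: shape = 6.663, scale = 4.496; initial fraction = 0.802
#>   bins: 29  deviance: 23.99  iterations: 3
#>   cross-over: 977 kbp (fitted prior), 675 kbp (equal prior)

crossover(fit, ci = TRUE, n_boot = 10000, seed = 1)
#> Cis/trans cross-over (fitted prior): 977 kbp
#>   95% bootstrap CI: [873 - 1,101] kbp (10000 draws, seed 1)

classify_qtl(c(5e4, 2e6), fit)
#>    dist class posterior_cis
#> 1 5e+04   cis    0.99925685
#> 2 2e+06 trans    0.03691327
```

Reading: the generator drew 2,051 traits with true `(κ, λ, w) = (6.78,
4.48, 0.799)`; the fit recovers them within about one standard error each
(the parenthesized values). The Weibull cis model fits better than the
Gaussian alternative (KS p 0.79 vs 0.19). A variant 50 kb from its
cognate gene's TSS is essentially certainly cis (posterior 0.999); at
2 Mb the odds have flipped (posterior 0.037), and the boundary — where
the posterior is exactly 1/2 — sits at 977 kbp for this realization, or
675 kbp if cis and trans are treated as a priori equally likely.

`plot(fit)` overlays the fitted cis, trans and combined curves on the
binned counts. Real study tables enter through `read_study_table()` (YAML
column schema) and the filters `filter_intrachromosomal_primary()`,
`filter_eqtl_zscore()`, `filter_metabolite_single_gene()` and
`compute_distances()`; `inst/cli/cistrans.R` wires the same steps into
shell subcommands (`preprocess`, `fit`, `crossover`, `simulate`).

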