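test_that("cis-only least squares recovers pure-Weibull parameters", {
  d <- simulate_qtl_distances(1e5, shape = 6.5, scale = 4.4, fraction = 1,
                              seed = 21)
  fit <- cistrans_fit(d, truncate_at = 8.5)
  expect_lt(abs(coef(fit)[["shape"]] - 6.5), 0.1)
  expect_lt(abs(coef(fit)[["scale"]] - 4.4), 0.02)
  expect_equal(coef(fit)[["fraction"]], 1)
  expect_true(is.na(fit$se[["fraction"]]))
})

test_that("degenerate histograms are refused", {
  expect_error(cistrans_fit(rep(1e4, 50), truncate_at = 6),
               "fewer than 3")
  d <- simulate_qtl_distances(500, fraction = 1, seed = 3)
  expect_error(cistrans_fit(d, truncate_at = 2), "fewer than 3")
  expect_error(cistrans_fit(numeric(0)), "no distances")
})

test_that("three-parameter mixture recovers simulated truth within 3 SEs", {
  truth <- c(shape = 6.2, scale = 4.4, fraction = 0.7)
  d <- simulate_qtl_distances(2000, shape = truth[1], scale = truth[2],
                              fraction = truth[3], seed = 101)
  fit <- cistrans_fit(d)
  est <- coef(fit)
  for (p in names(truth)) {
    expect_lt(abs(est[[p]] - truth[[p]]), 3 * fit$se[[p]])
  }
  expect_true(fit$converged)
  expect_true(all(fit$se > 0, na.rm = TRUE))
})

test_that("stage-1 initial fit equals a fraction-fixed fit on sub-cutoff bins", {
  d <- simulate_qtl_distances(2051, seed = 1)
  fit <- cistrans_fit(d)
  sub <- cistrans_fit(d, truncate_at = fit$cutoff, fit_alternative = FALSE)
  expect_equal(unname(fit$initial$par), unname(coef(sub)[1:2]),
               tolerance = 1e-6)
  # initial fraction is the count share below the cutoff
  expect_equal(fit$initial$fraction, mean(log10(d$dist) < fit$cutoff),
               tolerance = 1e-9)
})

test_that("the final fit improves on its starting objective", {
  for (s in c(1, 7)) {
    d <- simulate_qtl_distances(1500, seed = s)
    fit <- cistrans_fit(d, fit_alternative = FALSE)
    expect_lte(fit$deviance, fit$start_deviance)
  }
})

test_that("refitting data simulated from the fit recovers it (closure)", {
  d <- simulate_qtl_distances(2051, seed = 1)
  fit <- cistrans_fit(d, fit_alternative = FALSE)
  d2 <- simulate(fit, seed = 99)[[1]]
  fit2 <- cistrans_fit(d2, fit_alternative = FALSE)
  for (p in c("shape", "scale", "fraction")) {
    expect_lt(abs(coef(fit2)[[p]] - coef(fit)[[p]]), 3 * fit2$se[[p]])
  }
})

test_that("KS machinery matches a hand computation and is self-consistent", {
  m <- trans_model()
  pmix <- mixture_params(shape = 6.777, scale = 4.478, fraction = 0.799)
  x <- c(1e3, 2e4, 1e5, 3e6, 9e7)
  ks <- ks_mixture_test(x, pmix, m)
  expect_equal(unname(ks$statistic),
               ks_stat_hand(log10(x), function(q) mixture_cdf(q, pmix, m)))
  # a sample drawn from the fitted model itself should not be rejected
  d <- simulate_qtl_distances(2000, shape = 6.777, scale = 4.478,
                              fraction = 0.799, seed = 55)
  expect_gt(ks_mixture_test(d$dist, pmix, m)$p.value, 0.001)
  expect_error(ks_mixture_test(numeric(0), pmix, m), "empty")
})

test_that("the Weibull cis model outfits the Gaussian alternative on pQTL-like data", {
  d <- simulate_qtl_distances(2051, seed = 1)
  fit <- cistrans_fit(d)
  expect_gte(fit$ks[["weibull"]], fit$ks[["gaussian"]])
  expect_s3_class(fit$alt$params, "mixture_params")
  expect_identical(fit$alt$params$cis, "gaussian")
})

test_that("a fraction pinned at its bound is flagged", {
  # noiseless pure-trans expected counts force the cis weight to the w = 0
  # bound, which must be reported, not silently accepted
  m <- trans_model()
  breaks <- seq(0, 8.5, by = 0.25)
  counts <- expected_counts(
    breaks, mixture_params(shape = 6.777, scale = 4.478, fraction = 0), m,
    total = 2000)
  expect_warning(
    res <- cistrans:::ls_fit(breaks, counts, total = 2000, model = m,
                             cis = "weibull",
                             start = c(shape = 6.777, scale = 4.478),
                             weighted = TRUE, maxiter = 200,
                             free_fraction = TRUE, fraction_start = 0.2),
    "pinned")
  expect_true(res$pinned)
  expect_lt(res$fraction, 1e-6)
})

test_that("fit accepts the canonical data.frame shape and exposes methods", {
  d <- simulate_qtl_distances(1200, seed = 13)
  f1 <- cistrans_fit(d, fit_alternative = FALSE)
  f2 <- cistrans_fit(d$dist, fit_alternative = FALSE)
  expect_equal(coef(f1), coef(f2))
  expect_equal(length(fitted(f1)), length(f1$histogram$counts))
  r <- residuals(f1)
  expect_equal(unname(r * sqrt(pmax(fitted(f1), .Machine$double.eps))),
               unname(residuals(f1, type = "response")))
  expect_output(print(f1), "mixture fit")
  expect_output(print(summary(f1)), "cross-over")
  V <- vcov(f1)
  expect_equal(dim(V), c(3, 3))
  expect_equal(unname(sqrt(diag(V))), unname(f1$se), tolerance = 1e-8)
  post <- predict(f1, c(1e4, 1e8))
  expect_gt(post[1], 0.99)
  expect_lt(post[2], 0.01)
  cls <- predict(f1, c(1e4, 1e8), type = "class")
  expect_equal(as.character(cls), c("cis", "trans"))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(f1))
})
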