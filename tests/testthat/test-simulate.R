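test_that("degenerate mixture fractions produce pure components", {
  cis_only <- simulate_qtl_distances(1e4, shape = 6.78, scale = 4.48,
                                     fraction = 1, seed = 71)
  expect_true(all(cis_only$class == "cis"))
  ks <- suppressWarnings(stats::ks.test(
    log10(cis_only$dist), function(q) pcis_log10(pmax(q, 0), 6.78, 4.48)))
  expect_gt(ks$p.value, 0.01)

  trans_only <- simulate_qtl_distances(2e4, fraction = 0, seed = 72)
  expect_true(all(trans_only$class == "trans"))
  expect_equal(mean(trans_only$dist > 1e6), 0.99, tolerance = 0.01)
})

test_that("default generator reproduces the two-regime shape of pQTL data", {
  d <- simulate_qtl_distances(2051, seed = 2026)
  h <- log10_histogram(d$dist)
  short <- h$counts[h$labels < 5.5]
  long <- h$counts[h$labels >= 6.5]
  trough <- h$counts[h$labels >= 5.5 & h$labels < 6.5]
  expect_gt(max(short), max(trough) * 3)
  expect_gt(max(long), max(trough))
  # ~80% of records below 1 Mb (within 4 binomial sigmas of the fraction)
  tol <- 4 * sqrt(0.799 * 0.201 / 2051)
  expect_lt(abs(mean(d$dist < 1e6) - 0.799), tol + 0.01)
  expect_true(all(d$dist >= 1))
  expect_true(all(d$dist == floor(d$dist)))
})

test_that("latent labels follow the mixture fraction and their components", {
  n <- 1e5
  d <- simulate_qtl_distances(n, seed = 73)
  w_hat <- mean(d$class == "cis")
  expect_lt(abs(w_hat - 0.799), 4 * sqrt(0.799 * 0.201 / n))
  # label-conditional distributions match direct component samplers
  set.seed(74)
  ref_cis <- as.numeric(rcis(n, 6.78, 4.48))
  ks_c <- suppressWarnings(
    stats::ks.test(log10(d$dist[d$class == "cis"]), log10(ref_cis)))
  expect_gt(ks_c$p.value, 0.01)
  ref_trans <- as.numeric(rtrans(n, trans_model()))
  ks_t <- suppressWarnings(
    stats::ks.test(log10(d$dist[d$class == "trans"]), log10(ref_trans)))
  expect_gt(ks_t$p.value, 0.01)
})

test_that("cis draws respect chromosome bounds and the generator is reproducible", {
  chroms <- chromosome_set(c("small", "big"), c(5e4, 2.5e8))
  d <- simulate_qtl_distances(4000, chromosomes = chroms, seed = 75)
  small <- d[d$chrom == "small", ]
  expect_true(all(small$dist < 5e4))
  a <- simulate_qtl_distances(500, seed = 9)
  b <- simulate_qtl_distances(500, seed = 9)
  expect_identical(a, b)
  expect_equal(nrow(simulate_qtl_distances(0, seed = 1)), 0)
})

test_that("a battery of datasets drives parameter recovery across a grid", {
  dir <- tempfile("battery")
  grid <- expand.grid(shape = c(5.5, 6.8, 8),
                      fraction = c(0.6, 0.8, 0.9),
                      scale = 4.5, n = 2000, seed = 0)
  grid$seed <- 100 + seq_len(nrow(grid))
  man <- simulate_study_battery(grid, dir)
  expect_equal(nrow(man), 9)
  expect_true(all(file.exists(file.path(dir, man$file))))
  expect_true(file.exists(file.path(dir, "manifest.json")))

  hits <- 0L
  for (i in seq_len(nrow(man))) {
    dat <- utils::read.delim(file.path(dir, man$file[i]))
    fit <- tryCatch(
      suppressWarnings(cistrans_fit(dat, fit_alternative = FALSE)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ok <- abs(coef(fit)[["shape"]] - man$shape[i]) <=
      3 * fit$se[["shape"]] &&
      abs(coef(fit)[["scale"]] - man$scale[i]) <= 3 * fit$se[["scale"]] &&
      abs(coef(fit)[["fraction"]] - man$fraction[i]) <=
      3 * fit$se[["fraction"]]
    hits <- hits + ok
  }
  expect_gte(hits, 8)

  # single-row grids work and identical seeds give byte-identical files
  dir2 <- tempfile("battery"); dir3 <- tempfile("battery")
  one <- grid[5, ]
  simulate_study_battery(one, dir2)
  simulate_study_battery(one, dir3)
  f2 <- file.path(dir2, "dataset_001.tsv")
  f3 <- file.path(dir3, "dataset_001.tsv")
  expect_identical(readLines(f2), readLines(f3))
})

test_that("simulate -> fit -> crossover closes on the generating model", {
  truth <- crossover_distance(6.78, 4.48, 0.799)$distance
  d <- simulate_qtl_distances(2051, seed = 1)
  fit <- cistrans_fit(d, fit_alternative = FALSE)
  est <- crossover(fit)$distance
  expect_lt(abs(est - truth) / truth, 0.10)
})
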