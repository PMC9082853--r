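#' Cis/trans cross-over distance
#'
#' The empirical boundary between the cis and trans regimes: the distance at
#' which the fraction-weighted cis (Weibull) density equals the
#' complementary-weighted trans density on the log10 scale,
#' `w * f_cis(lx) = (1 - w) * f_trans(lx)`. Because both densities are
#' transformed identically, the root is the same whether the comparison is
#' made in log or linear space. Under `prior = "equal"` the two regimes are
#' treated as a priori equally likely (`w = 1/2` on both sides, i.e. the
#' unweighted densities are compared), which pulls the boundary inward
#' whenever the fitted cis fraction exceeds one half.
#'
#' The root is bracketed between the cis (Weibull) mode and the trans mode
#' and found by bisection/interpolation to 1e-10 in lx, then polished so the
#' density difference at the root is below 1e-12. If the density difference
#' changes sign more than once on the bracket, the largest root below the
#' trans mode is returned with a warning.
#'
#' @param object A [cistrans_fit()] (for the generic), or use
#'   [crossover_distance()] directly with printed parameters.
#' @param prior `"fitted"` (use the fitted cis fraction; requires
#'   `0 < w < 1`) or `"equal"`.
#' @param ci Compute a parametric-bootstrap confidence interval (fits only).
#' @param level Confidence level for the interval.
#' @param n_boot Bootstrap draws.
#' @param seed RNG seed for the bootstrap.
#' @param ... Passed on.
#' @return An object of class `"crossover"`: list with `distance` (bp),
#'   `lx` (the root), `prior`, and when `ci = TRUE` also `ci_low`,
#'   `ci_high`, `level`, `n_boot`, `seed`.
#' @examples
#' # cross-over from published pQTL fit parameters
#' crossover_distance(shape = 6.777, scale = 4.478, fraction = 0.799)
#' @export
crossover <- function(object, ...) UseMethod("crossover")

#' @rdname crossover
#' @export
crossover.cistrans_fit <- function(object, prior = c("fitted", "equal"),
                                   ci = FALSE, level = 0.95,
                                   n_boot = 10000, seed = 1, ...) {
  prior <- match.arg(prior)
  if (object$cis != "weibull") {
    stop("cross-over is defined for the Weibull cis component")
  }
  p <- coef(object)
  res <- crossover_distance(shape = p[["shape"]], scale = p[["scale"]],
                            fraction = p[["fraction"]],
                            model = object$model, prior = prior)
  if (ci) {
    res <- crossover_ci(object, prior = prior, level = level,
                        n_boot = n_boot, seed = seed)
  }
  res
}

#' @rdname crossover
#' @param shape,scale Weibull cis parameters.
#' @param fraction Fitted cis fraction `w`.
#' @param model A [trans_model()].
#' @export
crossover_distance <- function(shape, scale, fraction = 0.5,
                               model = trans_model(),
                               prior = c("fitted", "equal")) {
  prior <- match.arg(prior)
  w <- if (prior == "equal") 0.5 else fraction
  if (w <= 0 || w >= 1) {
    stop("fitted-prior cross-over requires 0 < fraction < 1")
  }
  g <- function(lx) {
    w * stats::dweibull(lx, shape, scale) -
      (1 - w) * dtrans_log10(lx, model)
  }
  # bracket: cis mode to trans mode
  lo <- if (shape > 1) scale * ((shape - 1) / shape)^(1 / shape) else
    0.5 * scale
  hi <- stats::optimize(function(lx) dtrans_log10(lx, model),
                        c(0, log10(model$max_length)),
                        maximum = TRUE)$maximum
  if (!(g(lo) > 0 && g(hi) < 0)) {
    stop("no sign change of the density difference between the cis mode (",
         signif(lo, 4), ") and the trans mode (", signif(hi, 4), ")")
  }
  # guard against multiple crossings on the bracket
  grid <- seq(lo, hi, length.out = 512)
  sg <- sign(g(grid))
  flips <- which(diff(sg) != 0)
  if (length(flips) > 1L) {
    warning("multiple density crossings found; returning the largest ",
            "root below the trans mode")
    lo <- grid[flips[length(flips)]]
    hi <- grid[flips[length(flips)] + 1L]
  }
  root <- stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
  # polish by bisection until the density difference itself is ~0
  a <- root - 1e-10; b <- root + 1e-10
  if (g(a) > 0 && g(b) < 0) {
    for (i in 1:60) {
      m <- (a + b) / 2
      if (abs(g(m)) < 1e-13 || (b - a) < 4e-16 * max(1, abs(m))) break
      if (g(m) > 0) a <- m else b <- m
    }
    root <- (a + b) / 2
  }
  structure(list(distance = 10^root, lx = root, prior = prior,
                 residual = g(root)),
            class = "crossover")
}

#' Parametric-bootstrap confidence interval for the cross-over
#'
#' Draws parameter vectors from the multivariate normal centred at the
#' fitted optimum with the fit's covariance, recomputes the cross-over for
#' each draw, and returns the percentile interval. Draws outside the
#' parameter domain (fraction outside (0, 1), non-positive shape or scale)
#' or with no density crossing are rejected; more than 5% failures is an
#' error. Deterministic given `seed`.
#'
#' @param fit A [cistrans_fit()], or any list with elements `params`
#'   (a [mixture_params()]), `vcov` (3x3 covariance for shape, scale,
#'   fraction) and `model` (a [trans_model()]).
#' @inheritParams crossover
#' @return A `"crossover"` object with `ci_low` and `ci_high` in bp.
#' @export
crossover_ci <- function(fit, prior = c("fitted", "equal"), level = 0.95,
                         n_boot = 10000, seed = 1) {
  prior <- match.arg(prior)
  params <- fit$params
  if (params$cis != "weibull") stop("cross-over CI needs a Weibull cis fit")
  V <- fit$vcov
  if (is.null(V) || any(!is.finite(V))) {
    stop("fit has no finite parameter covariance")
  }
  mu <- c(params$par[["shape"]], params$par[["scale"]], params$fraction)
  if (nrow(V) == 2L) {  # fraction fixed: pad with zero variance
    V <- rbind(cbind(V, 0), 0)
  }
  point <- crossover_distance(mu[1], mu[2], mu[3], fit$model, prior)
  set.seed(seed)
  draws <- MASS::mvrnorm(n_boot, mu = mu, Sigma = V)
  ok <- draws[, 1] > 0 & draws[, 2] > 0 &
    draws[, 3] > 0 & draws[, 3] < 1
  xo <- rep(NA_real_, n_boot)
  for (i in which(ok)) {
    xo[i] <- tryCatch(
      crossover_distance(draws[i, 1], draws[i, 2], draws[i, 3],
                         fit$model, prior)$distance,
      warning = function(w) suppressWarnings(
        crossover_distance(draws[i, 1], draws[i, 2], draws[i, 3],
                           fit$model, prior)$distance),
      error = function(e) NA_real_)
  }
  fail <- mean(is.na(xo))
  if (fail > 0.05) {
    stop("cross-over root-finding failed for ", round(100 * fail, 1),
         "% of bootstrap draws")
  }
  qs <- stats::quantile(xo, c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE, names = FALSE)
  structure(list(distance = point$distance, lx = point$lx, prior = prior,
                 residual = point$residual,
                 ci_low = qs[1], ci_high = qs[2], level = level,
                 n_boot = n_boot, n_failed = sum(is.na(xo)), seed = seed),
            class = "crossover")
}

#' @export
print.crossover <- function(x, ...) {
  cat("Cis/trans cross-over (", x$prior, " prior): ",
      format(round(x$distance / 1e3), big.mark = ","), " kbp\n", sep = "")
  if (!is.null(x$ci_low)) {
    cat("  ", 100 * x$level, "% bootstrap CI: [",
        format(round(x$ci_low / 1e3), big.mark = ","), " - ",
        format(round(x$ci_high / 1e3), big.mark = ","), "] kbp (",
        x$n_boot, " draws, seed ", x$seed, ")\n", sep = "")
  }
  invisible(x)
}

#' Classify distances as cis or trans
#'
#' Labels a record cis when its distance falls below the cross-over under
#' the chosen prior convention, and reports the posterior probability of the
#' cis component at the record's log10 distance,
#' `w f_cis / (w f_cis + (1-w) f_trans)` (with `w = 1/2` under the
#' equal-prior convention). The posterior is exactly 1/2 at the cross-over.
#'
#' @param distance Distances in bp (`>= 1`).
#' @param fit A [cistrans_fit()], or a [mixture_params()] with a Weibull cis
#'   component (then supply `model`).
#' @param model A [trans_model()]; taken from `fit` when available.
#' @param prior Prior convention, `"fitted"` or `"equal"`.
#' @return A data.frame with columns `dist`, `class` (factor cis/trans) and
#'   `posterior_cis`.
#' @export
classify_qtl <- function(distance, fit, model = NULL,
                         prior = c("fitted", "equal")) {
  prior <- match.arg(prior)
  if (any(distance < 1)) stop("distances must be >= 1 bp")
  if (inherits(fit, "cistrans_fit")) {
    params <- fit$params
    model <- fit$model
  } else {
    params <- fit
    if (is.null(model)) model <- trans_model()
  }
  if (params$cis != "weibull") stop("classification needs a Weibull cis model")
  shape <- params$par[["shape"]]; scale <- params$par[["scale"]]
  w <- if (prior == "equal") 0.5 else params$fraction
  xo <- crossover_distance(shape, scale, params$fraction, model, prior)
  lx <- log10(distance)
  fc <- stats::dweibull(lx, shape, scale)
  ft <- dtrans_log10(lx, model)
  post <- w * fc / (w * fc + (1 - w) * ft)
  data.frame(
    dist = distance,
    class = factor(ifelse(distance < xo$distance, "cis", "trans"),
                   levels = c("cis", "trans")),
    posterior_cis = post
  )
}
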