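#' Fit the cis/trans mixture to variant-TSS distances
#'
#' The central estimator of the package. Variant-TSS distances are binned at
#' `bin_width` log10 units and a three-parameter mixture — a Weibull density
#' on log10 distance (cis) plus the parameter-free chromosome-length trans
#' model — is fit to the bin counts by weighted nonlinear least squares in
#' two stages:
#'
#' 1. **Initial cis fit.** A Weibull-only fit (`fraction` fixed at 1) to the
#'    bins entirely below `cutoff`, the trough between the two histogram
#'    peaks (located automatically by [suggest_cutoff()] unless given). The
#'    initial cis fraction is the share of records below the cutoff.
#' 2. **Combined fit.** Shape, scale and the cis fraction `w` are freed and
#'    fit to *all* bins, starting from the stage-1 values, with expected
#'    counts `total * (w * dF_cis + (1-w) * dF_trans)` per bin.
#'
#' Standard errors come from the Jacobian-based covariance at the optimum,
#' scaled by the residual variance. Goodness of fit is a one-sample
#' Kolmogorov-Smirnov test of the *unbinned* log10 distances against the
#' fitted mixture CDF; the same protocol is run with a Gaussian cis
#' component (mean/sd on log10 distance) as the comparison model, so both
#' p-values are always reported.
#'
#' Residual-variance weighting uses `1/max(count, 1)` per bin (approximate
#' Poisson weighting); set `weighted = FALSE` for ordinary least squares.
#'
#' @param x Numeric vector of distances in bp, or a data.frame with a
#'   `dist` column (the canonical distance-table shape).
#' @param chromosomes A [chromosome_set()] defining the trans model.
#' @param bin_width Histogram bin width in log10 units.
#' @param cutoff Initial cis cutoff in log10 units, or `"auto"` to take the
#'   histogram trough.
#' @param cis Cis family for the primary fit: `"weibull"` (default) or
#'   `"gaussian"`.
#' @param truncate_at If non-`NULL`, fit a cis-only model (`fraction` fixed
#'   at 1) to bins below this log10 limit — for studies that only test
#'   variants within a fixed window (e.g. 1 Mb) of the gene. The fraction is
#'   reported as 1 with no standard error.
#' @param weighted Use `1/max(count, 1)` bin weights (default `TRUE`).
#' @param fit_alternative Also fit the other cis family for the KS
#'   comparison (default `TRUE`; skipped for truncated fits).
#' @param maxiter Iteration cap for the Levenberg-Marquardt optimizer.
#'
#' @return An object of class `"cistrans_fit"`; see the methods
#'   [coef.cistrans_fit()], `summary()`, `plot()`, [predict.cistrans_fit()],
#'   [simulate.cistrans_fit()], `residuals()`, `vcov()`, and [crossover()].
#' @examples
#' d <- simulate_qtl_distances(2051, seed = 1)
#' fit <- cistrans_fit(d)
#' coef(fit)
#' crossover(fit)
#' @export
cistrans_fit <- function(x, chromosomes = grch38_chromosomes(),
                         bin_width = 0.25, cutoff = "auto",
                         cis = c("weibull", "gaussian"),
                         truncate_at = NULL, weighted = TRUE,
                         fit_alternative = TRUE, maxiter = 200) {
  cl <- match.call()
  cis <- match.arg(cis)
  if (is.data.frame(x)) {
    if (!"dist" %in% names(x)) stop("data.frame input must have a 'dist' column")
    x <- x$dist
  }
  if (length(x) == 0L) stop("no distances supplied")
  model <- trans_model(chromosomes)
  hist <- log10_histogram(x, bin_width = bin_width)
  lx <- log10(x[is.finite(x) & x >= 1])

  if (!is.null(truncate_at)) {
    res <- fit_cis_only(hist, limit = truncate_at, cis = cis,
                        weighted = weighted, maxiter = maxiter)
    params <- make_params(res$par, fraction = 1, cis = cis)
    # KS against the cis CDF conditioned on the truncation window
    lx_sub <- lx[lx < truncate_at]
    ks_main <- withCallingHandlers(
      stats::ks.test(lx_sub,
                     function(q) cis_cdf(q, params) /
                       cis_cdf(truncate_at, params)),
      warning = function(w) {
        if (grepl("ties", conditionMessage(w))) invokeRestart("muffleWarning")
      })
    out <- structure(list(
      call = cl, distances = x, histogram = hist, model = model,
      cis = cis, cutoff = NA_real_, truncated = truncate_at,
      weighted = weighted,
      initial = NULL,
      params = params,
      se = c(res$se, fraction = NA_real_),
      vcov = res$vcov,
      n = hist$total, n_fit = res$n_fit,
      deviance = res$deviance, start_deviance = res$start_deviance,
      iterations = res$iterations, converged = res$converged,
      pinned = FALSE,
      ks = stats::setNames(list(ks_main$p.value), cis),
      alt = NULL,
      meta = fit_meta(chromosomes)
    ), class = "cistrans_fit")
    return(out)
  }

  if (identical(cutoff, "auto")) cutoff <- suggest_cutoff(hist)
  main <- fit_two_stage(hist, model, cutoff, cis, weighted, maxiter)
  params <- make_params(main$final$par, fraction = main$final$fraction,
                        cis = cis)
  ks_main <- ks_mixture_test(x, params, model)

  alt <- NULL
  ks_alt_p <- NA_real_
  if (fit_alternative) {
    other <- if (cis == "weibull") "gaussian" else "weibull"
    alt_try <- tryCatch(
      fit_two_stage(hist, model, cutoff, other, weighted, maxiter),
      error = function(e) {
        warning("alternative (", other, ") cis fit failed: ",
                conditionMessage(e))
        NULL
      })
    if (!is.null(alt_try)) {
      alt_params <- make_params(alt_try$final$par,
                                fraction = alt_try$final$fraction,
                                cis = other)
      ks_alt_p <- ks_mixture_test(x, alt_params, model)$p.value
      alt <- list(params = alt_params,
                  se = c(alt_try$final$se,
                         fraction = alt_try$final$fraction_se))
    }
  }
  ks <- list(ks_main$p.value, ks_alt_p)
  names(ks) <- c(cis, if (cis == "weibull") "gaussian" else "weibull")

  structure(list(
    call = cl, distances = x, histogram = hist, model = model,
    cis = cis, cutoff = cutoff, truncated = NULL, weighted = weighted,
    initial = main$initial,
    params = params,
    se = c(main$final$se, fraction = main$final$fraction_se),
    vcov = main$final$vcov,
    n = hist$total, n_fit = length(hist$counts),
    deviance = main$final$deviance,
    start_deviance = main$final$start_deviance,
    iterations = main$final$iterations,
    converged = main$final$converged,
    pinned = main$final$pinned,
    ks = ks,
    alt = alt,
    meta = fit_meta(chromosomes)
  ), class = "cistrans_fit")
}

fit_meta <- function(chromosomes) {
  list(package_version = as.character(utils::packageVersion("cistrans")),
       n_chromosomes = nrow(chromosomes),
       genome = if (identical(chromosomes$length,
                              grch38_chromosomes()$length))
         "GRCh38 chr1-22+X (built-in default)" else "user-supplied")
}

make_params <- function(par, fraction, cis) {
  if (cis == "weibull") {
    mixture_params(shape = par[["shape"]], scale = par[["scale"]],
                   fraction = fraction, cis = "weibull")
  } else {
    mixture_params(mean = par[["mean"]], sd = par[["sd"]],
                   fraction = fraction, cis = "gaussian")
  }
}

# crude moment-based starting values for the cis family from sub-cutoff bins
cis_start <- function(mids, counts, cis) {
  m <- sum(mids * counts) / sum(counts)
  s <- sqrt(sum(counts * (mids - m)^2) / max(sum(counts) - 1, 1))
  s <- max(s, 0.05)
  if (cis == "gaussian") return(c(mean = m, sd = s))
  k0 <- min(max((s / m)^(-1.086), 0.2), 40)  # standard CV inversion
  c(shape = k0, scale = m / gamma(1 + 1 / k0))
}

cis_bounds <- function(cis) {
  if (cis == "weibull") {
    list(lower = c(0.1, 0.5), upper = c(50, 10),
         names = c("shape", "scale"))
  } else {
    list(lower = c(0.5, 0.01), upper = c(10, 10),
         names = c("mean", "sd"))
  }
}

# weighted LS fit of expected counts over a bin subset; fraction free or
# fixed. Returns parameters, SEs, covariance, diagnostics.
ls_fit <- function(breaks, counts, total, model, cis, start, weighted,
                   maxiter, free_fraction, fraction_start = NULL) {
  b <- cis_bounds(cis)
  wts <- if (weighted) 1 / sqrt(pmax(counts, 1)) else rep(1, length(counts))
  expected <- function(p) {
    params <- make_params(stats::setNames(p[1:2], b$names),
                          fraction = if (free_fraction) p[3] else 1,
                          cis = cis)
    expected_counts(breaks, params, model, total = total)
  }
  fn <- function(p) (counts - expected(p)) * wts
  par0 <- unname(start[b$names])
  lower <- b$lower; upper <- b$upper
  if (free_fraction) {
    par0 <- c(par0, fraction_start)
    lower <- c(lower, 0); upper <- c(upper, 1)
  }
  res <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper, fn = fn,
    control = minpack.lm::nls.lm.control(maxiter = maxiter))
  if (res$info == 0 || res$info == 9) {
    stop("least-squares fit did not converge (", res$message,
         "); last iterate: ", paste(signif(res$par, 5), collapse = ", "))
  }
  npar <- length(par0)
  dof <- max(length(counts) - npar, 1)
  sigma2 <- sum(res$fvec^2) / dof
  covm <- tryCatch(sigma2 * solve(res$hessian), error = function(e) {
    matrix(NA_real_, npar, npar)
  })
  nm <- c(b$names, if (free_fraction) "fraction")
  dimnames(covm) <- list(nm, nm)
  pinned <- free_fraction &&
    (res$par[3] <= 1e-8 || res$par[3] >= 1 - 1e-8)
  if (pinned) warning("cis fraction pinned at a bound (",
                      signif(res$par[3], 4), ")")
  list(par = stats::setNames(res$par[1:2], b$names),
       fraction = if (free_fraction) res$par[3] else 1,
       se = stats::setNames(sqrt(diag(covm))[1:2], b$names),
       fraction_se = if (free_fraction) unname(sqrt(diag(covm))[3]) else
         NA_real_,
       vcov = covm,
       deviance = sum(res$fvec^2),
       start_deviance = sum(fn(par0)^2),
       iterations = res$niter, converged = TRUE, pinned = pinned,
       n_fit = length(counts))
}

# stage 1: cis-only fit on bins entirely below 'limit' (fraction fixed at 1)
fit_cis_only <- function(hist, limit, cis, weighted, maxiter,
                         start = NULL) {
  nb <- length(hist$counts)
  keep <- which(hist$breaks[-1] <= limit + 1e-9)
  if (length(keep) == 0L || sum(hist$counts[keep] > 0) < 3L) {
    stop("fewer than 3 occupied bins below the cutoff (",
         limit, "); cannot fit the cis component")
  }
  breaks <- hist$breaks[c(keep, max(keep) + 1L)]
  counts <- hist$counts[keep]
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  if (is.null(start)) start <- cis_start(mids, counts, cis)
  # trans mass below the cis cutoff is negligible, so the restricted
  # objective is the mixture objective with fraction pinned at 1
  ls_fit(breaks, counts, total = sum(counts), model = trans_model(),
         cis = cis, start = start, weighted = weighted,
         maxiter = maxiter, free_fraction = FALSE)
}

fit_two_stage <- function(hist, model, cutoff, cis, weighted, maxiter) {
  stage1 <- fit_cis_only(hist, limit = cutoff, cis = cis,
                         weighted = weighted, maxiter = maxiter)
  below <- sum(hist$counts[hist$breaks[-1] <= cutoff + 1e-9])
  frac0 <- below / hist$total
  initial <- list(par = stage1$par, se = stage1$se, fraction = frac0,
                  cutoff = cutoff)
  final <- ls_fit(hist$breaks, hist$counts, total = hist$total,
                  model = model, cis = cis, start = stage1$par,
                  weighted = weighted, maxiter = maxiter,
                  free_fraction = TRUE, fraction_start = frac0)
  list(initial = initial, final = final)
}

#' One-sample Kolmogorov-Smirnov test against a fitted mixture
#'
#' Tests the unbinned log10 distances against the mixture CDF
#' `w * F_cis + (1 - w) * F_trans`. Parameters are typically estimated from
#' the same data, which makes the test anti-conservative; p-values are
#' reported as-is for model comparison, not as calibrated significance.
#'
#' @param distances Distances in bp (must be non-empty).
#' @param params A [mixture_params()].
#' @param model A [trans_model()].
#' @return An object of class `"htest"` from [stats::ks.test()].
#' @export
ks_mixture_test <- function(distances, params, model) {
  if (length(distances) == 0L) stop("empty distance list")
  lx <- log10(distances)
  # distances are integer bp, so occasional ties are expected and harmless
  # at genome scale; silence only the ties warning
  withCallingHandlers(
    stats::ks.test(lx, function(q) mixture_cdf(q, params, model)),
    warning = function(w) {
      if (grepl("ties", conditionMessage(w))) invokeRestart("muffleWarning")
    })
}

#' @export
coef.cistrans_fit <- function(object, ...) {
  c(object$params$par, fraction = object$params$fraction)
}

#' @export
vcov.cistrans_fit <- function(object, ...) object$vcov

#' @export
fitted.cistrans_fit <- function(object, ...) {
  expected_counts(object$histogram, object$params, object$model)
}

#' @export
residuals.cistrans_fit <- function(object,
                                   type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  e <- fitted(object)
  r <- object$histogram$counts - e
  if (type == "pearson") r / sqrt(pmax(e, .Machine$double.eps)) else r
}

#' @export
print.cistrans_fit <- function(x, digits = 4, ...) {
  cat("Cis/trans mixture fit (", x$cis, " cis component) on ", x$n,
      " distances\n", sep = "")
  est <- coef(x)
  se <- x$se
  line <- paste0(names(est), " = ", signif(est, digits),
                 ifelse(is.na(se), " (fixed)",
                        paste0(" (", signif(se, 3), ")")))
  cat(" ", paste(line, collapse = ", "), "\n")
  if (!is.null(x$truncated)) {
    cat("  cis-only fit truncated at lx <", x$truncated, "\n")
  } else {
    cat("  initial cutoff lx =", x$cutoff, "\n")
  }
  for (nm in names(x$ks)) {
    cat("  KS p (", nm, " cis): ", signif(x$ks[[nm]], 3), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.cistrans_fit <- function(object, ...) {
  xo <- if (is.null(object$truncated) && object$params$fraction > 0 &&
            object$params$fraction < 1) {
    list(fitted = crossover(object, prior = "fitted"),
         equal = crossover(object, prior = "equal"))
  } else NULL
  structure(list(fit = object, crossover = xo),
            class = "summary.cistrans_fit")
}

#' @export
print.summary.cistrans_fit <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  if (!is.null(f$initial)) {
    cat("  initial (cis-only) fit: ",
        paste(names(f$initial$par), "=",
              signif(f$initial$par, digits), collapse = ", "),
        "; initial fraction = ", signif(f$initial$fraction, digits),
        "\n", sep = "")
  }
  cat("  bins:", f$n_fit, " deviance:", signif(f$deviance, digits),
      " iterations:", f$iterations, "\n")
  if (!is.null(x$crossover)) {
    cat("  cross-over: ",
        format(round(x$crossover$fitted$distance / 1e3), big.mark = ","),
        " kbp (fitted prior), ",
        format(round(x$crossover$equal$distance / 1e3), big.mark = ","),
        " kbp (equal prior)\n", sep = "")
  }
  invisible(x)
}

#' Posterior cis/trans prediction for new distances
#'
#' @param object A [cistrans_fit()].
#' @param newdata Distances in bp (defaults to the fitted data).
#' @param type `"posterior"` (probability the record is cis), `"class"`
#'   (cis/trans label by the cross-over cutoff), or `"density"` (mixture
#'   density at the record's log10 distance).
#' @param prior Prior convention for classification, see [crossover()].
#' @param ... Unused.
#' @return Numeric vector, or factor for `type = "class"`.
#' @export
predict.cistrans_fit <- function(object, newdata = NULL,
                                 type = c("posterior", "class", "density"),
                                 prior = c("fitted", "equal"), ...) {
  type <- match.arg(type)
  prior <- match.arg(prior)
  d <- if (is.null(newdata)) object$distances else newdata
  if (is.data.frame(d)) d <- d$dist
  if (type == "class") {
    return(classify_qtl(d, object, prior = prior)$class)
  }
  lx <- log10(pmax(d, 1))
  w <- object$params$fraction
  fc <- cis_pdf(lx, object$params)
  ft <- dtrans_log10(lx, object$model)
  if (type == "density") w * fc + (1 - w) * ft
  else w * fc / (w * fc + (1 - w) * ft)
}

#' Simulate distance datasets from a fitted mixture
#'
#' @param object A [cistrans_fit()] with a Weibull cis component.
#' @param nsim Number of replicate datasets.
#' @param seed RNG seed (optional).
#' @param ... Unused.
#' @return A data.frame with `nsim` columns, each a simulated vector of
#'   `object$n` distances in bp.
#' @export
simulate.cistrans_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (object$cis != "weibull") {
    stop("simulation is defined for the Weibull cis component")
  }
  if (!is.null(seed)) set.seed(seed)
  p <- coef(object)
  out <- as.data.frame(replicate(nsim, simulate_qtl_distances(
    n = object$n, shape = p[["shape"]], scale = p[["scale"]],
    fraction = p[["fraction"]],
    chromosomes = object$model$chromosomes)$dist))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a fitted cis/trans mixture over its histogram
#'
#' Draws the binned counts with the fitted cis-only, trans-only and combined
#' per-bin expected curves overlaid, in the style of the log-distance
#' histograms the model is fit to.
#'
#' @param x A [cistrans_fit()].
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.cistrans_fit <- function(x, ...) {
  h <- x$histogram
  mids <- (h$breaks[-1] + h$breaks[-length(h$breaks)]) / 2
  lxs <- seq(min(h$breaks), max(h$breaks), length.out = 400)
  w <- x$params$fraction
  scale <- h$total * h$bin_width
  cis_curve <- scale * w * cis_pdf(lxs, x$params)
  trans_curve <- scale * (1 - w) * dtrans_log10(lxs, x$model)
  graphics::plot(mids, h$counts, type = "h", lwd = 6, col = "grey70",
                 lend = 1, xlab = "log10 variant-TSS distance (bp)",
                 ylab = "QTL count per bin",
                 ylim = c(0, max(h$counts) * 1.05), ...)
  graphics::lines(lxs, cis_curve, col = "red", lwd = 2)
  graphics::lines(lxs, trans_curve, col = "blue", lwd = 2)
  graphics::lines(lxs, cis_curve + trans_curve, col = "purple",
                  lwd = 2, lty = 2)
  graphics::legend("topright", bty = "n", lwd = 2,
                   col = c("red", "blue", "purple"),
                   lty = c(1, 1, 2),
                   legend = c("cis (Weibull)", "trans (random pair)",
                              "combined"))
  invisible(x)
}
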