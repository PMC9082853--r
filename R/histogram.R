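#' Bin distances into fixed-width log10 bins
#'
#' Deterministic binning of variant-TSS distances at (by default) 0.25 log10
#' units, four bins per order of magnitude. Bin k covers
#' `[k*w, (k+1)*w)` in `lx = log10(d)` with k a non-negative integer, so bin
#' edges lie on multiples of the width and a distance of exactly `10^4`
#' starts (and labels) its own bin. Bins are labelled by their left edge by
#' default; a bin-center labelling is available. Leading and trailing empty
#' bins are trimmed; interior empty bins are kept.
#'
#' Distances below 1 bp have no `lx >= 0` representation and are excluded
#' with a warning; the excluded count is recorded.
#'
#' @param distances Numeric distances in bp.
#' @param bin_width Bin width in log10 units (default 0.25).
#' @param label Labelling convention, `"left"` (default) or `"center"`.
#' @return An object of class `"log10_histogram"`: list with `bin_width`,
#'   `breaks` (all bin edges, length nbins+1), `labels`, `counts`, `total`,
#'   `n_rejected`, `label_convention`.
#' @examples
#' h <- log10_histogram(c(10, 99, 100))
#' h$labels[h$counts > 0]   # 1.00 1.75 2.00
#' @export
log10_histogram <- function(distances, bin_width = 0.25,
                            label = c("left", "center")) {
  label <- match.arg(label)
  if (!is.numeric(distances)) stop("'distances' must be numeric")
  if (bin_width <= 0) stop("'bin_width' must be > 0")
  bad <- !is.finite(distances) | distances < 1
  if (any(bad)) {
    warning(sum(bad), " distance(s) below 1 bp (or non-finite) excluded")
  }
  d <- distances[!bad]
  if (length(d) == 0L) stop("no usable distances (all < 1 bp or non-finite)")
  lx <- log10(d)
  # small forward nudge so representation error at exact bin edges cannot
  # push a boundary value into the lower bin
  k <- floor(lx / bin_width + 1e-9)
  kr <- min(k):max(k)
  counts <- tabulate(match(k, kr), length(kr))
  breaks <- c(kr, max(kr) + 1L) * bin_width
  labels <- if (label == "left") kr * bin_width else (kr + 0.5) * bin_width
  structure(list(
    bin_width = bin_width,
    breaks = breaks,
    labels = labels,
    counts = counts,
    total = sum(counts),
    n_rejected = sum(bad),
    label_convention = label
  ), class = "log10_histogram")
}

#' @export
print.log10_histogram <- function(x, ...) {
  occ <- sum(x$counts > 0)
  cat("log10 distance histogram: ", x$total, " records in ", occ,
      " occupied bins (width ", x$bin_width, ", ", x$label_convention,
      "-edge labels)\n", sep = "")
  cat("  span: [", min(x$breaks), ", ", max(x$breaks), ") log10 bp",
      if (x$n_rejected > 0) paste0("; ", x$n_rejected, " rejected < 1 bp"),
      "\n", sep = "")
  invisible(x)
}

#' Suggest the initial cis cutoff from the histogram trough
#'
#' The two-stage fit starts with a cis-only fit below the observed minimum
#' between the two peaks of the distance histogram. This locates the
#' minimum-count bin strictly between the two tallest local maxima, breaking
#' ties toward larger lx, and returns its left edge. Sampling noise can put
#' several local maxima inside one regime's peak, so the second peak is the
#' tallest local maximum at least `min_separation` bins away from the
#' tallest one (default 4 bins = one order of magnitude; the cis and trans
#' modes of real QTL data sit 3-4 orders apart).
#'
#' @param hist A [log10_histogram()].
#' @param min_separation Minimum distance, in bins, between the two peaks.
#' @return Cutoff in log10 units (a bin left edge).
#' @export
suggest_cutoff <- function(hist, min_separation = 4L) {
  stopifnot(inherits(hist, "log10_histogram"))
  cnt <- hist$counts
  n <- length(cnt)
  if (n < 3L) stop("histogram too short to locate a trough; give 'cutoff' explicitly")
  left <- c(-Inf, cnt[-n])
  right <- c(cnt[-1], -Inf)
  peaks <- which(cnt > 0 & cnt >= left & cnt >= right & (cnt > left | cnt > right))
  main <- peaks[which.max(cnt[peaks])]
  far <- peaks[abs(peaks - main) >= min_separation]
  if (length(peaks) < 2L || length(far) == 0L) {
    stop("histogram looks unimodal; give an explicit 'cutoff'")
  }
  second <- far[which.max(cnt[far])]
  top2 <- sort(c(main, second))
  between <- seq(top2[1] + 1L, top2[2] - 1L)
  if (length(between) == 0L) {
    stop("no bins between the two main peaks; give an explicit 'cutoff'")
  }
  lo <- between[cnt[between] == min(cnt[between])]
  hist$breaks[max(lo)]  # tie -> larger lx; left edge of the trough bin
}

#' Mixture parameter sets
#'
#' Bundles a cis-component parameterization (Weibull `shape`/`scale`, or
#' Gaussian `mean`/`sd`) with the cis (Weibull) mixture fraction `w`.
#'
#' @param shape,scale Weibull parameters (cis = "weibull").
#' @param mean,sd Normal parameters on log10 distance (cis = "gaussian").
#' @param fraction Cis mixture weight, in `[0, 1]`.
#' @param cis Cis family, `"weibull"` (default) or `"gaussian"`.
#' @return An object of class `"mixture_params"`.
#' @export
mixture_params <- function(shape = NULL, scale = NULL, fraction,
                           mean = NULL, sd = NULL,
                           cis = c("weibull", "gaussian")) {
  cis <- match.arg(cis)
  if (fraction < 0 || fraction > 1) stop("'fraction' must be in [0, 1]")
  if (cis == "weibull") {
    if (is.null(shape) || is.null(scale)) stop("weibull cis needs shape and scale")
    if (shape <= 0 || scale <= 0) stop("'shape' and 'scale' must be > 0")
    par <- c(shape = shape, scale = scale)
  } else {
    if (is.null(mean) || is.null(sd)) stop("gaussian cis needs mean and sd")
    if (sd <= 0) stop("'sd' must be > 0")
    par <- c(mean = mean, sd = sd)
  }
  structure(list(cis = cis, par = par, fraction = fraction),
            class = "mixture_params")
}

cis_cdf <- function(lx, params) {
  lx <- pmax(lx, 0)
  if (params$cis == "weibull") {
    stats::pweibull(lx, params$par[["shape"]], params$par[["scale"]])
  } else {
    pcis_gaussian(lx, params$par[["mean"]], params$par[["sd"]])
  }
}

cis_pdf <- function(lx, params) {
  if (params$cis == "weibull") {
    stats::dweibull(pmax(lx, 0), params$par[["shape"]], params$par[["scale"]])
  } else {
    dcis_gaussian(lx, params$par[["mean"]], params$par[["sd"]])
  }
}

#' Mixture cumulative distribution on log10 distance
#'
#' `F(lx) = w * F_cis(lx) + (1 - w) * F_trans(lx)`; the CDF used for
#' model-expected bin counts and the one-sample Kolmogorov-Smirnov test.
#'
#' @param lx log10 distances.
#' @param params A [mixture_params()].
#' @param model A [trans_model()].
#' @return Probabilities.
#' @export
mixture_cdf <- function(lx, params, model) {
  w <- params$fraction
  w * cis_cdf(lx, params) +
    (1 - w) * ptrans(pmax(10^lx, 0), model, lower.tail = TRUE)
}

#' Model-expected counts per histogram bin
#'
#' Exact CDF differences (not midpoint densities) of the cis/trans mixture
#' over each bin `[l, r)`, scaled by the record total.
#'
#' @param hist A [log10_histogram()], or a numeric vector of bin edges
#'   (length nbins + 1).
#' @param params A [mixture_params()].
#' @param model A [trans_model()].
#' @param total Record total to scale to; defaults to the histogram total.
#' @return Expected count per bin.
#' @export
expected_counts <- function(hist, params, model, total = NULL) {
  breaks <- if (inherits(hist, "log10_histogram")) hist$breaks else hist
  if (is.null(total)) {
    if (!inherits(hist, "log10_histogram")) {
      stop("'total' required when 'hist' is a vector of edges")
    }
    total <- hist$total
  }
  Fv <- mixture_cdf(breaks, params, model)
  total * diff(Fv)
}
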