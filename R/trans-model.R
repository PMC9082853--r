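#' The distance-independent (trans) random-pair model
#'
#' Distribution of the distance between two positions drawn at random on the
#' same chromosome, marginalized over chromosomes. On a chromosome of length
#' N there are `2 * (N - d)` ordered position pairs at distance `d` (for
#' `0 < d < N`) out of `N^2`, so the within-chromosome density is linear and
#' hits zero at `d = N`; a random intrachromosomal pair lands on chromosome i
#' with probability `N_i^2 / sum(N_j^2)`. The mixture over chromosomes is the
#' trans model: it has no free parameters once the chromosome lengths are
#' fixed.
#'
#' The pmf is renormalized so the discrete sum over d = 1..max(N_i) is
#' exactly 1 (the raw form sums to `sum(N_i*(N_i-1))/sum(N_i^2)`, an O(1/N)
#' deficit that would otherwise leak into mixture weights).
#'
#' @param chromosomes A [chromosome_set()]; defaults to GRCh38 chr1-22+X.
#' @return An object of class `"trans_model"`: a list with the chromosome
#'   table, per-chromosome weights `N_i^2/sum(N_i^2)`, the discrete
#'   normalization constant, and the maximum chromosome length.
#' @seealso [dtrans()], [ptrans()], [rtrans()], [dtrans_log10()]
#' @examples
#' m <- trans_model()
#' ptrans(1e6, m, lower.tail = FALSE)  # ~0.99: random pairs are far apart
#' @export
trans_model <- function(chromosomes = grch38_chromosomes()) {
  if (!inherits(chromosomes, "chromosome_set")) {
    chromosomes <- chromosome_set(chromosomes$name, chromosomes$length)
  }
  N <- chromosomes$length
  structure(list(
    chromosomes = chromosomes,
    weights = N^2 / sum(N^2),
    sum_sq = sum(N^2),
    pair_total = sum(N * (N - 1)),
    normalization = sum(N * (N - 1)) / sum(N^2),
    max_length = max(N)
  ), class = "trans_model")
}

#' @export
print.trans_model <- function(x, ...) {
  cat("Trans (random intrachromosomal pair) model\n")
  cat("  chromosomes:", nrow(x$chromosomes), " max length:",
      format(x$max_length, big.mark = ","), "bp\n")
  cat("  P(d > 1 Mb) =", signif(ptrans(1e6, x, lower.tail = FALSE), 4), "\n")
  invisible(x)
}

#' Trans-model density on the base-pair scale
#'
#' Probability mass at integer distance `d`,
#' `sum_i 2*(N_i - d) [d < N_i] / sum_i N_i^2`, renormalized (by default) so
#' the discrete sum over d = 1..max(N_i) equals 1.
#'
#' @param d Distances in bp; must be strictly positive (the model excludes
#'   the degenerate zero-distance diagonal).
#' @param model A [trans_model()].
#' @param normalized If `FALSE`, return the raw un-renormalized value.
#' @return Probability per bp, zero for `d >= max(N_i)`.
#' @export
dtrans <- function(d, model = trans_model(), normalized = TRUE) {
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop("trans density is defined only for d > 0")
  }
  N <- model$chromosomes$length
  dens <- vapply(d, function(dd) sum(2 * pmax(N - dd, 0)), numeric(1)) /
    model$sum_sq
  if (normalized) dens <- dens / model$normalization
  dens
}

#' Trans-model density on the log10 scale
#'
#' Change of variables of [dtrans()] to `lx = log10(d)`:
#' `f(lx) = f_linear(10^lx) * 10^lx * ln(10)`. This is the curve overlaid on
#' log-binned distance histograms and compared against the cis density at
#' the cross-over.
#'
#' @param lx log10 distance; any finite value (density is 0 above
#'   `log10(max N_i)`).
#' @inheritParams dtrans
#' @return Probability density per log10 unit.
#' @export
dtrans_log10 <- function(lx, model = trans_model(), normalized = TRUE) {
  if (any(!is.finite(lx))) stop("'lx' must be finite")
  dtrans(10^lx, model, normalized = normalized) * 10^lx * log(10)
}

#' Trans-model distribution function
#'
#' Exact tail of the discrete random-pair distance: the number of ordered
#' same-chromosome pairs more than `floor(q)` apart is
#' `sum_i (N_i - k) * (N_i - k - 1)` with `k = floor(q)`, out of
#' `sum_i N_i * (N_i - 1)` pairs at nonzero distance. Matches brute-force
#' pair enumeration exactly and the continuous density to O(1/N).
#'
#' @param q Distances in bp, `q >= 0`.
#' @param model A [trans_model()].
#' @param lower.tail If `TRUE` (default) return `P(d <= q)`, else `P(d > q)`.
#' @return Probabilities.
#' @export
ptrans <- function(q, model = trans_model(), lower.tail = TRUE) {
  if (any(!is.finite(q)) || any(q < 0)) stop("'q' must be finite and >= 0")
  N <- model$chromosomes$length
  k <- floor(q)
  upper <- vapply(k, function(kk) {
    sum(pmax(N - kk, 0) * pmax(N - kk - 1, 0))
  }, numeric(1)) / model$pair_total
  if (lower.tail) 1 - upper else upper
}

#' Sample random intrachromosomal pair distances
#'
#' Draws a chromosome with probability `N_i^2/sum(N_j^2)`, then two
#' independent uniform integer positions on it, returning the absolute
#' difference; zero differences are redrawn on the same chromosome.
#'
#' @param n Number of draws (`n >= 0`).
#' @param model A [trans_model()].
#' @return Integer-valued distances in bp. The assigned chromosome of each
#'   draw is available as attribute `"chrom"`.
#' @export
rtrans <- function(n, model = trans_model()) {
  n <- as.integer(n)
  if (n < 0) stop("'n' must be >= 0")
  if (n == 0L) {
    return(structure(numeric(0), chrom = character(0)))
  }
  N <- model$chromosomes$length
  idx <- sample.int(nrow(model$chromosomes), n, replace = TRUE,
                    prob = model$weights)
  d <- abs(floor(stats::runif(n) * N[idx]) - floor(stats::runif(n) * N[idx]))
  while (any(zero <- d == 0)) {
    iz <- which(zero)
    d[iz] <- abs(floor(stats::runif(length(iz)) * N[idx[iz]]) -
                 floor(stats::runif(length(iz)) * N[idx[iz]]))
  }
  structure(d, chrom = model$chromosomes$name[idx])
}
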