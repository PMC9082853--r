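#' File-to-file pipeline steps
#'
#' Thin wrappers that chain the package's stages as a reproducible pipeline:
#' preprocess a study table to the canonical distance TSV, fit the mixture
#' and serialize the result to JSON, compute cross-over distances from a
#' serialized fit, and simulate synthetic datasets. Every output embeds the
#' package version, the configuration and (where randomness is involved)
#' the seed, and contains no timestamps, so re-running with identical
#' inputs is byte-identical. The same steps are exposed as shell
#' subcommands by the `cistrans` script under `inst/cli/`.
#'
#' @name pipeline
NULL

config_fingerprint <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

load_chromosomes <- function(chrom_lengths) {
  if (is.null(chrom_lengths)) grch38_chromosomes()
  else read_chromosome_lengths(chrom_lengths)
}

#' @rdname pipeline
#' @param input Path to the input table.
#' @param output Path for the canonical distance TSV; a rejection summary
#'   is written next to it as `<output>.rejected.tsv`.
#' @param schema Column-mapping schema for [read_study_table()]; `NULL` if
#'   the table already uses canonical column names.
#' @param filter Filtering recipe: `"pqtl"`
#'   ([filter_intrachromosomal_primary()]), `"eqtl"`
#'   ([filter_eqtl_zscore()] then the intrachromosomal-primary rule),
#'   `"metabolite"` ([filter_metabolite_single_gene()]; needs `gene_map`),
#'   or `"none"` (distances passed through).
#' @param gene_map Path to the metabolite interacting-gene TSV
#'   (`trait`, `gene`, `gene_chrom`, `gene_tss`).
#' @param zscore_threshold Minimum |Z| for the eQTL recipe.
#' @return `pipeline_preprocess()`: the canonical data.frame, invisibly.
#' @export
pipeline_preprocess <- function(input, output, schema = NULL,
                                filter = c("pqtl", "eqtl", "metabolite",
                                           "none"),
                                gene_map = NULL,
                                zscore_threshold = 5.4485) {
  filter <- match.arg(filter)
  rec <- if (is.null(schema)) {
    utils::read.delim(input, stringsAsFactors = FALSE)
  } else {
    read_study_table(input, schema)
  }
  rejected <- list()
  keep_rej <- function(x) {
    rejected[[length(rejected) + 1L]] <<- attr(x, "rejected")
    x
  }
  rec <- switch(filter,
    pqtl = keep_rej(filter_intrachromosomal_primary(rec)),
    eqtl = keep_rej(filter_intrachromosomal_primary(
      keep_rej(filter_eqtl_zscore(rec, threshold = zscore_threshold)))),
    metabolite = {
      if (is.null(gene_map)) stop("metabolite recipe needs 'gene_map'")
      gm <- utils::read.delim(gene_map, stringsAsFactors = FALSE)
      keep_rej(filter_metabolite_single_gene(rec, gm))
    },
    none = rec)
  out <- keep_rej(compute_distances(rec))
  utils::write.table(out, output, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rej <- do.call(rbind, lapply(rejected, function(r) {
    if (is.null(r)) NULL else data.frame(trait = r$trait,
                                         reason = r$reason)
  }))
  utils::write.table(
    if (is.null(rej)) data.frame(trait = character(), reason = character())
    else rej,
    paste0(output, ".rejected.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(out)
}

#' @rdname pipeline
#' @param chrom_lengths Optional chromosome-length file
#'   ([read_chromosome_lengths()]); default GRCh38 chr1-22+X.
#' @param bin_width,cutoff,cis,truncate_at,weighted Passed to
#'   [cistrans_fit()].
#' @return `pipeline_fit()`: the [cistrans_fit()] object, invisibly; the
#'   JSON at `output` carries parameters, standard errors, covariance,
#'   KS p-values, cutoff, diagnostics and a config fingerprint, plus a
#'   `table_row` summarizing both stages.
#' @export
pipeline_fit <- function(input, output, chrom_lengths = NULL,
                         bin_width = 0.25, cutoff = "auto",
                         cis = "weibull", truncate_at = NULL,
                         weighted = TRUE) {
  chromosomes <- load_chromosomes(chrom_lengths)
  dat <- utils::read.delim(input, stringsAsFactors = FALSE)
  fit <- cistrans_fit(dat, chromosomes = chromosomes,
                      bin_width = bin_width, cutoff = cutoff, cis = cis,
                      truncate_at = truncate_at, weighted = weighted)
  config <- list(bin_width = bin_width, cutoff = cutoff, cis = cis,
                 truncate_at = truncate_at, weighted = weighted,
                 chrom_lengths = if (is.null(chrom_lengths)) "GRCh38-default"
                 else chrom_lengths)
  payload <- list(
    package = "cistrans", version = fit$meta$package_version,
    config = config, config_md5 = config_fingerprint(config),
    genome = fit$meta$genome,
    n = fit$n, cutoff = fit$cutoff, truncated = fit$truncated,
    cis = fit$cis,
    estimate = as.list(coef(fit)),
    se = as.list(fit$se),
    vcov = fit$vcov,
    initial = if (is.null(fit$initial)) NULL else
      list(estimate = as.list(fit$initial$par),
           fraction = fit$initial$fraction),
    ks_pvalue = fit$ks,
    diagnostics = list(iterations = fit$iterations,
                       deviance = fit$deviance,
                       converged = fit$converged,
                       fraction_pinned = fit$pinned),
    table_row = fit_table_row(fit)
  )
  jsonlite::write_json(payload, output, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", na = "null")
  invisible(fit)
}

# one row in the layout of the published curve-fit parameter table
fit_table_row <- function(fit) {
  est <- coef(fit)
  list(
    initial_cutoff = fit$cutoff,
    initial_shape = if (is.null(fit$initial)) NA else
      unname(fit$initial$par[1]),
    initial_scale = if (is.null(fit$initial)) NA else
      unname(fit$initial$par[2]),
    initial_fraction = if (is.null(fit$initial)) 1 else
      fit$initial$fraction,
    final_shape = unname(est[1]), final_shape_se = unname(fit$se[1]),
    final_scale = unname(est[2]), final_scale_se = unname(fit$se[2]),
    final_fraction = unname(est[["fraction"]]),
    final_fraction_se = unname(fit$se[["fraction"]]),
    ks_pvalue_weibull = fit$ks[["weibull"]],
    ks_pvalue_gaussian = if (is.null(fit$ks[["gaussian"]])) NA else
      fit$ks[["gaussian"]]
  )
}

#' @rdname pipeline
#' @param fit_json Path to a `pipeline_fit()` JSON.
#' @param n_boot,seed,level Bootstrap settings for [crossover_ci()].
#' @return `pipeline_crossover()`: data.frame with one row per prior
#'   convention, invisibly; written as both JSON (`output`) and TSV
#'   (`<output>.tsv`).
#' @export
pipeline_crossover <- function(fit_json, output, chrom_lengths = NULL,
                               n_boot = 10000, seed = 1, level = 0.95) {
  stored <- jsonlite::read_json(fit_json, simplifyVector = TRUE)
  if (!identical(stored$cis, "weibull")) {
    stop("cross-over needs a Weibull cis fit")
  }
  model <- trans_model(load_chromosomes(chrom_lengths))
  est <- stored$estimate
  V <- stored$vcov
  params <- mixture_params(shape = est$shape, scale = est$scale,
                           fraction = est$fraction)
  pseudo <- list(params = params, vcov = as.matrix(V), model = model)
  rows <- lapply(c("fitted", "equal"), function(pr) {
    x <- crossover_ci(pseudo, prior = pr, level = level,
                      n_boot = n_boot, seed = seed)
    data.frame(prior = pr, distance_bp = x$distance,
               distance_kbp = round(x$distance / 1e3),
               ci_low_bp = x$ci_low, ci_high_bp = x$ci_high,
               level = level, n_boot = n_boot, seed = seed)
  })
  tab <- do.call(rbind, rows)
  jsonlite::write_json(
    list(package = "cistrans",
         version = as.character(utils::packageVersion("cistrans")),
         source_fit = stored$config_md5, crossover = tab),
    output, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.table(tab, paste0(output, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' @rdname pipeline
#' @param n,shape,scale,fraction Generator settings for
#'   [simulate_qtl_distances()].
#' @return `pipeline_simulate()`: the simulated data.frame, invisibly;
#'   written as TSV with a JSON manifest at `<output>.manifest.json`.
#' @export
pipeline_simulate <- function(output, n, shape = 6.78, scale = 4.48,
                              fraction = 0.799, seed = 1,
                              chrom_lengths = NULL) {
  chromosomes <- load_chromosomes(chrom_lengths)
  dat <- simulate_qtl_distances(n, shape, scale, fraction,
                                chromosomes = chromosomes, seed = seed)
  utils::write.table(dat, output, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  config <- list(n = n, shape = shape, scale = scale, fraction = fraction,
                 seed = seed)
  jsonlite::write_json(
    list(package = "cistrans",
         version = as.character(utils::packageVersion("cistrans")),
         config = config, config_md5 = config_fingerprint(config),
         truth = list(n_cis = sum(dat$class == "cis"),
                      n_trans = sum(dat$class == "trans"),
                      redraws = attr(dat, "redraws"))),
    paste0(output, ".manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dat)
}
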