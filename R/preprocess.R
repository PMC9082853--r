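#' Study-table preprocessing: from QTL summary records to distances
#'
#' Converts study-specific QTL summary tables into the canonical
#' variant-TSS distance table the mixture fit consumes. Records are plain
#' data.frames with (a subset of) the columns `trait` (protein, transcript
#' or metabolite identifier), `variant_chrom`, `variant_pos` (1-based bp),
#' `gene`, `gene_chrom`, `gene_tss` (1-based bp), `strength` (association
#' strength: -log10 p or |Z|), `pvalue`, `rank` (primary-association flag)
#' and optionally a precomputed `dist`.
#'
#' Every filter returns the retained rows with the dropped rows attached as
#' attribute `"rejected"` (the input rows plus a `reason` code), so records
#' are conserved: `nrow(input) == nrow(output) + nrow(rejected)`. All
#' filters are idempotent.
#'
#' @name qtl_preprocess
NULL

reject <- function(kept, dropped_list) {
  rej <- do.call(rbind, dropped_list[!vapply(dropped_list, is.null,
                                             logical(1))])
  attr(kept, "rejected") <-
    if (is.null(rej)) NULL else `rownames<-`(rej, NULL)
  kept
}

with_reason <- function(df, reason) {
  if (nrow(df) == 0L) return(NULL)
  df$reason <- reason
  df
}

record_distance <- function(records) {
  if ("dist" %in% names(records)) return(records$dist)
  if (all(c("variant_pos", "gene_tss") %in% names(records))) {
    return(abs(records$variant_pos - records$gene_tss))
  }
  rep(0, nrow(records))  # no distance information: ties fall through to position
}

#' Keep the strongest intrachromosomal primary association per trait
#'
#' Drops records whose variant and cognate gene lie on different
#' chromosomes, drops traits whose cognate gene is ambiguous (more than one
#' distinct gene on the variant's chromosome), then keeps one record per
#' trait: the one flagged primary (when a `rank` column is present) or the
#' strongest by `strength`, with ties broken by smaller distance, then
#' smaller variant position.
#'
#' @param records A QTL record data.frame (see [qtl_preprocess]).
#' @return The retained records, with dropped rows in `attr(,"rejected")`.
#' @export
filter_intrachromosomal_primary <- function(records) {
  stopifnot(all(c("trait", "variant_chrom", "gene_chrom") %in%
                  names(records)))
  drops <- list()
  inter <- records$variant_chrom != records$gene_chrom
  drops$inter <- with_reason(records[inter, , drop = FALSE],
                             "interchromosomal")
  rec <- records[!inter, , drop = FALSE]

  gene_id <- if ("gene" %in% names(rec)) rec$gene else rec$gene_tss
  key <- paste(rec$trait, rec$variant_chrom, sep = "\r")
  n_genes <- vapply(split(gene_id, key),
                    function(g) length(unique(g)), integer(1))
  ambig <- n_genes[key] > 1L
  drops$ambig <- with_reason(rec[ambig, , drop = FALSE],
                             "ambiguous_cognate_gene")
  rec <- rec[!ambig, , drop = FALSE]

  if ("rank" %in% names(rec)) {
    nonprim <- !(rec$rank %in% c("primary", 1, "1"))
    drops$rank <- with_reason(rec[nonprim, , drop = FALSE], "not_primary")
    rec <- rec[!nonprim, , drop = FALSE]
  }

  if (nrow(rec) > 0L) {
    d <- record_distance(rec)
    strength <- if ("strength" %in% names(rec)) abs(rec$strength) else
      rep(0, nrow(rec))
    pos <- if ("variant_pos" %in% names(rec)) rec$variant_pos else
      seq_len(nrow(rec))
    ord <- order(rec$trait, -strength, d, pos)
    best <- !duplicated(rec$trait[ord])
    keep_idx <- sort(ord[best])
    drops$weaker <- with_reason(rec[-keep_idx, , drop = FALSE],
                                "weaker_association")
    rec <- rec[keep_idx, , drop = FALSE]
  }
  reject(`rownames<-`(rec, NULL), drops)
}

#' Filter eQTL records by |Z| and keep the top eQTL per gene
#'
#' Retains records whose absolute Z-score is at least `threshold`
#' (inclusive; the default 5.4485 corresponds to p = 5e-8), then keeps the
#' single largest-|Z| record per trait.
#'
#' @param records A QTL record data.frame whose `strength` column holds
#'   Z-scores.
#' @param threshold Minimum |Z| (default 5.4485).
#' @return Retained records with `attr(,"rejected")`.
#' @export
filter_eqtl_zscore <- function(records, threshold = 5.4485) {
  stopifnot(all(c("trait", "strength") %in% names(records)))
  drops <- list()
  weak <- abs(records$strength) < threshold
  drops$weak <- with_reason(records[weak, , drop = FALSE],
                            "below_zscore_threshold")
  rec <- records[!weak, , drop = FALSE]
  if (nrow(rec) > 0L) {
    d <- record_distance(rec)
    pos <- if ("variant_pos" %in% names(rec)) rec$variant_pos else
      seq_len(nrow(rec))
    ord <- order(rec$trait, -abs(rec$strength), d, pos)
    keep_idx <- sort(ord[!duplicated(rec$trait[ord])])
    drops$weaker <- with_reason(rec[-keep_idx, , drop = FALSE],
                                "weaker_association")
    rec <- rec[keep_idx, , drop = FALSE]
  }
  reject(`rownames<-`(rec, NULL), drops)
}

#' Metabolite QTLs with a single interacting gene per chromosome
#'
#' For each (metabolite, chromosome) pair with *exactly one* interacting
#' gene on that chromosome in the supplied map, keeps the strongest
#' (smallest p-value) association of that metabolite on that chromosome,
#' provided p is strictly below `p_max`. Gene coordinates are joined from
#' the map and the variant-TSS distance computed.
#'
#' @param records Data.frame with `trait` (metabolite id), `variant_chrom`,
#'   `variant_pos` and `pvalue`.
#' @param gene_map Data.frame with `trait`, `gene`, `gene_chrom`,
#'   `gene_tss`: the metabolite-to-interacting-gene table (e.g. from a
#'   metabolite database export).
#' @param p_max Strict p-value ceiling (default 5e-8).
#' @return Retained records (with `gene`, `gene_chrom`, `gene_tss`, `dist`
#'   added) and `attr(,"rejected")`.
#' @export
filter_metabolite_single_gene <- function(records, gene_map,
                                          p_max = 5e-8) {
  stopifnot(all(c("trait", "variant_chrom", "variant_pos", "pvalue") %in%
                  names(records)),
            all(c("trait", "gene", "gene_chrom", "gene_tss") %in%
                  names(gene_map)))
  drops <- list()
  unmapped <- !(records$trait %in% gene_map$trait)
  if (any(unmapped)) {
    warning(sum(unmapped), " record(s) for metabolites absent from the ",
            "interacting-gene map dropped")
  }
  drops$unmapped <- with_reason(records[unmapped, , drop = FALSE],
                                "metabolite_not_in_map")
  rec <- records[!unmapped, , drop = FALSE]

  map_key <- paste(gene_map$trait, gene_map$gene_chrom, sep = "\r")
  genes_per <- table(map_key)
  rec_key <- paste(rec$trait, rec$variant_chrom, sep = "\r")
  n_genes <- as.integer(genes_per[rec_key])
  n_genes[is.na(n_genes)] <- 0L
  bad <- n_genes != 1L
  drops$multi <- with_reason(rec[bad, , drop = FALSE],
                             "not_single_interacting_gene")
  rec <- rec[!bad, , drop = FALSE]

  if (nrow(rec) > 0L) {
    rec_key <- paste(rec$trait, rec$variant_chrom, sep = "\r")
    ord <- order(rec_key, rec$pvalue, rec$variant_pos)
    keep_idx <- sort(ord[!duplicated(rec_key[ord])])
    drops$weaker <- with_reason(rec[-keep_idx, , drop = FALSE],
                                "weaker_association")
    rec <- rec[keep_idx, , drop = FALSE]
    insig <- !(rec$pvalue < p_max)  # strict inequality
    drops$insig <- with_reason(rec[insig, , drop = FALSE],
                               "p_value_not_below_threshold")
    rec <- rec[!insig, , drop = FALSE]
    if (nrow(rec) > 0L) {
      mi <- match(paste(rec$trait, rec$variant_chrom, sep = "\r"), map_key)
      rec$gene <- gene_map$gene[mi]
      rec$gene_chrom <- gene_map$gene_chrom[mi]
      rec$gene_tss <- gene_map$gene_tss[mi]
      rec$dist <- abs(rec$variant_pos - rec$gene_tss)
    }
  }
  reject(`rownames<-`(rec, NULL), drops)
}

#' Derive the canonical distance table
#'
#' Computes the variant-TSS distance as the absolute base-pair difference
#' between variant position and TSS; records with a precomputed `dist`
#' column pass through unchanged. Records with neither are rejected with a
#' reason code.
#'
#' @param records A QTL record data.frame.
#' @return Data.frame with columns `trait`, `chrom`, `dist` and (when
#'   available) `strength` — the canonical shape consumed by
#'   [cistrans_fit()] — with `attr(,"rejected")`.
#' @export
compute_distances <- function(records) {
  stopifnot("trait" %in% names(records))
  has_pre <- if ("dist" %in% names(records)) !is.na(records$dist) else
    rep(FALSE, nrow(records))
  has_pos <- if (all(c("variant_pos", "gene_tss") %in% names(records))) {
    !is.na(records$variant_pos) & !is.na(records$gene_tss)
  } else rep(FALSE, nrow(records))
  bad <- !has_pre & !has_pos
  drops <- list(bad = with_reason(records[bad, , drop = FALSE],
                                  "no_distance_information"))
  rec <- records[!bad, , drop = FALSE]
  keep_pre <- has_pre[!bad]
  d <- numeric(nrow(rec))
  d[keep_pre] <- rec$dist[keep_pre]
  if (any(!keep_pre)) {
    d[!keep_pre] <- abs(rec$variant_pos[!keep_pre] -
                          rec$gene_tss[!keep_pre])
  }
  chrom <- if ("variant_chrom" %in% names(rec)) rec$variant_chrom else
    NA_character_
  out <- data.frame(trait = rec$trait, chrom = chrom, dist = d,
                    stringsAsFactors = FALSE)
  if ("strength" %in% names(rec)) out$strength <- rec$strength
  reject(out, drops)
}

#' Read a study summary table through a column-mapping schema
#'
#' Study tables differ only in column names and separators; a small schema
#' (a YAML file or a list) maps source columns onto the canonical record
#' fields, so supporting a new study needs no code change. Schema fields:
#' `columns` (named list, canonical name -> source column name) and
#' optional `sep` (default tab).
#'
#' @param path Path to the headered study table (TSV/CSV).
#' @param schema Path to a YAML schema file, or an equivalent list.
#' @return A QTL record data.frame with canonical column names; unmapped
#'   source columns are passed through untouched.
#' @export
read_study_table <- function(path, schema) {
  if (is.character(schema)) schema <- yaml::read_yaml(schema)
  sep <- if (is.null(schema$sep)) "\t" else schema$sep
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  cols <- schema$columns
  missing <- setdiff(unlist(cols), names(tab))
  if (length(missing)) {
    stop("schema refers to column(s) absent from the table: ",
         paste(missing, collapse = ", "))
  }
  for (canon in names(cols)) {
    src <- cols[[canon]]
    if (src != canon) {
      tab[[canon]] <- tab[[src]]
      tab[[src]] <- NULL
    }
  }
  tab
}
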