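# Independent brute-force oracles used to pin down the analytic code paths.

# Enumerate all ordered same-chromosome position pairs (i, j), i != j, on
# integer positions 1..N per chromosome; tally counts per distance.
enum_pair_counts <- function(lengths) {
  counts <- integer(max(lengths) - 1L)
  for (N in lengths) {
    for (i in seq_len(N)) {
      for (j in seq_len(N)) {
        d <- abs(i - j)
        if (d > 0L) counts[d] <- counts[d] + 1L
      }
    }
  }
  counts
}

enum_pair_pmf <- function(lengths) {
  counts <- enum_pair_counts(lengths)
  counts / sum(counts)
}

enum_tail <- function(lengths, x) {
  counts <- enum_pair_counts(lengths)
  sum(counts[seq_along(counts) > x]) / sum(counts)
}

# per-record binning loop (no vectorization), left-edge labels
brute_bin <- function(distances, w = 0.25) {
  ks <- integer(0)
  for (d in distances) {
    if (d >= 1) ks <- c(ks, floor(log10(d) / w + 1e-9))
  }
  kr <- min(ks):max(ks)
  counts <- integer(length(kr))
  for (k in ks) counts[k - kr[1] + 1L] <- counts[k - kr[1] + 1L] + 1L
  list(labels = kr * w, counts = counts)
}

# textbook one-sample KS statistic
ks_stat_hand <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  Fx <- cdf(x)
  max(pmax(seq_len(n) / n - Fx, Fx - (seq_len(n) - 1) / n))
}

# group-by/argmax loop oracle for the primary intrachromosomal filter
# (records without rank columns; strength maximization, dist then pos ties)
brute_primary_filter <- function(records) {
  keep <- integer(0)
  for (tr in unique(records$trait)) {
    idx <- which(records$trait == tr &
                   records$variant_chrom == records$gene_chrom)
    if (length(idx) == 0L) next
    d <- abs(records$variant_pos[idx] - records$gene_tss[idx])
    s <- abs(records$strength[idx])
    ord <- order(-s, d, records$variant_pos[idx])
    keep <- c(keep, idx[ord[1]])
  }
  records[sort(keep), , drop = FALSE]
}

toy_model <- function(lengths, names = LETTERS[seq_along(lengths)]) {
  trans_model(chromosome_set(names, lengths))
}

extdata <- function(f) system.file("extdata", f, package = "cistrans")
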