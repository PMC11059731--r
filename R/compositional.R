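#' Prevalence/abundance filter for features
#'
#' Keeps a feature iff it reaches at least `min_count` reads in at least
#' `ceiling(min_prevalence * n_samples)` samples. The defaults implement the
#' usual amplicon rule of requiring at least 2 reads in at least 5% of
#' samples. Idempotent; samples are never dropped here.
#'
#' @param counts count matrix (samples x features).
#' @param min_count minimum reads for a sample to qualify (default 2).
#' @param min_prevalence minimum fraction of qualifying samples (default 0.05).
#' @param quiet suppress the retained-feature message.
#' @return filtered count matrix.
#' @export
filter_taxa <- function(counts, min_count = 2, min_prevalence = 0.05,
                        quiet = FALSE) {
  validate_count_table(counts)
  if (!(min_prevalence > 0 && min_prevalence <= 1)) {
    stop_("min_prevalence must lie in (0, 1]")
  }
  need <- ceiling(min_prevalence * nrow(counts))
  keep <- colSums(counts >= min_count) >= need
  if (!any(keep)) {
    warning("all features removed by the prevalence filter", call. = FALSE)
  }
  if (!quiet) {
    message(sprintf("filter_taxa: kept %d / %d features (>= %d reads in >= %d samples)",
                    sum(keep), ncol(counts), min_count, need))
  }
  counts[, keep, drop = FALSE]
}

#' Read-depth filter for samples
#'
#' Keeps a sample iff its library size (row sum) is at least `min_depth`;
#' samples at exactly the boundary are kept (the exclusion rule is N < 2000).
#'
#' @param counts count matrix (samples x features).
#' @param min_depth minimum library size (default 2000 reads).
#' @param quiet suppress the log message.
#' @return filtered count matrix.
#' @export
filter_samples <- function(counts, min_depth = 2000, quiet = FALSE) {
  validate_count_table(counts)
  keep <- rowSums(counts) >= min_depth
  if (!any(keep)) {
    warning("all samples removed by the depth filter", call. = FALSE)
  }
  if (!quiet) {
    message(sprintf("filter_samples: kept %d / %d samples (depth >= %d)",
                    sum(keep), nrow(counts), min_depth))
  }
  counts[keep, , drop = FALSE]
}

#' Agglomerate features to a taxonomic rank
#'
#' Features sharing the same lineage down to `rank` are summed; per-sample
#' totals are conserved exactly (integer arithmetic). Output feature ids are
#' lineage strings from domain down to `rank`, joined by `";"`.
#'
#' @param counts count matrix (samples x features).
#' @param taxonomy taxonomy data.frame covering every feature in `counts`.
#' @param rank one of `"domain"`..`"genus"` or `"asv"` (identity).
#' @return agglomerated count matrix.
#' @export
agglomerate <- function(counts, taxonomy,
                        rank = c("genus", "order", "class", "family",
                                 "phylum", "domain", "asv")) {
  rank <- match.arg(rank)
  validate_count_table(counts)
  if (rank == "asv") return(counts)
  miss <- setdiff(colnames(counts), taxonomy$feature_id)
  if (length(miss) > 0) {
    stop_("feature(s) missing from taxonomy: ",
          paste(head(miss, 5), collapse = ", "),
          if (length(miss) > 5) sprintf(" (+%d more)", length(miss) - 5))
  }
  idx <- match(colnames(counts), taxonomy$feature_id)
  upto <- TAX_RANKS[seq_len(match(rank, TAX_RANKS))]
  lineage <- do.call(paste, c(lapply(upto, function(r) taxonomy[[r]][idx]),
                              sep = ";"))
  agg <- t(rowsum(t(counts), group = lineage))
  storage.mode(agg) <- storage.mode(counts)
  validate_count_table(agg)
  agg
}

#' Relative abundances
#'
#' @param counts count matrix with strictly positive row sums.
#' @return matrix of per-sample proportions (rows sum to 1).
#' @export
relative_abundance <- function(counts) {
  totals <- rowSums(counts)
  if (any(totals <= 0)) {
    stop_("zero-sum sample row(s): ",
          paste(rownames(counts)[totals <= 0], collapse = ", "),
          " - remove them with filter_samples() first")
  }
  counts / totals
}

#' Centered log-ratio transform with pseudo-counts
#'
#' Counts are converted to relative abundances; zeros are replaced by a
#' pseudo-count delta equal to half the smallest nonzero relative abundance in
#' the whole matrix (a single delta for all cells preserves perturbation
#' invariance across samples); each row is then mapped to
#' `clr(x)_j = ln x_j - mean_k ln x_k`. Rows are not re-closed after the zero
#' replacement: the log-mean centering absorbs the closure constant, so
#' re-closure would only rescale every entry of a row identically.
#'
#' @param counts count matrix (samples x features); relative-abundance
#'   matrices are accepted too.
#' @param pseudocount `"half_min_rel"` (default) or an explicit positive value
#'   used as delta on the relative-abundance scale.
#' @param per_sample if `TRUE`, delta is half the per-row minimum nonzero
#'   relative abundance instead of the global one.
#' @return CLR matrix; rows sum to zero. The delta used is attached as
#'   attribute `"pseudocount"`.
#' @export
clr_transform <- function(counts, pseudocount = "half_min_rel",
                          per_sample = FALSE) {
  if (any(rowSums(counts) <= 0)) {
    stop_("all-zero sample row(s): ",
          paste(rownames(counts)[rowSums(counts) <= 0], collapse = ", "))
  }
  rel <- counts / rowSums(counts)
  if (identical(pseudocount, "half_min_rel")) {
    if (per_sample) {
      delta <- apply(rel, 1, function(r) min(r[r > 0]) / 2)
      rel <- rel + 0 # copy
      for (i in seq_len(nrow(rel))) rel[i, rel[i, ] == 0] <- delta[i]
    } else {
      delta <- min(rel[rel > 0]) / 2
      rel[rel == 0] <- delta
    }
  } else {
    if (!is.numeric(pseudocount) || pseudocount <= 0) {
      stop_("pseudocount must be 'half_min_rel' or a positive number")
    }
    delta <- pseudocount
    rel[rel == 0] <- delta
  }
  lx <- log(rel)
  clr <- lx - rowMeans(lx)
  attr(clr, "pseudocount") <- delta
  clr
}

#' Aitchison distances
#'
#' Euclidean distances between CLR-transformed samples.
#'
#' @param clr CLR matrix as returned by [clr_transform()].
#' @return symmetric distance matrix with zero diagonal and sample dimnames.
#' @export
aitchison_distance <- function(clr) {
  if (anyNA(clr) || any(!is.finite(clr))) stop_("CLR matrix has non-finite values")
  as.matrix(dist(clr, method = "euclidean"))
}
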