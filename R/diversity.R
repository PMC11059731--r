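#' Rarefy a count vector without replacement
#'
#' Draws a multivariate-hypergeometric subsample of exactly `depth` reads:
#' `depth` read indices are sampled without replacement from the pooled reads
#' and mapped back to features, so every rarefied count is bounded by the
#' original and the row sum equals `depth`.
#'
#' @param x non-negative integer count vector.
#' @param depth number of reads to keep; must not exceed `sum(x)`.
#' @param seed optional seed for this single draw.
#' @return rarefied count vector (same names/length as `x`).
#' @export
rarefy <- function(x, depth, seed = NULL) {
  if (any(x < 0) || any(x != round(x))) stop_("counts must be non-negative integers")
  total <- sum(x)
  if (depth > total) {
    stop_(sprintf("rarefaction depth %d exceeds the library size %d", depth, total))
  }
  out <- x
  out[] <- 0L
  if (depth == 0) return(out)
  draw <- with_seed(seed, sample.int(total, depth))
  hits <- tabulate(findInterval(draw, cumsum(x), left.open = TRUE) + 1L,
                   nbins = length(x))
  out[] <- hits
  out
}

#' Alpha diversity indices
#'
#' `shannon()` is the natural-log Shannon index `H' = -sum p ln p`;
#' `observed_features()` counts nonzero features; `pielou()` is the evenness
#' `J' = H'/ln S`, undefined (returned as `NA` with a warning) when only one
#' feature is present.
#'
#' @param x non-negative count (or abundance) vector with positive sum.
#' @return scalar index value.
#' @export
shannon <- function(x) {
  if (sum(x) <= 0) stop_("Shannon index needs a positive total")
  unname(vegan::diversity(rbind(x), index = "shannon"))
}

#' @rdname shannon
#' @export
observed_features <- function(x) {
  as.integer(vegan::specnumber(rbind(x)))
}

#' @rdname shannon
#' @export
pielou <- function(x) {
  s <- observed_features(x)
  if (s < 2) {
    warning("Pielou's evenness is undefined for a single feature", call. = FALSE)
    return(NA_real_)
  }
  shannon(x) / log(s)
}

#' Repeated-rarefaction alpha diversity
#'
#' For every sample, draws `n_repeats` seeded rarefied subsamples at `depth`
#' reads and reports the mean and standard deviation of observed richness,
#' Shannon `H'` and Pielou `J'` across the repeats. The defaults (depth 2000,
#' 100 repeats) match the standard protocol for unevenly sequenced amplicon
#' libraries; diversity should be computed on the unagglomerated ASV table.
#'
#' @param counts count matrix (samples x features) with all row sums
#'   at least `depth`.
#' @param depth rarefaction depth in reads.
#' @param n_repeats number of random subsamples per sample.
#' @param seed master seed; per-draw randomness is derived from it
#'   deterministically.
#' @return data.frame (one row per sample): `sample_id`, `observed_mean/sd`,
#'   `shannon_mean/sd`, `pielou_mean/sd`, with attributes `rarefaction_depth`
#'   and `n_repeats`.
#' @export
repeated_rarefaction_diversity <- function(counts, depth = 2000,
                                           n_repeats = 100, seed = 1) {
  validate_count_table(counts)
  under <- rowSums(counts) < depth
  if (any(under)) {
    stop_("sample(s) below the rarefaction depth: ",
          paste(rownames(counts)[under], collapse = ", "),
          " - remove them with filter_samples() first")
  }
  res <- with_seed(seed, {
    t(vapply(seq_len(nrow(counts)), function(i) {
      x <- counts[i, ]
      obs <- numeric(n_repeats); sha <- numeric(n_repeats); pie <- numeric(n_repeats)
      for (r in seq_len(n_repeats)) {
        sub <- rarefy(x, depth)
        obs[r] <- observed_features(sub)
        sha[r] <- shannon(sub)
        s <- obs[r]
        pie[r] <- if (s >= 2) sha[r] / log(s) else NA_real_
      }
      c(mean(obs), sd(obs), mean(sha), sd(sha), mean(pie), sd(pie))
    }, numeric(6)))
  })
  out <- data.frame(sample_id = rownames(counts),
                    observed_mean = res[, 1], observed_sd = res[, 2],
                    shannon_mean = res[, 3], shannon_sd = res[, 4],
                    pielou_mean = res[, 5], pielou_sd = res[, 6],
                    stringsAsFactors = FALSE)
  attr(out, "rarefaction_depth") <- depth
  attr(out, "n_repeats") <- n_repeats
  out
}
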