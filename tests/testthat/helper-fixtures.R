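# shared fixtures and independent oracles, all built in code

toy_counts <- function(x, samples = NULL, features = NULL) {
  m <- as.matrix(x)
  rownames(m) <- samples %||% paste0("S", seq_len(nrow(m)))
  colnames(m) <- features %||% paste0("F", seq_len(ncol(m)))
  m
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# planted Gaussian clusters with centers at pairwise distance
# sep_mult * within_sd (orthogonal construction)
planted_clusters <- function(n = 100, p = 20, k = 5, sep_mult = 8,
                             within_sd = 1, seed = 1) {
  set.seed(seed)
  centers <- matrix(0, k, p)
  for (j in seq_len(k)) {
    centers[j, j] <- sep_mult * within_sd / sqrt(2)
  }
  labels <- sample(rep_len(seq_len(k), n))
  x <- centers[labels, ] + matrix(rnorm(n * p, 0, within_sd), n, p)
  rownames(x) <- paste0("S", seq_len(n))
  colnames(x) <- paste0("F", seq_len(p))
  list(x = x, labels = labels, centers = centers)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

make_assignment <- function(units, samples = NULL, k = max(units)) {
  structure(as.integer(units),
            names = samples %||% paste0("S", seq_along(units)),
            k_units = as.integer(k), class = "bmu_assignment")
}

# brute-force one-way PERMANOVA for two groups: enumerates every subset of
# size n1 as group 1 and computes pseudo-F with naive loops
oracle_permanova_p <- function(d, n1) {
  m <- as.matrix(d)
  n <- nrow(m)
  f_of <- function(g1) {
    g <- rep(2L, n); g[g1] <- 1L
    ss_t <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) ss_t <- ss_t + m[i, j]^2
    ss_t <- ss_t / n
    ss_w <- 0
    for (lev in 1:2) {
      idx <- which(g == lev)
      s <- 0
      if (length(idx) > 1) {
        for (a in 1:(length(idx) - 1)) for (b in (a + 1):length(idx)) {
          s <- s + m[idx[a], idx[b]]^2
        }
      }
      ss_w <- ss_w + s / length(idx)
    }
    ((ss_t - ss_w) / 1) / (ss_w / (n - 2))
  }
  subsets <- combn(n, n1)
  fs <- apply(subsets, 2, f_of)
  f_obs <- f_of(seq_len(n1))
  mean(fs >= f_obs - 1e-12)
}

write_tsv_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# minimal valid metadata for a set of samples
minimal_metadata <- function(samples, temp = NULL) {
  n <- length(samples)
  data.frame(sample_id = samples,
             station = rep("ST101", n),
             depth = rep(0, n),
             month = rep("Feb", n),
             season = rep_len(c("Winter", "Summer"), n),
             layer = rep("L1", n),
             Temp = temp %||% seq(10, 20, length.out = n),
             AAP_abs = rep(1e4, n),
             stringsAsFactors = FALSE)
}
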