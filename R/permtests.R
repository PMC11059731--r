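as_dist_matrix <- function(d) {
  m <- if (inherits(d, "dist")) as.matrix(d) else as.matrix(d)
  if (nrow(m) != ncol(m)) stop_("distance matrix must be square")
  if (max(abs(m - t(m))) > 1e-8) stop_("distance matrix must be symmetric")
  m
}

check_groups <- function(groups, n) {
  g <- as.factor(groups)
  if (length(g) != n) stop_("groups length must match the distance matrix")
  g <- droplevels(g)
  sizes <- table(g)
  if (nlevels(g) < 2) stop_("need at least 2 groups")
  if (any(sizes < 2)) {
    stop_("group(s) of size 1: ", paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  g
}

# number of distinct assignments of a fixed multiset of labels to positions
n_distinct_relabelings <- function(g) {
  sizes <- as.vector(table(g))
  exp(lgamma(length(g) + 1) - sum(lgamma(sizes + 1)))
}

# all distinct arrangements of the label multiset, as an (m x n) integer matrix
multiset_permutations <- function(labels) {
  labels <- as.integer(labels)
  rec <- function(v) {
    if (length(v) == 1L) return(matrix(v))
    out <- list()
    for (x in sort(unique(v))) {
      sub <- rec(v[-match(x, v)])
      out[[length(out) + 1L]] <- cbind(x, sub, deparse.level = 0)
    }
    do.call(rbind, out)
  }
  rec(labels)
}

# Anderson's one-way pseudo-F from squared distances:
#   SS_T = (1/N) sum_{i<j} d_ij^2,  SS_W = sum_g (1/n_g) sum_{i<j in g} d_ij^2,
#   F = [(SS_T - SS_W)/(a-1)] / [SS_W/(N-a)]
pseudo_f <- function(d2, g) {
  n <- nrow(d2)
  a <- nlevels(g)
  ss_t <- sum(d2) / (2 * n)
  ss_w <- 0
  for (lev in levels(g)) {
    idx <- which(g == lev)
    ss_w <- ss_w + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
}

#' One-way PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: Anderson's pseudo-F on the
#' (typically Aitchison) distance matrix, with significance from random label
#' permutations, `p = (b + 1) / (m + 1)` for `b` exceedances among `m`
#' permutations — so p is never zero. When the number of distinct relabelings
#' is at most `exhaustive_max` the full enumeration is used instead and
#' `p` is the exact proportion of relabelings with `F >= F_obs`.
#'
#' @param d distance matrix or `dist` object.
#' @param groups factor of group labels (>= 2 groups, each with >= 2 members).
#' @param n_perm number of random permutations (default 9999).
#' @param seed seed for the permutation stream.
#' @param exhaustive_max enumeration threshold (default 10000 relabelings).
#' @return a `perm_test` list: `statistic` (pseudo-F), `p`, `n_perm`,
#'   `exhaustive`, `method`, `groups`.
#' @export
permanova_oneway <- function(d, groups, n_perm = 9999, seed = 1,
                             exhaustive_max = 10000) {
  m <- as_dist_matrix(d)
  g <- check_groups(groups, nrow(m))
  d2 <- m^2
  f_obs <- pseudo_f(d2, g)
  n_distinct <- n_distinct_relabelings(g)
  if (n_distinct <= exhaustive_max) {
    relab <- multiset_permutations(as.integer(g))
    relab <- unique(relab)
    fs <- apply(relab, 1, function(lab) {
      pseudo_f(d2, factor(lab, levels = seq_len(nlevels(g))))
    })
    p <- mean(fs >= f_obs - 1e-12)
    result <- list(statistic = f_obs, p = p, n_perm = nrow(relab),
                   exhaustive = TRUE)
  } else {
    fs <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        pseudo_f(d2, g[sample.int(length(g))])
      }, numeric(1))
    })
    b <- sum(fs >= f_obs - 1e-12)
    p <- (b + 1) / (n_perm + 1)
    result <- list(statistic = f_obs, p = p, n_perm = n_perm,
                   exhaustive = FALSE)
  }
  structure(c(result,
              list(method = "PERMANOVA (one-way, pseudo-F)",
                   groups = levels(g))),
            class = "perm_test")
}

# Principal-coordinate embedding of a distance matrix, split into real
# (positive-eigenvalue) and imaginary (negative-eigenvalue) axes.
pcoa_axes <- function(m) {
  a <- -0.5 * m^2
  g <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-8
  pos <- e$values > tol
  neg <- e$values < -tol
  list(
    real = e$vectors[, pos, drop = FALSE] %*%
      diag(sqrt(e$values[pos]), sum(pos)),
    imag = e$vectors[, neg, drop = FALSE] %*%
      diag(sqrt(-e$values[neg]), sum(neg))
  )
}

anova_f <- function(z, g) {
  n <- length(z); a <- nlevels(g)
  gm <- mean(z)
  means <- tapply(z, g, mean)
  sizes <- tabulate(g, nbins = a)
  ssb <- sum(sizes * (means - gm)^2)
  ssw <- sum((z - means[g])^2)
  (ssb / (a - 1)) / (ssw / (n - a))
}

#' PERMDISP: homogeneity of multivariate dispersions
#'
#' Embeds the distance matrix by principal coordinates, computes each sample's
#' deviation from its group centroid — with the standard correction combining
#' real and imaginary axes, `z_i = sqrt(max(0, d_real^2 - d_imag^2))` — and
#' tests the one-way ANOVA F of the deviations by permuting their group
#' labels. A significant result indicates groups differ in dispersion.
#'
#' @inheritParams permanova_oneway
#' @return a `perm_test` list with the dispersion F statistic, the per-sample
#'   `deviations`, and the permutation p-value `(b + 1)/(m + 1)`.
#' @export
permdisp <- function(d, groups, n_perm = 9999, seed = 1) {
  m <- as_dist_matrix(d)
  g <- check_groups(groups, nrow(m))
  ax <- pcoa_axes(m)
  z <- numeric(nrow(m))
  for (lev in levels(g)) {
    idx <- which(g == lev)
    c_real <- colMeans(ax$real[idx, , drop = FALSE])
    d2_real <- rowSums(sweep(ax$real[idx, , drop = FALSE], 2, c_real)^2)
    d2_imag <- 0
    if (ncol(ax$imag) > 0) {
      c_imag <- colMeans(ax$imag[idx, , drop = FALSE])
      d2_imag <- rowSums(sweep(ax$imag[idx, , drop = FALSE], 2, c_imag)^2)
    }
    z[idx] <- sqrt(pmax(0, d2_real - d2_imag))
  }
  f_obs <- anova_f(z, g)
  fs <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      anova_f(z, g[sample.int(length(g))])
    }, numeric(1))
  })
  b <- sum(fs >= f_obs - 1e-12)
  structure(list(statistic = f_obs, p = (b + 1) / (n_perm + 1),
                 n_perm = n_perm, exhaustive = FALSE,
                 method = "PERMDISP (deviations from centroid)",
                 groups = levels(g), deviations = z),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  groups: %s\n", paste(x$groups, collapse = ", ")))
  cat(sprintf("  statistic F = %.4f, p = %.4g (%s, %d permutations)\n",
              x$statistic, x$p,
              if (x$exhaustive) "exhaustive" else "sampled", x$n_perm))
  invisible(x)
}
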