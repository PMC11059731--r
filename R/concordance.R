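#' Metabarcoding pseudoabundance
#'
#' Converts a group's metabarcoding relative abundance (percent) into an
#' absolute estimate on the microscopy scale:
#' `pseudoabundance = rel_pct * aap_abs / 100` (cells/mL).
#'
#' @param rel_pct relative abundance in percent, in `[0, 100]`.
#' @param aap_abs total AAP absolute abundance (cells/mL), non-negative.
#' @return pseudoabundance in cells/mL (vectorized).
#' @export
pseudoabundance <- function(rel_pct, aap_abs) {
  if (any(rel_pct < -1e-9 | rel_pct > 100 + 1e-9, na.rm = TRUE)) {
    stop_("rel_pct must lie in [0, 100]")
  }
  if (any(aap_abs < 0, na.rm = TRUE)) stop_("aap_abs must be non-negative")
  rel_pct * aap_abs / 100
}

# all permutations of 1..n as an (n! x n) integer matrix
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations_of(n - 1L)
  m <- nrow(sub)
  out <- matrix(0L, n * m, n)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * m + 1L):(i * m)
    out[rows, 1L] <- i
    rest <- setdiff(seq_len(n), i)
    out[rows, -1L] <- matrix(rest[sub], m)
  }
  out
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' rho is computed on average ranks (ties handled). The two-sided p-value is
#' exact by full enumeration of the `n!` orderings for `n <= 9` and uses the
#' t approximation `t = rho * sqrt((n-2)/(1-rho^2))` otherwise. Missing values
#' are dropped pairwise.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `rho`, `p`, `n` (complete pairs) and `method`
#'   (`"exact"` or `"t-approximation"`).
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop_("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop_("need at least 3 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("Spearman correlation undefined for a constant vector",
            call. = FALSE)
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= 9) {
    perms <- permutations_of(n)
    sx <- sd(rx); sy <- sd(ry); mx <- mean(rx); my <- mean(ry)
    sums <- as.vector(matrix(ry[perms], nrow(perms)) %*% rx)
    rhos <- (sums / n - mx * my) * n / ((n - 1) * sx * sy)
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t-approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

#' Default FISH probe to pufM taxon mapping
#'
#' GAM42a targets the Gammaproteobacteria class, ALF968 the Alphaproteobacteria
#' class, and ROS537 the Roseobacter clade, equated here with the order
#' Rhodobacterales (which holds nearly all alphaproteobacterial AAP reads in
#' marine pufM surveys). The mapping is configuration: pass your own when the
#' equation does not hold for your data.
#'
#' @return named list of `list(probe, rank, taxon)` entries.
#' @export
default_concordance_mapping <- function() {
  list(
    Gammaproteobacteria = list(probe = "GAM42a", rank = "class",
                               taxon = "Gammaproteobacteria"),
    Alphaproteobacteria = list(probe = "ALF968", rank = "class",
                               taxon = "Alphaproteobacteria"),
    Roseobacter = list(probe = "ROS537", rank = "order",
                       taxon = "Rhodobacterales")
  )
}

#' FISH-IR vs metabarcoding concordance
#'
#' For each probe group, computes the metabarcoding pseudoabundance
#' (group relative abundance x AAP absolute abundance / 100) and its Spearman
#' correlation with the FISH-IR measurement. By default the FISH side is put
#' on the same absolute scale (`fish_pct * AAP_abs / 100`, i.e. probe counts
#' in cells/mL); `fish_scale = "percent"` correlates the raw percentages
#' instead.
#'
#' @param counts count matrix (samples x ASVs), typically after filtering.
#' @param taxonomy taxonomy table covering the counts.
#' @param metadata metadata with `AAP_abs` and the `fish_*` columns.
#' @param mapping probe/taxon mapping, see [default_concordance_mapping()].
#' @param fish_scale `"counts"` (default) or `"percent"`.
#' @return data.frame with one row per group: `group, probe, rho, p, n,
#'   method`.
#' @export
concordance <- function(counts, taxonomy, metadata,
                        mapping = default_concordance_mapping(),
                        fish_scale = c("counts", "percent")) {
  fish_scale <- match.arg(fish_scale)
  rows <- match(rownames(counts), metadata$sample_id)
  if (anyNA(rows)) {
    stop_("sample(s) missing from metadata: ",
          paste(rownames(counts)[is.na(rows)], collapse = ", "))
  }
  aap <- metadata$AAP_abs[rows]
  out <- lapply(names(mapping), function(group) {
    m <- mapping[[group]]
    agg <- agglomerate(counts, taxonomy, rank = m$rank)
    leaf <- vapply(strsplit(colnames(agg), ";", fixed = TRUE),
                   function(v) v[length(v)], "")
    j <- which(leaf == m$taxon)
    if (length(j) != 1) {
      stop_(sprintf("taxon '%s' not found at rank '%s'", m$taxon, m$rank))
    }
    rel_pct <- 100 * relative_abundance(agg)[, j]
    pseudo <- pseudoabundance(rel_pct, aap)
    fish_col <- paste0("fish_", m$probe)
    if (!fish_col %in% names(metadata)) {
      stop_("metadata lacks column ", fish_col)
    }
    fish <- metadata[[fish_col]][rows]
    if (fish_scale == "counts") fish <- fish * aap / 100
    s <- spearman_cor(fish, pseudo)
    data.frame(group = group, probe = m$probe, rho = s$rho, p = s$p,
               n = s$n, method = s$method, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
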