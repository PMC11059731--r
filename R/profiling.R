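new_bmu_profile <- function(k, member_ids) {
  structure(list(k_units = k, member_ids = member_ids,
                 env_means = NULL, env_n = NULL, taxon_means = NULL),
            class = "bmu_profile")
}

profile_skeleton <- function(assignment) {
  k <- attr(assignment, "k_units") %||% max(assignment)
  new_bmu_profile(k, bmu_members(assignment))
}

#' Per-unit environmental averages
#'
#' For every BMU, the arithmetic mean of each requested environmental variable
#' over its member samples. Missing measurements are skipped and the count of
#' contributing samples is recorded per unit and variable.
#'
#' @param assignment a `bmu_assignment`.
#' @param metadata sample metadata containing every assigned sample.
#' @param variables variable names to average (default: the standard abiotic +
#'   biotic panel present in the metadata).
#' @param profile optional existing `bmu_profile` to extend.
#' @return a `bmu_profile` with `env_means` (units x variables) and `env_n`.
#' @export
profile_environment <- function(assignment, metadata,
                                variables = intersect(ENV_VARIABLES,
                                                      names(metadata)),
                                profile = NULL) {
  miss <- setdiff(names(assignment), metadata$sample_id)
  if (length(miss) > 0) {
    stop_("assigned sample(s) missing from metadata: ",
          paste(miss, collapse = ", "))
  }
  unknown <- setdiff(variables, names(metadata))
  if (length(unknown) > 0) {
    numeric_cols <- names(metadata)[vapply(metadata, is.numeric, logical(1))]
    stop_("unknown variable(s): ", paste(unknown, collapse = ", "),
          "; available numeric variables: ",
          paste(setdiff(numeric_cols, "depth"), collapse = ", "))
  }
  profile <- profile %||% profile_skeleton(assignment)
  k <- profile$k_units
  rows <- match(names(assignment), metadata$sample_id)
  env_means <- matrix(NA_real_, k, length(variables),
                      dimnames = list(paste0("U", seq_len(k)), variables))
  env_n <- matrix(0L, k, length(variables),
                  dimnames = dimnames(env_means))
  for (u in seq_len(k)) {
    sel <- rows[unclass(assignment) == u]
    for (v in variables) {
      vals <- metadata[[v]][sel]
      env_n[u, v] <- sum(!is.na(vals))
      if (env_n[u, v] > 0) env_means[u, v] <- mean(vals, na.rm = TRUE)
    }
  }
  profile$env_means <- env_means
  profile$env_n <- env_n
  profile
}

#' Per-unit average CLR taxon values
#'
#' The BMU-wise mean CLR value of every taxon: the machine-readable form of
#' the "relative contribution of taxa to each characteristic environment"
#' heatmaps.
#'
#' @param assignment a `bmu_assignment`.
#' @param clr CLR matrix covering every assigned sample.
#' @param profile optional existing `bmu_profile` to extend.
#' @return a `bmu_profile` with `taxon_means` (units x taxa).
#' @export
profile_taxa <- function(assignment, clr, profile = NULL) {
  miss <- setdiff(names(assignment), rownames(clr))
  if (length(miss) > 0) {
    stop_("assigned sample(s) missing from the CLR matrix: ",
          paste(miss, collapse = ", "))
  }
  profile <- profile %||% profile_skeleton(assignment)
  k <- profile$k_units
  taxon_means <- matrix(NA_real_, k, ncol(clr),
                        dimnames = list(paste0("U", seq_len(k)),
                                        colnames(clr)))
  for (u in seq_len(k)) {
    sel <- names(assignment)[unclass(assignment) == u]
    if (length(sel) > 0) {
      taxon_means[u, ] <- colMeans(clr[sel, , drop = FALSE])
    }
  }
  profile$taxon_means <- taxon_means
  profile
}

#' Full BMU profile
#'
#' Convenience wrapper building the environmental and taxon parts in one call;
#' a diversity table can be joined (by `sample_id`) so that per-unit mean
#' richness, Shannon and Pielou values appear alongside the environmental
#' averages.
#'
#' @param assignment a `bmu_assignment`.
#' @param metadata sample metadata (optional).
#' @param clr CLR matrix (optional).
#' @param diversity output of [repeated_rarefaction_diversity()] (optional).
#' @param variables environmental variables to average.
#' @return a `bmu_profile`.
#' @export
bmu_profile <- function(assignment, metadata = NULL, clr = NULL,
                        diversity = NULL,
                        variables = intersect(ENV_VARIABLES, names(metadata))) {
  profile <- profile_skeleton(assignment)
  if (!is.null(metadata)) {
    if (!is.null(diversity)) {
      div <- diversity[, c("sample_id", "observed_mean", "shannon_mean",
                           "pielou_mean")]
      metadata <- merge(metadata, div, by = "sample_id", all.x = TRUE,
                        sort = FALSE)
      variables <- c(variables, "observed_mean", "shannon_mean", "pielou_mean")
    }
    profile <- profile_environment(assignment, metadata, variables, profile)
  }
  if (!is.null(clr)) profile <- profile_taxa(assignment, clr, profile)
  profile
}

#' @export
print.bmu_profile <- function(x, ...) {
  cat(sprintf("BMU profile: %d units (%s members)\n", x$k_units,
              paste(lengths(x$member_ids), collapse = "/")))
  if (!is.null(x$env_means)) {
    cat("  environmental variables:", ncol(x$env_means), "\n")
  }
  if (!is.null(x$taxon_means)) cat("  taxa:", ncol(x$taxon_means), "\n")
  invisible(x)
}

#' Long-format profile table for heatmap rendering
#'
#' Flattens a `bmu_profile` to rows `(unit, kind, name, mean, n)` with
#' `kind` in `{env, taxon}`, sorted deterministically (unit, kind, name), and
#' optionally writes it as TSV. Empty units appear with `n = 0` and `NA` mean.
#'
#' @param profile a `bmu_profile`.
#' @param path output TSV path, or `NULL` to only return the data.frame.
#' @return the long-format data.frame, invisibly when `path` is given.
#' @export
export_heatmap_table <- function(profile, path = NULL) {
  pieces <- list()
  if (!is.null(profile$env_means)) {
    pieces$env <- data.frame(
      unit = rep(rownames(profile$env_means), ncol(profile$env_means)),
      kind = "env",
      name = rep(colnames(profile$env_means), each = nrow(profile$env_means)),
      mean = as.vector(profile$env_means),
      n = as.vector(profile$env_n),
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(profile$taxon_means)) {
    members <- lengths(profile$member_ids)
    pieces$taxon <- data.frame(
      unit = rep(rownames(profile$taxon_means), ncol(profile$taxon_means)),
      kind = "taxon",
      name = rep(colnames(profile$taxon_means),
                 each = nrow(profile$taxon_means)),
      mean = as.vector(profile$taxon_means),
      n = rep(members, ncol(profile$taxon_means)),
      stringsAsFactors = FALSE
    )
  }
  if (length(pieces) == 0) stop_("profile has neither env nor taxon part")
  out <- do.call(rbind, pieces)
  out <- out[order(out$unit, out$kind, out$name, method = "radix"), ]
  rownames(out) <- NULL
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
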