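#' Validate a count table
#'
#' A count table is a plain numeric matrix with samples as rows and features
#' (ASVs or agglomerated taxa) as columns, unique non-empty dimnames and
#' non-negative integral entries.
#'
#' @param counts matrix to validate.
#' @return the validated matrix, invisibly unchanged.
#' @export
validate_count_table <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop_("count table must be a numeric matrix (samples x features)")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_("count table needs sample rownames and feature colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    stop_("duplicated sample ids: ",
          paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    stop_("duplicated feature ids: ",
          paste(unique(colnames(counts)[duplicated(colnames(counts))]),
                collapse = ", "))
  }
  if (any(!nzchar(rownames(counts))) || any(!nzchar(colnames(counts)))) {
    stop_("empty sample or feature identifier")
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop_(sprintf(
      "invalid count at sample '%s', feature '%s': %s (counts must be non-negative integers; %d offending cell(s))",
      rownames(counts)[i], colnames(counts)[j],
      format(counts[i, j]), nrow(bad)))
  }
  invisible(counts)
}

#' Read a count table from a tab-separated file
#'
#' The canonical file layout has taxa as rows: first column the feature id,
#' remaining columns one per sample (this is how amplicon feature tables are
#' usually shipped). `orientation = "samples"` accepts the transposed layout.
#' Internally counts are always held samples-as-rows.
#'
#' @param path file to read.
#' @param orientation `"taxa"` (default; features as file rows) or
#'   `"samples"` (samples as file rows).
#' @param sep field separator; tab by default, `","` accepted for CSV.
#' @return validated count matrix, samples as rows.
#' @export
read_count_table <- function(path, orientation = c("taxa", "samples"),
                             sep = "\t") {
  orientation <- match.arg(orientation)
  raw <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character")
  if (ncol(raw) < 2) stop_("count table file needs an id column plus data")
  ids <- raw[[1]]
  mat <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat),
                                 dimnames = list(ids, colnames(mat))))
  nas <- which(is.na(num) & !is.na(mat), arr.ind = TRUE)
  if (nrow(nas) > 0 || anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)
    stop_(sprintf("non-numeric or missing count at file row '%s', column '%s'",
                  rownames(num)[bad[1, 1]], colnames(num)[bad[1, 2]]))
  }
  if (orientation == "taxa") num <- t(num)
  validate_count_table(num)
  num
}

#' Write a count table to a tab-separated file
#'
#' Emits the canonical taxa-as-rows layout with feature rows sorted
#' lexicographically so that outputs are diffable; `read_count_table()` of the
#' result reproduces the table (up to that stable feature order).
#'
#' @param counts validated count matrix (samples as rows).
#' @param path output file.
#' @param id_column header for the feature-id column.
#' @export
write_count_table <- function(counts, path, id_column = "feature_id") {
  validate_count_table(counts)
  ord <- order(colnames(counts), method = "radix")
  out <- t(counts[, ord, drop = FALSE])
  df <- data.frame(id = rownames(out), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

placeholder_fill <- function(tax) {
  # Unclassified ranks inherit a deterministic placeholder from the deepest
  # classified ancestor: e.g. a blank genus under order Rhodobacterales (with
  # blank family) becomes "o:Rhodobacterales_unclassified". Injective per
  # parent lineage because the ancestor label is embedded.
  prefix <- c(domain = "d", phylum = "p", class = "c", order = "o",
              family = "f", genus = "g")
  for (i in seq_along(TAX_RANKS)) {
    col <- TAX_RANKS[i]
    blank <- is.na(tax[[col]]) | !nzchar(trimws(tax[[col]]))
    if (!any(blank)) next
    if (i == 1L) stop_("taxonomy rows with unclassified domain are not allowed")
    parent_rank <- TAX_RANKS[i - 1L]
    parent <- tax[[parent_rank]][blank]
    # a placeholder parent keeps its own tag rather than nesting tags
    already <- grepl("_unclassified$", parent)
    lab <- ifelse(already, parent,
                  paste0(prefix[[parent_rank]], ":", parent, "_unclassified"))
    tax[[col]][blank] <- lab
  }
  tax
}

#' Read a taxonomy table
#'
#' Expects tab-separated columns `feature_id, domain, phylum, class, order,
#' family, genus`. Blank or missing ranks are filled with deterministic
#' placeholders derived from the deepest classified rank.
#'
#' @param path file to read.
#' @param sep field separator.
#' @return data.frame with one row per feature and the six rank columns.
#' @export
read_taxonomy <- function(path, sep = "\t") {
  tax <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character")
  validate_taxonomy(tax, allow_blank = TRUE)
  placeholder_fill(tax)
}

#' @rdname read_taxonomy
#' @param tax taxonomy data.frame to validate.
#' @param allow_blank whether unclassified (blank) ranks are tolerated
#'   (they are filled by the reader).
#' @export
validate_taxonomy <- function(tax, allow_blank = FALSE) {
  need <- c("feature_id", TAX_RANKS)
  missing_cols <- setdiff(need, names(tax))
  if (length(missing_cols) > 0) {
    stop_("taxonomy table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(tax$feature_id)) {
    stop_("duplicated feature ids in taxonomy: ",
          paste(unique(tax$feature_id[duplicated(tax$feature_id)]),
                collapse = ", "))
  }
  if (!allow_blank) {
    for (col in TAX_RANKS) {
      if (any(is.na(tax[[col]]) | !nzchar(trimws(tax[[col]])))) {
        stop_("taxonomy has blank entries at rank '", col, "'")
      }
    }
  }
  invisible(tax)
}

#' Write a taxonomy table
#' @param tax taxonomy data.frame.
#' @param path output file.
#' @export
write_taxonomy <- function(tax, path) {
  validate_taxonomy(tax)
  tax <- tax[order(tax$feature_id, method = "radix"), , drop = FALSE]
  write.table(tax, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a sample metadata table
#'
#' The metadata table carries the sampling design (`station`, `depth`,
#' `month`, `season`, `layer`), the abiotic and biotic environmental
#' variables, the FISH-IR relative abundances (`fish_ALF968`, `fish_GAM42a`,
#' `fish_ROS537`, % of AAP cells) and the AAP absolute abundance `AAP_abs`
#' (cells/mL). Missing environmental measurements are allowed and carried as
#' `NA`; vocabulary and range violations are reported collectively.
#'
#' @param path file to read.
#' @param sep field separator.
#' @return data.frame with `sample_id` plus the columns present in the file.
#' @export
read_metadata <- function(path, sep = "\t") {
  meta <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE)
  validate_metadata(meta)
  meta
}

#' @rdname read_metadata
#' @param meta metadata data.frame to validate.
#' @export
validate_metadata <- function(meta) {
  problems <- character(0)
  if (!"sample_id" %in% names(meta)) {
    stop_("metadata lacks a 'sample_id' column")
  }
  if (anyDuplicated(meta$sample_id)) {
    problems <- c(problems, paste0(
      "duplicated sample ids: ",
      paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", ")))
  }
  if ("season" %in% names(meta)) {
    bad <- setdiff(unique(as.character(meta$season[!is.na(meta$season)])), SEASONS)
    if (length(bad) > 0) {
      problems <- c(problems, paste0(
        "unknown season token(s): ", paste(bad, collapse = ", "),
        " (expected ", paste(SEASONS, collapse = "/"), ")"))
    }
  }
  if ("layer" %in% names(meta)) {
    bad <- setdiff(unique(as.character(meta$layer[!is.na(meta$layer)])), LAYERS)
    if (length(bad) > 0) {
      problems <- c(problems, paste0(
        "unknown layer token(s): ", paste(bad, collapse = ", "),
        " (expected ", paste(LAYERS, collapse = "/"), ")"))
    }
  }
  for (col in intersect(paste0("fish_", FISH_PROBES), names(meta))) {
    v <- meta[[col]]
    if (any(v < 0 | v > 100, na.rm = TRUE)) {
      problems <- c(problems, paste0(col, " outside [0, 100]"))
    }
  }
  for (col in intersect(c(BIOTIC_VARIABLES, "depth"), names(meta))) {
    if (any(meta[[col]] < 0, na.rm = TRUE)) {
      problems <- c(problems, paste0(col, " has negative values"))
    }
  }
  if (length(problems) > 0) {
    stop_("invalid metadata:\n  - ", paste(problems, collapse = "\n  - "))
  }
  invisible(meta)
}

#' Write a sample metadata table
#' @param meta metadata data.frame.
#' @param path output file.
#' @export
write_metadata <- function(meta, path) {
  validate_metadata(meta)
  lead <- intersect(c("sample_id", "station", "depth", "month", "season",
                      "layer"), names(meta))
  rest <- sort(setdiff(names(meta), lead), method = "radix")
  write.table(meta[, c(lead, rest), drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
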