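#' Pipeline configuration
#'
#' Describes a full analysis run: either paths to the three input tables or a
#' [sim_config()] for synthetic mode, the filter thresholds, the agglomeration
#' ranks to analyse, the neural gas settings, the diversity and permutation
#' test settings, the concordance mapping and the master seed. Stage seeds are
#' derived deterministically from the master seed, so a run is fully
#' reproducible from its configuration.
#'
#' @param counts_path,taxonomy_path,metadata_path input table paths
#'   (all three, or none in synthetic mode).
#' @param sim a [sim_config()] for synthetic mode.
#' @param min_count,min_prevalence feature filter, see [filter_taxa()].
#' @param min_depth sample filter, see [filter_samples()].
#' @param ranks agglomeration ranks to run (default order, genus, asv).
#' @param ng_settings neural gas settings ([ng_config()]); its seed is
#'   overridden per rank from the master seed.
#' @param rarefaction_depth,n_rarefactions diversity settings.
#' @param permanova_factor metadata column tested by PERMANOVA/PERMDISP
#'   (default `"season"`); set `NULL` to skip.
#' @param n_perm permutations for the tests.
#' @param concordance_mapping see [default_concordance_mapping()]; `NULL`
#'   skips the concordance stage.
#' @param fish_scale FISH side of the concordance, see [concordance()].
#' @param outdir output directory.
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(counts_path = NULL, taxonomy_path = NULL,
                            metadata_path = NULL, sim = NULL,
                            min_count = 2, min_prevalence = 0.05,
                            min_depth = 2000,
                            ranks = c("order", "genus", "asv"),
                            ng_settings = ng_config(),
                            rarefaction_depth = 2000, n_rarefactions = 100,
                            permanova_factor = "season", n_perm = 9999,
                            concordance_mapping = default_concordance_mapping(),
                            fish_scale = "counts",
                            outdir, seed = 1) {
  paths <- list(counts = counts_path, taxonomy = taxonomy_path,
                metadata = metadata_path)
  have_paths <- !vapply(paths, is.null, logical(1))
  if (any(have_paths) && !all(have_paths)) {
    stop_("provide all three input paths, or none (synthetic mode)")
  }
  if (all(have_paths) == !is.null(sim)) {
    stop_("exactly one of {input paths, sim} must be given")
  }
  if (length(ranks) == 0) stop_("at least one agglomeration rank is required")
  ranks <- match.arg(ranks, c(TAX_RANKS, "asv"), several.ok = TRUE)
  if (!is_count(n_perm)) stop_("n_perm must be a positive integer")
  structure(list(paths = if (all(have_paths)) paths else NULL,
                 sim = sim, min_count = min_count,
                 min_prevalence = min_prevalence, min_depth = min_depth,
                 ranks = ranks, ng_settings = ng_settings,
                 rarefaction_depth = rarefaction_depth,
                 n_rarefactions = n_rarefactions,
                 permanova_factor = permanova_factor, n_perm = n_perm,
                 concordance_mapping = concordance_mapping,
                 fish_scale = fish_scale,
                 outdir = outdir, seed = as.integer(seed)),
            class = "pipeline_config")
}

pipeline_config_to_list <- function(config) {
  list(
    input = config$paths,
    sim = if (is.null(config$sim)) NULL else sim_config_to_list(config$sim),
    filters = list(min_count = config$min_count,
                   min_prevalence = config$min_prevalence,
                   min_depth = config$min_depth),
    ranks = as.list(config$ranks),
    ng = list(k_units = config$ng_settings$k_units,
              epochs = config$ng_settings$epochs,
              eps_initial = config$ng_settings$eps_initial,
              eps_final = config$ng_settings$eps_final,
              lambda_initial = config$ng_settings$lambda_initial,
              lambda_final = config$ng_settings$lambda_final),
    diversity = list(depth = config$rarefaction_depth,
                     n_repeats = config$n_rarefactions),
    tests = list(factor = config$permanova_factor, n_perm = config$n_perm),
    concordance = list(mapping = config$concordance_mapping,
                       fish_scale = config$fish_scale),
    seed = config$seed
  )
}

#' Read a pipeline configuration from YAML
#'
#' Reads the YAML written by [run_pipeline()] into the run directory
#' (`config.yaml`), which suffices to replay the run exactly.
#'
#' @param path YAML file.
#' @param outdir output directory for the replay.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, outdir) {
  x <- yaml::read_yaml(path)
  mapping <- x$concordance$mapping
  pipeline_config(
    counts_path = x$input$counts, taxonomy_path = x$input$taxonomy,
    metadata_path = x$input$metadata,
    sim = if (is.null(x$sim)) NULL else sim_config_from_list(x$sim),
    min_count = x$filters$min_count, min_prevalence = x$filters$min_prevalence,
    min_depth = x$filters$min_depth,
    ranks = unlist(x$ranks),
    ng_settings = ng_config(k_units = x$ng$k_units, epochs = x$ng$epochs,
                            eps_initial = x$ng$eps_initial,
                            eps_final = x$ng$eps_final,
                            lambda_initial = x$ng$lambda_initial,
                            lambda_final = x$ng$lambda_final),
    rarefaction_depth = x$diversity$depth,
    n_rarefactions = x$diversity$n_repeats,
    permanova_factor = x$tests$factor, n_perm = x$tests$n_perm,
    concordance_mapping = mapping, fish_scale = x$concordance$fish_scale,
    outdir = outdir, seed = x$seed
  )
}

#' Run the full analysis pipeline
#'
#' Executes filter (taxa first, then samples) -> per-rank agglomeration ->
#' CLR -> neural gas training, BMU assignment and relabelling -> BMU profiles
#' -> repeated-rarefaction diversity (on the unagglomerated ASV table) ->
#' PERMANOVA/PERMDISP on Aitchison distances -> FISH concordance, writing
#' every intermediate table as TSV plus `config.yaml` and `manifest.json`
#' into the output directory. A rerun with the same configuration (or with
#' the configuration read back from `config.yaml`) writes byte-identical
#' numeric outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the filtered tables, per-rank results
#'   (`model`, `assignment`, `clr`, `profile`, `permanova`, `permdisp`),
#'   `diversity`, `concordance`, `labels` (synthetic mode) and `outdir`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stop_("config must be a pipeline_config")
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  labels <- NULL
  if (!is.null(config$sim)) {
    dataset <- stage("synthesize", generate_dataset(config$sim))
    counts <- dataset$counts
    taxonomy <- dataset$taxonomy
    metadata <- dataset$metadata
    labels <- dataset$labels
  } else {
    counts <- stage("read counts", read_count_table(config$paths$counts))
    taxonomy <- stage("read taxonomy", read_taxonomy(config$paths$taxonomy))
    metadata <- stage("read metadata", read_metadata(config$paths$metadata))
  }

  n_features0 <- ncol(counts); n_samples0 <- nrow(counts)
  counts_f <- stage("filter taxa",
                    filter_taxa(counts, config$min_count,
                                config$min_prevalence, quiet = TRUE))
  counts_f <- stage("filter samples",
                    filter_samples(counts_f, config$min_depth, quiet = TRUE))
  dropped_features <- setdiff(colnames(counts), colnames(counts_f))
  dropped_samples <- setdiff(rownames(counts), rownames(counts_f))
  metadata <- metadata[metadata$sample_id %in% rownames(counts_f), ,
                       drop = FALSE]
  if (!is.null(labels)) labels <- labels[rownames(counts_f)]
  write_count_table(counts_f, file.path(outdir, "counts_filtered.tsv"))

  diversity <- stage("diversity", repeated_rarefaction_diversity(
    counts_f, depth = config$rarefaction_depth,
    n_repeats = config$n_rarefactions, seed = config$seed + 101L))
  write.table(diversity, file.path(outdir, "diversity.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  rank_results <- list()
  deltas <- list()
  for (i in seq_along(config$ranks)) {
    rank <- config$ranks[i]
    agg <- stage(paste0("agglomerate [", rank, "]"),
                 agglomerate(counts_f, taxonomy, rank = rank))
    clr <- stage(paste0("clr [", rank, "]"), clr_transform(agg))
    deltas[[rank]] <- attr(clr, "pseudocount")
    ngc <- config$ng_settings
    ngc$seed <- config$seed + 200L + i
    model <- stage(paste0("neural gas [", rank, "]"),
                   train_neural_gas(clr, ngc))
    assignment <- assign_bmu(model, clr)
    rl <- relabel_units(model, assignment)
    model <- rl$model; assignment <- rl$assignment

    profile <- stage(paste0("profile [", rank, "]"),
                     bmu_profile(assignment, metadata, clr,
                                 diversity = diversity,
                                 variables = intersect(
                                   c(ENV_VARIABLES,
                                     paste0("fish_", FISH_PROBES)),
                                   names(metadata))))
    export_heatmap_table(profile,
                         file.path(outdir, paste0("profile_", rank, ".tsv")))
    write.table(data.frame(sample_id = names(assignment),
                           unit = as.integer(assignment)),
                file.path(outdir, paste0("assignment_", rank, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(unit = rownames(model$codebook),
                           model$codebook, check.names = FALSE),
                file.path(outdir, paste0("codebook_", rank, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)

    dmat <- aitchison_distance(clr)
    pa <- pd <- NULL
    if (!is.null(config$permanova_factor) &&
        config$permanova_factor %in% names(metadata)) {
      grp <- metadata[[config$permanova_factor]][
        match(rownames(clr), metadata$sample_id)]
      sizes <- table(grp)
      if (length(sizes) >= 2 && all(sizes >= 2)) {
        pa <- stage(paste0("permanova [", rank, "]"),
                    permanova_oneway(dmat, grp, n_perm = config$n_perm,
                                     seed = config$seed + 300L + i))
        pd <- stage(paste0("permdisp [", rank, "]"),
                    permdisp(dmat, grp, n_perm = config$n_perm,
                             seed = config$seed + 400L + i))
      }
    }
    rank_results[[rank]] <- list(rank = rank, clr = clr, model = model,
                                 assignment = assignment, profile = profile,
                                 permanova = pa, permdisp = pd)
  }

  perm_rows <- do.call(rbind, lapply(rank_results, function(r) {
    if (is.null(r$permanova)) return(NULL)
    data.frame(rank = r$rank,
               test = c("PERMANOVA", "PERMDISP"),
               statistic = c(r$permanova$statistic, r$permdisp$statistic),
               p = c(r$permanova$p, r$permdisp$p),
               n_perm = c(r$permanova$n_perm, r$permdisp$n_perm))
  }))
  if (!is.null(perm_rows)) {
    write.table(perm_rows, file.path(outdir, "permutation_tests.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  conc <- NULL
  if (!is.null(config$concordance_mapping)) {
    conc <- stage("concordance",
                  concordance(counts_f, taxonomy, metadata,
                              mapping = config$concordance_mapping,
                              fish_scale = config$fish_scale))
    write.table(conc, file.path(outdir, "concordance.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  # precision 17 so doubles survive the YAML round trip bit-exactly and a
  # replay from config.yaml reproduces the run byte-identically
  yaml::write_yaml(pipeline_config_to_list(config),
                   file.path(outdir, "config.yaml"), precision = 17L)
  manifest <- list(
    package = "compng",
    version = as.character(utils::packageVersion("compng")),
    seed = config$seed,
    stage_seeds = list(diversity = config$seed + 101L,
                       neural_gas = config$seed + 200L + seq_along(config$ranks),
                       permanova = config$seed + 300L + seq_along(config$ranks),
                       permdisp = config$seed + 400L + seq_along(config$ranks)),
    input = list(n_samples = n_samples0, n_features = n_features0),
    filtered = list(n_samples = nrow(counts_f), n_features = ncol(counts_f),
                    dropped_samples = dropped_samples,
                    dropped_features_n = length(dropped_features)),
    clr_pseudocount = deltas,
    unit_membership = lapply(rank_results, function(r) {
      as.list(tabulate(unclass(r$assignment), nbins = r$model$config$k_units))
    }),
    quantization_error = lapply(rank_results, function(r) {
      r$model$quantization_error
    }),
    config = "config.yaml"
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(counts = counts_f, taxonomy = taxonomy, metadata = metadata,
                 labels = labels, diversity = diversity, ranks = rank_results,
                 concordance = conc, outdir = outdir))
}
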