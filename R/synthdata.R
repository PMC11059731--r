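#' Synthetic nested taxonomy
#'
#' Builds a strictly nested lineage table (2 classes / 8 orders / 86 genera /
#' 661 ASVs by default, the scale of a one-year pufM survey) with child counts
#' per parent distributed as evenly as possible; the seed only shuffles which
#' parents receive the remainder children. Names are synthetic but stable
#' (`C1`, `C1.O2`, `C1.O2.G3`, `ASV0001`) unless overridden.
#'
#' @param shape named counts `c(classes, orders, genera, asvs)`; must be
#'   nested (`asvs >= genera >= orders >= classes >= 1`).
#' @param seed integer seed.
#' @param class_names,order_names optional label overrides (recycled onto the
#'   synthetic names in order).
#' @return taxonomy data.frame (`feature_id` + the six ranks). One family is
#'   emitted per order (`<order>.F1`): the family rank is carried for format
#'   compatibility but not subdivided.
#' @export
generate_taxonomy <- function(shape = c(classes = 2, orders = 8, genera = 86,
                                        asvs = 661),
                              seed = 1, class_names = NULL,
                              order_names = NULL) {
  if (length(shape) != 4) stop_("shape must give classes, orders, genera, asvs")
  shape <- as.integer(shape)
  if (any(shape < 1) || any(diff(shape) < 0)) {
    stop_("taxonomy shape must be nested: asvs >= genera >= orders >= classes >= 1")
  }
  n_class <- shape[1]; n_order <- shape[2]; n_genus <- shape[3]; n_asv <- shape[4]

  split_even <- function(n_children, n_parents) {
    base <- n_children %/% n_parents
    extra <- n_children %% n_parents
    k <- rep(base, n_parents)
    if (extra > 0) k[sample.int(n_parents, extra)] <- base + 1L
    k
  }

  with_seed(seed, {
    classes <- paste0("C", seq_len(n_class))
    if (!is.null(class_names)) classes <- rep_len(class_names, n_class)
    orders_per_class <- split_even(n_order, n_class)
    order_class <- rep(seq_len(n_class), orders_per_class)
    orders <- paste0(classes[order_class], ".O", seq_len(n_order))
    if (!is.null(order_names)) orders <- rep_len(order_names, n_order)
    genera_per_order <- split_even(n_genus, n_order)
    genus_order <- rep(seq_len(n_order), genera_per_order)
    genera <- paste0(orders[genus_order], ".G", seq_len(n_genus))
    asvs_per_genus <- split_even(n_asv, n_genus)
    asv_genus <- rep(seq_len(n_genus), asvs_per_genus)

    data.frame(
      feature_id = sprintf("ASV%04d", seq_len(n_asv)),
      domain = "Bacteria",
      phylum = "Proteobacteria",
      class = classes[order_class[genus_order[asv_genus]]],
      order = orders[genus_order[asv_genus]],
      family = paste0(orders[genus_order[asv_genus]], ".F1"),
      genus = genera[asv_genus],
      stringsAsFactors = FALSE
    )
  })
}

#' Cluster-linked environmental response (default)
#'
#' Per-cluster means and per-variable noise standard deviations for the
#' abiotic and biotic variables, emulating five contrasting Adriatic water
#' masses: a nutrient-enriched low-salinity coastal cluster through to a warm
#' saline oligotrophic one. Units: Temp degC; Sal (PSU); nutrients umol/L;
#' ChlA ug/L; cell counts cells/mL; BP ug C/L/d.
#'
#' @param n_clusters number of planted clusters (rows); the five defaults are
#'   recycled if more are requested.
#' @return list with `mean` (clusters x variables matrix) and `sd`
#'   (named vector). `AAP_abs` and `DIN` are not included: AAP abundance is
#'   drawn from its own log-normal law and DIN is NO3 + NO2 + NH4.
#' @export
default_env_response <- function(n_clusters = 5) {
  means <- rbind(
    Temp   = c(14, 16.5, 19, 21.5, 24),
    Sal    = c(37.2, 38.9, 38.5, 38.0, 37.6),
    NO3    = c(1.8, 0.15, 0.4, 1.0, 0.6),
    NO2    = c(0.25, 0.03, 0.08, 0.30, 0.12),
    NH4    = c(0.9, 0.15, 0.5, 0.35, 0.7),
    NTOT   = c(8, 3, 4.5, 6, 5),
    SRP    = c(0.15, 0.02, 0.05, 0.08, 0.10),
    PTOT   = c(0.35, 0.08, 0.12, 0.20, 0.25),
    SiO4   = c(3.5, 1.0, 1.6, 2.4, 2.8),
    ChlA   = c(0.8, 0.05, 0.15, 0.30, 0.50),
    UHB    = c(8e5, 3e5, 4e5, 6e5, 5e5),
    HNA    = c(4.5e5, 1.5e5, 2e5, 3e5, 2.5e5),
    SYN    = c(4e4, 8e3, 1.5e4, 3e4, 2e4),
    PROCHL = c(2e3, 1.2e4, 8e3, 4e3, 6e3),
    PE     = c(3e3, 5e2, 1e3, 2e3, 1.5e3),
    HNF    = c(1.2e3, 3e2, 5e2, 8e2, 6e2),
    BP     = c(6, 1, 2, 3.5, 4.5)
  )
  sds <- c(Temp = 0.5, Sal = 0.15, NO3 = 0.1, NO2 = 0.02, NH4 = 0.08,
           NTOT = 0.5, SRP = 0.015, PTOT = 0.03, SiO4 = 0.3, ChlA = 0.08,
           UHB = 5e4, HNA = 3e4, SYN = 4e3, PROCHL = 1e3, PE = 3e2,
           HNF = 1e2, BP = 0.5)
  m <- t(means)[rep_len(seq_len(5), n_clusters), , drop = FALSE]
  rownames(m) <- paste0("K", seq_len(n_clusters))
  list(mean = m, sd = sds)
}

#' Simulation configuration
#'
#' Describes a synthetic post-denoising dataset with the statistical structure
#' the downstream analysis assumes: samples drawn from `n_clusters_true`
#' planted clusters of a logistic-normal (Gaussian in CLR space) composition
#' model, integer counts drawn multinomially at log-normal read depths with a
#' hard floor, environmental variables Gaussian around cluster-specific means,
#' FISH-like class fractions equal to the true class-level composition plus
#' noise, and AAP absolute abundances log-normal around 1.43e4 cells/mL.
#'
#' @param n_samples number of samples (default 81).
#' @param n_clusters_true number of planted clusters (default 5).
#' @param taxonomy_shape named rank counts, see [generate_taxonomy()].
#' @param depth_meanlog,depth_sdlog log-normal read-depth law (default median
#'   58,227 reads, sdlog 1).
#' @param depth_floor hard minimum library size (>= 2000 reads).
#' @param cluster_logratio_centers optional `n_clusters_true x n_asvs` matrix
#'   of cluster centers in CLR space; generated from the seed when `NULL`.
#' @param effect_sd sd of the per-cluster center offsets (CLR units) used when
#'   centers are generated.
#' @param within_cluster_sd within-cluster spread per CLR coordinate.
#' @param env_response list with `mean` matrix and `sd` vector, see
#'   [default_env_response()].
#' @param fish_noise_sd sd of the FISH fraction noise (percentage points).
#' @param aap_meanlog,aap_sdlog log-normal law for AAP absolute abundance
#'   (defaults give mean 1.43e4 cells/mL, cv ~ 0.53).
#' @param label_scheme `"uniform"` (iid labels, default) or `"balanced"`
#'   (shuffled near-equal blocks).
#' @param seed master seed driving all randomness.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples = 81, n_clusters_true = 5,
                       taxonomy_shape = c(classes = 2, orders = 8,
                                          genera = 86, asvs = 661),
                       depth_meanlog = log(58227), depth_sdlog = 1,
                       depth_floor = 2000,
                       cluster_logratio_centers = NULL,
                       effect_sd = 1.0, within_cluster_sd = 0.6,
                       env_response = default_env_response(n_clusters_true),
                       fish_noise_sd = 5,
                       aap_meanlog = log(1.43e4) - 0.5^2 / 2, aap_sdlog = 0.5,
                       label_scheme = c("uniform", "balanced"), seed = 1) {
  label_scheme <- match.arg(label_scheme)
  if (!is_count(n_samples) || !is_count(n_clusters_true)) {
    stop_("n_samples and n_clusters_true must be positive integers")
  }
  shape <- as.integer(taxonomy_shape)
  if (any(shape < 1) || any(diff(shape) < 0)) {
    stop_("taxonomy_shape must be nested: asvs >= genera >= orders >= classes >= 1")
  }
  if (depth_floor < 2000) stop_("depth_floor must be at least 2000 reads")
  if (within_cluster_sd < 0 || fish_noise_sd < 0 || effect_sd < 0) {
    stop_("noise standard deviations must be non-negative")
  }
  if (!is.null(cluster_logratio_centers)) {
    if (nrow(cluster_logratio_centers) != n_clusters_true) {
      stop_("cluster_logratio_centers must have one row per cluster")
    }
  }
  if (nrow(env_response$mean) != n_clusters_true) {
    stop_("env_response must have one mean row per cluster")
  }
  if (any(env_response$sd < 0)) stop_("env_response sds must be non-negative")
  structure(list(
    n_samples = as.integer(n_samples),
    n_clusters_true = as.integer(n_clusters_true),
    taxonomy_shape = c(classes = shape[1], orders = shape[2],
                       genera = shape[3], asvs = shape[4]),
    depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
    depth_floor = as.integer(depth_floor),
    cluster_logratio_centers = cluster_logratio_centers,
    effect_sd = effect_sd, within_cluster_sd = within_cluster_sd,
    env_response = env_response, fish_noise_sd = fish_noise_sd,
    aap_meanlog = aap_meanlog, aap_sdlog = aap_sdlog,
    label_scheme = label_scheme, seed = as.integer(seed)
  ), class = "sim_config")
}

# months per season: Jan-Apr winter, May-Jun spring, Jul-Oct summer,
# Nov-Dec autumn (Adriatic hydrographic convention)
SEASON_MONTHS <- list(
  Winter = c("Jan", "Feb", "Mar", "Apr"),
  Spring = c("May", "Jun"),
  Summer = c("Jul", "Aug", "Sep", "Oct"),
  Autumn = c("Nov", "Dec")
)

#' Generate a synthetic dataset
#'
#' Draws the full four-table dataset described by a [sim_config()]: counts,
#' taxonomy, sample metadata and the planted ground-truth cluster labels. When
#' the taxonomy shape has two classes they are named Alphaproteobacteria and
#' Gammaproteobacteria (with Rhodobacterales among the alphaproteobacterial
#' orders when there are eight), so the FISH concordance stage works on the
#' default output without remapping.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (samples x ASVs integer matrix), `taxonomy`,
#'   `metadata`, `labels` (named integer vector of true clusters) and the
#'   echoed `config`.
#' @export
generate_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) stop_("config must be a sim_config")
  shape <- config$taxonomy_shape
  class_names <- if (shape[["classes"]] == 2) {
    c("Alphaproteobacteria", "Gammaproteobacteria")
  } else NULL
  order_names <- if (shape[["classes"]] == 2 && shape[["orders"]] == 8) {
    c("Rhodobacterales", "Sphingomonadales", "Rhizobiales", "Caulobacterales",
      "Pseudomonadales", "Burkholderiales", "Arenicellales", "Xanthomonadales")
  } else NULL
  taxonomy <- generate_taxonomy(shape, seed = config$seed,
                                class_names = class_names,
                                order_names = order_names)
  p <- shape[["asvs"]]
  n <- config$n_samples
  k <- config$n_clusters_true

  with_seed(config$seed + 1L, {
    centers <- config$cluster_logratio_centers
    if (is.null(centers)) {
      base <- rnorm(p, 0, 2)
      centers <- matrix(rep(base, each = k), k, p) +
        matrix(rnorm(k * p, 0, config$effect_sd), k, p)
    }
    if (ncol(centers) != p) {
      stop_(sprintf("cluster centers have %d features but the taxonomy has %d ASVs",
                    ncol(centers), p))
    }

    labels <- switch(config$label_scheme,
                     uniform = sample.int(k, n, replace = TRUE),
                     balanced = sample(rep_len(seq_len(k), n)))

    depths <- pmax(config$depth_floor,
                   round(rlnorm(n, config$depth_meanlog, config$depth_sdlog)))
    counts <- matrix(0L, n, p,
                     dimnames = list(sprintf("S%02d", seq_len(n)),
                                     taxonomy$feature_id))
    true_prob <- matrix(0, n, p)
    for (i in seq_len(n)) {
      z <- centers[labels[i], ] + rnorm(p, 0, config$within_cluster_sd)
      pr <- exp(z - max(z))
      pr <- pr / sum(pr)
      true_prob[i, ] <- pr
      counts[i, ] <- rmultinom(1, size = depths[i], prob = pr)[, 1]
    }

    er <- config$env_response
    env <- sapply(colnames(er$mean), function(v) {
      rnorm(n, mean = er$mean[labels, v], sd = er$sd[[v]])
    })
    nonneg <- setdiff(colnames(env), c("Temp", "Sal"))
    env[, nonneg] <- pmax(env[, nonneg], 0)
    env <- as.data.frame(env)
    env$DIN <- env$NO3 + env$NO2 + env$NH4
    aap_abs <- rlnorm(n, config$aap_meanlog, config$aap_sdlog)

    # FISH-like fractions: true class (and Rhodobacterales) composition in %
    # plus counting noise, clipped to [0, 100]
    class_of <- taxonomy$class[match(colnames(counts), taxonomy$feature_id)]
    order_of <- taxonomy$order[match(colnames(counts), taxonomy$feature_id)]
    frac_of <- function(sel) 100 * rowSums(true_prob[, sel, drop = FALSE])
    clip01 <- function(x) pmin(100, pmax(0, x))
    noise <- function() rnorm(n, 0, config$fish_noise_sd)
    alf <- clip01(frac_of(class_of == "Alphaproteobacteria") + noise())
    gam <- clip01(frac_of(class_of == "Gammaproteobacteria") + noise())
    ros <- clip01(frac_of(order_of == "Rhodobacterales") + noise())

    season_of_cluster <- rep_len(SEASONS, k)[labels]
    season <- ifelse(runif(n) < 0.7, season_of_cluster,
                     sample(SEASONS, n, replace = TRUE))
    month <- vapply(season, function(s) sample(SEASON_MONTHS[[s]], 1), "")
    depth_m <- sample(c(0, 10, 20, 30, 50, 75, 100), n, replace = TRUE)
    layer <- LAYERS[findInterval(depth_m, c(-Inf, 30, 50, 75), left.open = TRUE)]

    metadata <- data.frame(
      sample_id = rownames(counts),
      station = sample(c("ST101", "CJ007", "CJ009"), n, replace = TRUE),
      depth = depth_m, month = month, season = season, layer = layer,
      env,
      AAP_abs = aap_abs,
      fish_ALF968 = alf, fish_GAM42a = gam, fish_ROS537 = ros,
      stringsAsFactors = FALSE
    )
    validate_metadata(metadata)
    names(labels) <- rownames(counts)
    list(counts = counts, taxonomy = taxonomy, metadata = metadata,
         labels = labels, config = config)
  })
}

#' Write a synthetic dataset to disk
#'
#' Emits the three standard tab-separated tables plus the true-label table and
#' a JSON log echoing the configuration and seed.
#'
#' @param dataset output of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_table(dataset$counts, file.path(dir, "counts.tsv"))
  write_taxonomy(dataset$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_metadata(dataset$metadata, file.path(dir, "metadata.tsv"))
  write.table(data.frame(sample_id = names(dataset$labels),
                         cluster = as.integer(dataset$labels)),
              file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(sim_config_to_list(dataset$config),
                       file.path(dir, "simulation_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# serializable form of a sim_config (YAML/JSON round trip)
sim_config_to_list <- function(config) {
  list(
    n_samples = config$n_samples,
    n_clusters_true = config$n_clusters_true,
    taxonomy_shape = as.list(config$taxonomy_shape),
    depth = list(meanlog = config$depth_meanlog, sdlog = config$depth_sdlog,
                 floor = config$depth_floor),
    cluster_logratio_centers = if (is.null(config$cluster_logratio_centers)) {
      NULL
    } else {
      apply(config$cluster_logratio_centers, 1, identity, simplify = FALSE)
    },
    effect_sd = config$effect_sd,
    within_cluster_sd = config$within_cluster_sd,
    env_response = list(
      variables = colnames(config$env_response$mean),
      mean = apply(config$env_response$mean, 1, identity, simplify = FALSE),
      sd = as.list(config$env_response$sd)
    ),
    fish_noise_sd = config$fish_noise_sd,
    aap = list(meanlog = config$aap_meanlog, sdlog = config$aap_sdlog),
    label_scheme = config$label_scheme,
    seed = config$seed
  )
}

sim_config_from_list <- function(x) {
  er_vars <- unlist(x$env_response$variables)
  er_mean <- do.call(rbind, lapply(x$env_response$mean, unlist))
  colnames(er_mean) <- er_vars
  rownames(er_mean) <- paste0("K", seq_len(nrow(er_mean)))
  centers <- if (is.null(x$cluster_logratio_centers)) NULL else {
    do.call(rbind, lapply(x$cluster_logratio_centers, unlist))
  }
  sim_config(
    n_samples = x$n_samples, n_clusters_true = x$n_clusters_true,
    taxonomy_shape = unlist(x$taxonomy_shape),
    depth_meanlog = x$depth$meanlog, depth_sdlog = x$depth$sdlog,
    depth_floor = x$depth$floor,
    cluster_logratio_centers = centers,
    effect_sd = x$effect_sd, within_cluster_sd = x$within_cluster_sd,
    env_response = list(mean = er_mean, sd = unlist(x$env_response$sd)),
    fish_noise_sd = x$fish_noise_sd,
    aap_meanlog = x$aap$meanlog, aap_sdlog = x$aap$sdlog,
    label_scheme = x$label_scheme, seed = x$seed
  )
}
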