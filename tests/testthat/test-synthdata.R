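test_that("generate_taxonomy builds nested lineages of the requested shape", {
  tax <- generate_taxonomy(c(classes = 2, orders = 8, genera = 86, asvs = 661),
                           seed = 7)
  expect_equal(nrow(tax), 661)
  expect_equal(length(unique(tax$genus)), 86)
  expect_equal(length(unique(tax$order)), 8)
  expect_equal(length(unique(tax$class)), 2)
  # strict nesting: each child maps to exactly one parent
  expect_true(all(rowSums(table(tax$genus, tax$order) > 0) == 1))
  expect_true(all(rowSums(table(tax$order, tax$class) > 0) == 1))

  single <- generate_taxonomy(c(1, 1, 1, 1), seed = 1)
  expect_equal(nrow(single), 1)

  expect_identical(generate_taxonomy(seed = 3), generate_taxonomy(seed = 3))
  expect_error(generate_taxonomy(c(3, 2, 10, 20)), "nested")
})

test_that("generate_dataset honours depth floor, shape and determinism", {
  ds <- generate_dataset(sim_config())
  expect_equal(nrow(ds$counts), 81)
  expect_equal(ncol(ds$counts), 661)
  expect_true(all(rowSums(ds$counts) >= 2000))
  expect_true(all(ds$counts >= 0 & ds$counts == round(ds$counts)))
  expect_equal(length(ds$labels), 81)
  expect_true(all(ds$labels %in% 1:5))

  ds2 <- generate_dataset(sim_config())
  expect_identical(ds$counts, ds2$counts)
  expect_identical(ds$metadata, ds2$metadata)
  expect_identical(ds$labels, ds2$labels)

  bad <- sim_config(cluster_logratio_centers = matrix(0, 5, 10))
  expect_error(generate_dataset(bad), "features")
})

test_that("cluster labels are uniform across clusters (pooled over seeds)", {
  shape <- c(classes = 2, orders = 8, genera = 16, asvs = 40)
  pooled <- integer(5)
  for (s in 1:20) {
    ds <- generate_dataset(sim_config(taxonomy_shape = shape, seed = s))
    pooled <- pooled + tabulate(ds$labels, 5)
  }
  share <- pooled / sum(pooled)
  expect_true(all(abs(share - 0.2) < 0.3 * 0.2))
})

test_that("environmental variables track the planted cluster means", {
  er <- default_env_response(5)
  er$mean[, "Temp"] <- c(14, 16, 18, 20, 22)
  er$sd[["Temp"]] <- 0.5
  cfg <- sim_config(env_response = er, seed = 11,
                    taxonomy_shape = c(2, 8, 16, 40))
  ds <- generate_dataset(cfg)
  for (k in 1:5) {
    sel <- ds$labels == k
    ng <- sum(sel)
    expect_lt(abs(mean(ds$metadata$Temp[sel]) - er$mean[k, "Temp"]),
              3 * 0.5 / sqrt(ng))
  }
})

test_that("DIN is the sum of its nitrogen species and FISH fractions are valid", {
  ds <- generate_dataset(sim_config(taxonomy_shape = c(2, 8, 16, 40), seed = 4))
  m <- ds$metadata
  expect_equal(m$DIN, m$NO3 + m$NO2 + m$NH4)
  for (col in c("fish_ALF968", "fish_GAM42a", "fish_ROS537")) {
    expect_true(all(m[[col]] >= 0 & m[[col]] <= 100))
  }
})

test_that("noiseless limit recovers the planted center compositions", {
  cfg <- sim_config(n_samples = 20, n_clusters_true = 2,
                    taxonomy_shape = c(2, 8, 16, 40),
                    within_cluster_sd = 0,
                    depth_meanlog = log(2e5), depth_sdlog = 0,
                    env_response = default_env_response(2), seed = 8)
  ds <- generate_dataset(cfg)
  rel <- relative_abundance(ds$counts)
  for (k in 1:2) {
    sel <- ds$labels == k
    # all samples of a cluster share one composition when within-sd = 0
    spread <- apply(rel[sel, , drop = FALSE], 2, max) -
      apply(rel[sel, , drop = FALSE], 2, min)
    expect_lt(max(spread), 0.02)
  }
})

test_that("effect size zero yields chance-level cluster recovery", {
  aris <- vapply(1:5, function(s) {
    cfg <- sim_config(n_samples = 40, taxonomy_shape = c(2, 8, 16, 60),
                      effect_sd = 0, seed = s)
    ds <- generate_dataset(cfg)
    clr <- clr_transform(agglomerate(ds$counts, ds$taxonomy, "genus"))
    m <- train_neural_gas(clr, ng_config(epochs = 200, seed = s))
    ari(unclass(assign_bmu(m, clr)), ds$labels)
  }, numeric(1))
  expect_lte(median(aris), 0.1)
})

test_that("write_dataset emits readable tables and a config log", {
  dir <- tempfile("simdata")
  cfg <- sim_config(taxonomy_shape = c(2, 8, 16, 40), n_samples = 12, seed = 2)
  ds <- generate_dataset(cfg)
  write_dataset(ds, dir)
  back <- read_count_table(file.path(dir, "counts.tsv"))
  expect_identical(back[rownames(ds$counts), colnames(ds$counts)], ds$counts * 1)
  tax <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  expect_setequal(tax$feature_id, ds$taxonomy$feature_id)
  meta <- read_metadata(file.path(dir, "metadata.tsv"))
  expect_setequal(meta$sample_id, ds$metadata$sample_id)
  log <- jsonlite::read_json(file.path(dir, "simulation_log.json"))
  expect_equal(log$seed, 2)
})
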