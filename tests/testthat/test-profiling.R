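test_that("environmental averages are per-unit arithmetic means", {
  meta <- minimal_metadata(paste0("S", 1:3), temp = c(10, 20, 30))
  a <- make_assignment(c(1, 1, 2), k = 2)
  prof <- profile_environment(a, meta, variables = "Temp")
  expect_equal(unname(prof$env_means[, "Temp"]), c(15, 30))
  expect_equal(unname(prof$env_n[, "Temp"]), c(2L, 1L))

  # single unit: means equal global means
  one <- make_assignment(c(1, 1, 1), k = 1)
  p1 <- profile_environment(one, meta, variables = "Temp")
  expect_equal(unname(p1$env_means[1, "Temp"]), 20)

  expect_error(profile_environment(a, meta, variables = "Nitrogenase"),
               "available numeric variables")
  expect_error(profile_environment(make_assignment(1, samples = "S9"), meta),
               "missing from metadata")
})

test_that("missing environmental values are skipped and counted", {
  meta <- minimal_metadata(paste0("S", 1:4), temp = c(10, NA, 30, NA))
  a <- make_assignment(c(1, 1, 2, 2), k = 2)
  prof <- profile_environment(a, meta, variables = "Temp")
  expect_equal(unname(prof$env_means[, "Temp"]), c(10, 30))
  expect_equal(unname(prof$env_n[, "Temp"]), c(1L, 1L))
})

test_that("taxon means equal a brute-force group-by", {
  clr <- toy_counts(rbind(c(-1, 2), c(1, 0), c(3, -2)),
                    features = c("T1", "T2"))
  a <- make_assignment(c(1, 1, 2), k = 2)
  prof <- profile_taxa(a, clr)
  expect_equal(unname(prof$taxon_means[1, ]), c(0, 1))   # (-1,1) and (2,0)
  expect_equal(unname(prof$taxon_means[2, ]), c(3, -2))  # single member

  manual <- apply(clr, 2, function(col) tapply(col, unclass(a), mean))
  expect_equal(unname(prof$taxon_means), unname(manual))
  expect_error(profile_taxa(make_assignment(1, samples = "S9"), clr),
               "missing from the CLR")
})

test_that("membership-weighted unit means recover the global mean", {
  ds <- generate_dataset(sim_config(taxonomy_shape = c(2, 8, 16, 40),
                                    n_samples = 24, seed = 13))
  clr <- clr_transform(ds$counts)
  m <- train_neural_gas(clr, ng_config(k_units = 3, epochs = 50, seed = 1))
  a <- assign_bmu(m, clr)
  prof <- bmu_profile(a, ds$metadata, clr)
  sizes <- lengths(prof$member_ids)
  for (v in colnames(prof$env_means)) {
    pooled <- sum(sizes * prof$env_means[, v]) / sum(sizes)
    expect_lt(abs(pooled - mean(ds$metadata[[v]])), 1e-9)
  }
  expect_equal(sum(sizes), nrow(clr))
})

test_that("profiles are invariant under sample reordering", {
  meta <- minimal_metadata(paste0("S", 1:5), temp = c(1, 2, 3, 4, 10))
  clr <- toy_counts(matrix(rnorm(10), 5, 2), features = c("T1", "T2"))
  a <- make_assignment(c(1, 2, 1, 2, 1), k = 2)
  perm <- c(4, 1, 5, 3, 2)
  a_perm <- make_assignment(unclass(a)[perm], samples = names(a)[perm], k = 2)
  p1 <- bmu_profile(a, meta, clr)
  p2 <- bmu_profile(a_perm, meta[perm, ], clr[perm, ])
  expect_equal(p1$env_means, p2$env_means)
  expect_equal(p1$taxon_means, p2$taxon_means)
})

test_that("heatmap export is long, sorted, complete and round-trips", {
  meta <- minimal_metadata(paste0("S", 1:3), temp = c(10, 20, 30))
  clr <- toy_counts(rbind(c(-1, 1), c(0, 0), c(2, -2)),
                    features = c("T1", "T2"))
  a <- make_assignment(c(1, 1, 2), k = 3)  # unit 3 empty
  prof <- bmu_profile(a, meta, clr, variables = c("Temp", "AAP_abs"))
  tab <- export_heatmap_table(prof)
  expect_equal(nrow(tab), 3 * (2 + 2))
  empty <- tab[tab$unit == "U3", ]
  expect_true(all(empty$n == 0))
  expect_true(all(is.na(empty$mean)))

  path <- tempfile(fileext = ".tsv")
  export_heatmap_table(prof, path)
  back <- read.delim(path)
  expect_equal(back$mean, tab$mean)
  expect_equal(back$n, tab$n)
  expect_equal(back$name, tab$name)
})
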