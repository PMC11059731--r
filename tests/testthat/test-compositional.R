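test_that("prevalence filter applies the keep rule exactly and is idempotent", {
  counts <- toy_counts(rbind(c(2, 1), c(0, 1), c(0, 1), c(0, 1)),
                       features = c("A", "B"))
  kept <- filter_taxa(counts, min_count = 2, min_prevalence = 0.05,
                      quiet = TRUE)
  expect_identical(colnames(kept), "A")
  expect_identical(rownames(kept), rownames(counts))
  expect_identical(filter_taxa(kept, quiet = TRUE), kept)

  # min_count 1 with vanishing prevalence keeps everything present
  expect_identical(
    filter_taxa(counts, min_count = 1, min_prevalence = 1e-9, quiet = TRUE),
    counts)

  expect_warning(filter_taxa(counts, min_count = 10, quiet = TRUE),
                 "all features removed")
})

test_that("depth filter keeps the boundary sample", {
  counts <- toy_counts(cbind(c(1999, 2000, 58227)))
  kept <- filter_samples(counts, quiet = TRUE)
  expect_identical(rownames(kept), c("S2", "S3"))
  expect_identical(filter_samples(counts, min_depth = 0, quiet = TRUE), counts)
  expect_warning(filter_samples(counts, min_depth = 1e6, quiet = TRUE),
                 "all samples removed")
})

test_that("agglomeration sums lineages and conserves per-sample totals", {
  counts <- toy_counts(rbind(c(3, 1, 9), c(5, 1, 2)),
                       features = c("ASV1", "ASV2", "ASV3"))
  tax <- data.frame(feature_id = c("ASV1", "ASV2", "ASV3"),
                    domain = "B", phylum = "P", class = "C",
                    order = c("O1", "O1", "O2"),
                    family = c("F1", "F1", "F2"),
                    genus = c("G1", "G1", "G2"))
  agg <- agglomerate(counts, tax, "genus")
  g1 <- grep("G1$", colnames(agg))
  expect_equal(unname(agg[, g1]), c(4, 6))
  expect_equal(rowSums(agg), rowSums(counts))
  expect_identical(agglomerate(counts, tax, "asv"), counts)
  expect_error(agglomerate(counts, tax[-1, ], "genus"), "ASV1")

  ds <- generate_dataset(sim_config(seed = 5))
  genus <- agglomerate(ds$counts, ds$taxonomy, "genus")
  expect_equal(ncol(genus), 86)
  expect_equal(rowSums(genus), rowSums(ds$counts))
})

test_that("relative abundances are exact row-normalizations", {
  counts <- toy_counts(rbind(c(1, 2, 4)))
  expect_equal(unname(relative_abundance(counts)[1, ]), c(1, 2, 4) / 7)
  expect_equal(unname(relative_abundance(toy_counts(cbind(c(5, 9))))[, 1]),
               c(1, 1))
  zero <- toy_counts(rbind(c(1, 1), c(0, 0)))
  expect_error(relative_abundance(zero), "filter_samples")
})

test_that("CLR transform matches hand-computed log ratios", {
  counts <- toy_counts(rbind(c(1, 2, 4)))
  clr <- clr_transform(counts)
  expect_equal(unname(clr[1, ]), c(-log(2), 0, log(2)), tolerance = 1e-12)
  expect_equal(unname(clr_transform(toy_counts(rbind(c(3, 3, 3))))[1, ]),
               c(0, 0, 0))
  expect_error(clr_transform(toy_counts(rbind(c(0, 0)))), "all-zero")
})

test_that("pseudo-count is half the global minimum nonzero relative abundance", {
  counts <- toy_counts(rbind(c(0, 1, 9), c(5, 5, 10)))
  clr <- clr_transform(counts)
  expect_equal(attr(clr, "pseudocount"), (1 / 10) / 2)
  # zero cell carries log(delta) before centering
  lx <- log(c(0.05, 0.1, 0.9))
  expect_equal(unname(clr[1, ]), lx - mean(lx), tolerance = 1e-12)
  # explicit pseudocount accepted
  clr2 <- clr_transform(counts, pseudocount = 0.001)
  expect_equal(attr(clr2, "pseudocount"), 0.001)
  expect_error(clr_transform(counts, pseudocount = -1), "positive")
})

test_that("CLR rows sum to zero and distances are perturbation invariant", {
  ds <- generate_dataset(sim_config(taxonomy_shape = c(2, 8, 16, 40),
                                    n_samples = 12, seed = 9))
  clr <- clr_transform(ds$counts)
  expect_lt(max(abs(rowSums(clr))), 1e-9)

  # zero-free table: perturbing every sample by one positive vector leaves
  # CLR differences, hence Aitchison distances, unchanged
  x <- toy_counts(rbind(c(1, 2, 4), c(2, 2, 8), c(5, 1, 1)))
  pert <- c(3, 0.5, 7)
  d0 <- aitchison_distance(clr_transform(x))
  d1 <- aitchison_distance(clr_transform(sweep(x, 2, pert, `*`)))
  expect_lt(max(abs(d0 - d1)), 1e-9)
})

test_that("Aitchison distance matches the two-part closed form", {
  x <- toy_counts(rbind(c(1, 3), c(3, 1), c(1, 3)))
  d <- aitchison_distance(clr_transform(x))
  expect_equal(d[1, 2], sqrt(2) * log(3), tolerance = 1e-9)
  expect_equal(d[1, 3], 0)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
})
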