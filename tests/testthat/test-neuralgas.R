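test_that("ng_config validates its hyperparameters", {
  expect_error(ng_config(k_units = 0), "k_units")
  expect_error(ng_config(eps_initial = 1.5), "eps")
  expect_error(ng_config(eps_final = 0.9, eps_initial = 0.5), "eps")
  expect_error(ng_config(lambda_final = 0), "lambda")
  cfg <- ng_config()
  expect_equal(cfg$k_units, 5L)
  expect_equal(cfg$epochs, 1000L)
  expect_equal(cfg$eps_initial, 0.5)
  expect_equal(cfg$lambda_initial, 4.5)
})

test_that("a single unit converges to the data centroid", {
  set.seed(3)
  x <- matrix(rnorm(600, mean = 5, sd = 2), 200, 3)
  rownames(x) <- paste0("S", 1:200)
  m <- train_neural_gas(x, ng_config(k_units = 1, epochs = 200, seed = 10))
  err <- sqrt(sum((m$codebook[1, ] - colMeans(x))^2))
  expect_lt(err, 0.05 * mean(apply(x, 2, sd)))
})

test_that("training is reproducible and respects preconditions", {
  pc <- planted_clusters(n = 40, p = 6, k = 3, seed = 2)
  cfg <- ng_config(k_units = 3, epochs = 50, seed = 7)
  m1 <- train_neural_gas(pc$x, cfg)
  m2 <- train_neural_gas(pc$x, cfg)
  expect_identical(m1$codebook, m2$codebook)
  expect_equal(m1$n_presentations, 50 * 40)
  expect_error(train_neural_gas(pc$x[1:2, ], cfg), "exceeds")
  bad <- pc$x; bad[1, 1] <- NA
  expect_error(train_neural_gas(bad, cfg), "non-finite")
})

test_that("assignment is the brute-force nearest unit with lowest-index ties", {
  w <- toy_counts(rbind(c(0, 0), c(4, 0), c(2, 5)), samples = paste0("U", 1:3))
  x <- rbind(c(2, 5), c(2, 0), c(0.1, 0.2))
  rownames(x) <- paste0("S", 1:3)
  a <- assign_bmu(w, x)
  expect_equal(unclass(a)[["S1"]], 3L)     # exact codebook row
  expect_equal(unclass(a)[["S2"]], 1L)     # equidistant from U1, U2 -> U1
  expect_equal(unclass(a)[["S3"]], 1L)
  expect_error(assign_bmu(w, x[, 1, drop = FALSE]), "mismatch")

  pc <- planted_clusters(n = 60, p = 8, k = 4, seed = 5)
  m <- train_neural_gas(pc$x, ng_config(k_units = 4, epochs = 100, seed = 5))
  a <- assign_bmu(m, pc$x)
  brute <- apply(pc$x, 1, function(row) {
    which.min(colSums((t(m$codebook) - row)^2))
  })
  expect_equal(as.vector(unclass(a)), unname(brute))
})

test_that("quantization error matches hand arithmetic", {
  x <- toy_counts(cbind(c(0, 2)))
  expect_equal(quantization_error(toy_counts(cbind(1), samples = "U1"), x), 1.0)
  expect_equal(quantization_error(x, x), 0)
})

test_that("winner-only limit reproduces online k-means exactly", {
  pc <- planted_clusters(n = 30, p = 5, k = 3, seed = 4)
  cfg <- ng_config(k_units = 3, epochs = 20, lambda_initial = 1e-6,
                   lambda_final = 1e-6, seed = 9)
  m <- train_neural_gas(pc$x, cfg)

  # independent online k-means oracle with the same seeded draws
  draws <- compng:::ng_draws(30, 3, 20, 9)
  w <- pc$x[draws$init, , drop = FALSE]
  t_max <- length(draws$pres)
  for (t in seq_len(t_max)) {
    x <- pc$x[draws$pres[t], ]
    d2 <- rowSums(sweep(w, 2, x)^2)
    win <- which.min(d2)
    eps <- cfg$eps_initial * (cfg$eps_final / cfg$eps_initial)^(t / t_max)
    w[win, ] <- w[win, ] + eps * (x - w[win, ])
  }
  expect_lt(max(abs(m$codebook - w)), 1e-8)
})

test_that("codebook stays inside the data bounding box", {
  pc <- planted_clusters(n = 50, p = 4, k = 3, seed = 6)
  m <- train_neural_gas(pc$x, ng_config(k_units = 3, epochs = 100, seed = 6))
  lo <- apply(pc$x, 2, min); hi <- apply(pc$x, 2, max)
  expect_true(all(sweep(m$codebook, 2, lo, `>=`)))
  expect_true(all(sweep(m$codebook, 2, hi, `<=`)))
})

test_that("relabel_units orders by decreasing membership with stable ties", {
  w <- toy_counts(diag(3), samples = paste0("U", 1:3))
  model <- structure(list(codebook = w, config = ng_config(k_units = 3),
                          quantization_error = 0, qe_initial = 0,
                          n_presentations = 0, init_indices = 1:3),
                     class = "ng_model")
  a <- make_assignment(rep(1:3, c(10, 40, 31)), k = 3)
  rl <- relabel_units(model, a)
  sizes <- tabulate(unclass(rl$assignment), 3)
  expect_equal(sizes, c(40, 31, 10))
  # old unit 2 is new unit 1, old 3 -> 2, old 1 -> 3
  expect_equal(unname(rl$model$codebook[1, ]), unname(w[2, ]))
  expect_equal(unname(rl$model$codebook[3, ]), unname(w[1, ]))

  sorted <- make_assignment(rep(1:3, c(5, 4, 3)), k = 3)
  rl2 <- relabel_units(model, sorted)
  expect_equal(unname(unclass(rl2$assignment)), unname(unclass(sorted)))

  even <- make_assignment(rep(1:3, each = 2), k = 3)
  rl3 <- relabel_units(model, even)
  expect_equal(unname(unclass(rl3$assignment)), unname(unclass(even)))
})
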