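test_that("phenotype vectors hit the requested pairwise distances exactly", {
  # zero separation collapses to the uniform distribution
  v <- make_phenotype_vectors(2, 4, distance = 0)
  expect_equal(v[[1]], rep(0.25, 4))
  expect_equal(v[[2]], rep(0.25, 4))

  v <- make_phenotype_vectors(2, 4, distance = 0.2, seed = 1)
  expect_equal(sqrt(sum((v[[1]] - v[[2]])^2)), 0.2, tolerance = 1e-9)

  # all six pairwise distances for 4 classes at W = 16
  v <- make_phenotype_vectors(4, 16, distance = 0.25, seed = 3)
  for (vec in v) {
    expect_true(all(vec >= 0))
    expect_equal(sum(vec), 1, tolerance = 1e-12)
  }
  pairs <- utils::combn(4, 2)
  d <- apply(pairs, 2, function(ij) {
    sqrt(sum((v[[ij[1]]] - v[[ij[2]]])^2))
  })
  expect_equal(d, rep(0.25, 6), tolerance = 1e-9)

  # large separations stay exact (no clipping in the construction)
  v <- make_phenotype_vectors(2, 16, distance = 1, seed = 2)
  expect_equal(sqrt(sum((v[[1]] - v[[2]])^2)), 1, tolerance = 1e-9)

  expect_error(make_phenotype_vectors(5, 4, 0.1), "W must be at least")
  expect_error(make_phenotype_vectors(2, 4, 1.5), "not achievable")
})

test_that("patient simulation follows the bit-code Gaussian mixture", {
  spec <- tiny_spec(sigma = 1e-4, cells_per_patient = 2000L)
  vec <- c(0.4, 0.3, 0.2, 0.1)
  p <- simulate_patient(vec, spec, "P1", seed = 5)

  # noiseless limit: thresholding each marker at the midpoint re-encodes
  # the true type codes exactly
  mid <- (spec$mu_low + spec$mu_high) / 2
  bits <- (p$values > mid) * 1L
  decoded <- bits %*% 2L^(seq_len(spec$n_markers) - 1L)
  expect_identical(as.integer(decoded), p$true_cell_types)

  # one-hot on type 3 (binary 11): every marker is in the high state
  p3 <- simulate_patient(c(0, 0, 0, 1), spec, "P2", seed = 6)
  expect_true(all(p3$true_cell_types == 3L))
  expect_true(all(abs(p3$values - spec$mu_high) < 0.01))

  expect_error(simulate_patient(c(0.5, 0.5, 0.5, 0.5), spec, "bad"),
               "probability")
})

test_that("empirical type frequencies converge to the class vector", {
  spec <- tiny_spec(cells_per_patient = 10000L)
  p <- simulate_patient(rep(0.25, 4), spec, "P1", seed = 42)
  freq <- tabulate(p$true_cell_types + 1L, 4) / 10000
  expect_true(max(abs(freq - 0.25)) < 0.02)
})

test_that("pooled marker marginals recover the mixture component means", {
  spec <- tiny_spec(patients_per_phenotype = 4L, cells_per_patient = 5000L,
                    sigma = 0.2, distance = 0.3)
  co <- simulate_cohort(spec)
  pooled <- do.call(rbind, lapply(co$patients, `[[`, "values"))
  types <- unlist(lapply(co$patients, `[[`, "true_cell_types"))
  for (j in 1:2) {
    bit <- bitwAnd(bitwShiftR(types, j - 1L), 1L)
    for (b in 0:1) {
      x <- pooled[bit == b, j]
      mu <- if (b == 1) spec$mu_high else spec$mu_low
      se <- spec$sigma / sqrt(length(x))
      expect_lt(abs(mean(x) - mu), 3 * se)
    }
  }
})

test_that("cohorts are balanced and a pure function of the spec", {
  spec <- tiny_spec(seed = 21)
  co1 <- simulate_cohort(spec)
  expect_length(co1$patients, 12)
  expect_equal(as.vector(table(co1$labels)), c(6, 6))

  co2 <- simulate_cohort(tiny_spec(seed = 21))
  expect_identical(co1$patients[[7]]$values, co2$patients[[7]]$values)
  expect_identical(co1$labels, co2$labels)

  co3 <- simulate_cohort(tiny_spec(seed = 22))
  expect_false(identical(co1$patients[[1]]$values, co3$patients[[1]]$values))
})

test_that("a patient's cells are invariant to cohort size", {
  co_small <- simulate_cohort(tiny_spec(patients_per_phenotype = 2L))
  co_large <- simulate_cohort(tiny_spec(patients_per_phenotype = 6L))
  expect_identical(co_small$patients[[1]]$values,
                   co_large$patients[[1]]$values)
  expect_identical(co_small$patients[[2]]$true_cell_types,
                   co_large$patients[[2]]$true_cell_types)
})

test_that("ground-truth class count vectors separate at high distance", {
  spec <- cohort_spec(n_markers = 4, n_phenotypes = 2,
                      patients_per_phenotype = 10, cells_per_patient = 1000,
                      sigma = 0.1, distance = 1, seed = 9)
  co <- simulate_cohort(spec)
  freqs <- t(vapply(co$patients, function(p) {
    tabulate(p$true_cell_types + 1L, 16) / length(p$true_cell_types)
  }, numeric(16)))
  centroids <- rbind(colMeans(freqs[co$labels == 1, ]),
                     colMeans(freqs[co$labels == 2, ]))
  d2 <- as.matrix(dist(rbind(centroids, freqs)))[-(1:2), 1:2]
  nearest <- max.col(-d2)
  expect_equal(nearest, co$labels)
})

test_that("cohort round-trips through the manifest format", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(tiny_spec(patients_per_phenotype = 2L,
                                  cells_per_patient = 50L))
  write_cohort(co, dir)
  back <- read_cohort(file.path(dir, "manifest.tsv"))
  expect_length(back$patients, 4)
  expect_equal(back$labels, co$labels)
  expect_equal(back$patients[[3]]$values, co$patients[[3]]$values,
               tolerance = 1e-12, ignore_attr = TRUE)
})
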