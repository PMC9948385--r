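test_that("counts expand to canonical token lists", {
  cm <- as_count_matrix(rbind(c(2L, 0L, 1L), c(0L, 0L, 0L), c(1L, 1L, 1L)))
  tokens <- counts_to_tokens(cm)
  expect_identical(tokens[[1]], c(0L, 0L, 2L))
  expect_identical(tokens[[2]], integer(0))
  expect_identical(tokens[[3]], c(0L, 1L, 2L))
  expect_equal(sum(lengths(tokens)), sum(cm))
})

test_that("the full conditional matches the collapsed-Gibbs formula", {
  # hand-built decremented state: W = 2, K = 2, alpha = beta = 1,
  # Cwk = [[1,0],[0,1]], Cdk_d = (1,1); for token w = 0:
  # word factor (2/3, 1/3), doc factor constant => probs (2/3, 1/3)
  hp <- lda_hyperparams(K = 2, alpha = 1, beta = 1, n_iterations = 10,
                        n_burnin = 5)
  state <- list(tokens = list(c(0L, 1L, 0L)), z = list(c(1L, 2L, 1L)),
                W = 2L, K = 2L,
                Cwk = matrix(c(1L, 0L, 0L, 1L), 2, 2),
                Cdk = matrix(c(1L, 1L), 1, 2),
                topic_totals = c(1L, 1L), doc_totals = 2L)
  p <- conditional_topic_probs(state, d = 1, w = 0, hp)
  expect_equal(p, c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-12)

  # single topic: probability 1
  hp1 <- lda_hyperparams(K = 1, n_iterations = 10, n_burnin = 0)
  s1 <- list(tokens = list(0L), z = list(1L), W = 2L, K = 1L,
             Cwk = matrix(0L, 2, 1), Cdk = matrix(0L, 1, 1),
             topic_totals = 0L, doc_totals = 0L)
  expect_equal(conditional_topic_probs(s1, 1, 0, hp1), 1)

  # prior-dominated limit approaches uniform
  hp_big <- lda_hyperparams(K = 2, alpha = 1e8, beta = 1e8,
                            n_iterations = 10, n_burnin = 5)
  p_big <- conditional_topic_probs(state, 1, 0, hp_big)
  expect_equal(p_big, c(0.5, 0.5), tolerance = 1e-6)

  bad <- state
  bad$Cwk[1, 1] <- -1L
  expect_error(conditional_topic_probs(bad, 1, 0, hp), "bookkeeping")
})

test_that("a Gibbs sweep keeps the count matrices consistent", {
  cm <- as_count_matrix(rbind(c(3L, 1L, 0L), c(0L, 2L, 2L)))
  hp <- lda_hyperparams(K = 3, n_iterations = 10, n_burnin = 5, seed = 2)
  state <- init_gibbs_state(cm, hp)

  set.seed(99)
  state <- gibbs_sweep(state, hp)
  rebuilt <- phenotopics:::recount_state(
    list(tokens = state$tokens, z = state$z, W = state$W, K = state$K)
  )
  expect_identical(state$Cwk, rebuilt$Cwk)
  expect_identical(state$Cdk, rebuilt$Cdk)
  expect_equal(unname(state$doc_totals), unname(rowSums(cm)))

  # reproducible under the same RNG state
  s1 <- init_gibbs_state(cm, hp); set.seed(7); s1 <- gibbs_sweep(s1, hp)
  s2 <- init_gibbs_state(cm, hp); set.seed(7); s2 <- gibbs_sweep(s2, hp)
  expect_identical(s1$z, s2$z)

  # K = 1: counts invariant, all topics 1
  hp1 <- lda_hyperparams(K = 1, n_iterations = 10, n_burnin = 5)
  st1 <- init_gibbs_state(cm, hp1)
  st1b <- gibbs_sweep(st1, hp1)
  expect_identical(st1b$Cwk, st1$Cwk)
  expect_true(all(unlist(st1b$z) == 1L))
})

test_that("fit_lda separates documents with disjoint vocabularies", {
  cm <- as_count_matrix(rbind(c(5L, 0L), c(0L, 5L)))
  hp <- lda_hyperparams(K = 2, alpha = 0.1, beta = 0.1,
                        n_iterations = 400, n_burnin = 200, thin = 2,
                        seed = 3)
  fit <- fit_lda(cm, hp)
  theta <- fit$model$theta
  phi <- fit$model$phi
  expect_equal(unname(rowSums(theta)), c(1, 1), tolerance = 1e-9)
  expect_equal(unname(rowSums(phi)), c(1, 1), tolerance = 1e-9)
  expect_true(all(theta > 0) && all(phi > 0))

  top <- max.col(theta)
  expect_true(top[1] != top[2])
  expect_gt(theta[1, top[1]], 0.9)
  expect_gt(theta[2, top[2]], 0.9)
  expect_gt(phi[top[1], 1], 0.9)
  expect_gt(phi[top[2], 2], 0.9)
})

test_that("fit_lda with one topic has an exact closed form", {
  cm <- as_count_matrix(rbind(c(4L, 1L), c(2L, 3L)))
  hp <- lda_hyperparams(K = 1, beta = 0.5, n_iterations = 20, n_burnin = 10,
                        seed = 1)
  fit <- fit_lda(cm, hp)
  expect_equal(unname(fit$model$theta[, 1]), c(1, 1))
  n_w <- colSums(cm)
  expect_equal(unname(fit$model$phi[1, ]),
               unname((n_w + 0.5) / (sum(n_w) + 2 * 0.5)), tolerance = 1e-12)
})

test_that("fit_lda is deterministic given the seed and rejects empties", {
  cm <- as_count_matrix(rbind(c(3L, 2L), c(1L, 4L)))
  hp <- lda_hyperparams(K = 2, n_iterations = 50, n_burnin = 20, seed = 5)
  f1 <- fit_lda(cm, hp)
  f2 <- fit_lda(cm, hp)
  expect_identical(f1$model$theta, f2$model$theta)
  expect_identical(f1$state$z, f2$state$z)

  empty <- as_count_matrix(matrix(0L, 2, 3))
  expect_error(fit_lda(empty, hp), "empty")
})

test_that("collapsed log-likelihood matches a chain-rule oracle", {
  # empty corpus and the forced single-token case are exactly 0
  hp <- lda_hyperparams(K = 1, alpha = 1, beta = 0.7, n_iterations = 10,
                        n_burnin = 5)
  empty <- phenotopics:::recount_state(
    list(tokens = list(), z = list(), W = 1L, K = 1L)
  )
  expect_equal(log_likelihood(empty, hp), 0)
  one <- phenotopics:::recount_state(
    list(tokens = list(0L), z = list(1L), W = 1L, K = 1L)
  )
  expect_equal(log_likelihood(one, hp), 0)

  # 5-token corpus: sequential product of predictive probabilities
  hp2 <- lda_hyperparams(K = 2, alpha = 0.8, beta = 0.3, n_iterations = 10,
                         n_burnin = 5)
  tokens <- list(c(0L, 2L), c(1L, 1L, 0L))
  z <- list(c(1L, 2L), c(2L, 1L, 2L))
  W <- 3L; K <- 2L
  Cwk <- matrix(0, W, K); Cdk <- matrix(0, 2, K)
  tot_k <- numeric(K); tot_d <- numeric(2)
  ll_chain <- 0
  for (d in 1:2) for (i in seq_along(tokens[[d]])) {
    w1 <- tokens[[d]][i] + 1L; k <- z[[d]][i]
    p_z <- (Cdk[d, k] + 0.8) / (tot_d[d] + K * 0.8)
    p_w <- (Cwk[w1, k] + 0.3) / (tot_k[k] + W * 0.3)
    ll_chain <- ll_chain + log(p_z * p_w)
    Cwk[w1, k] <- Cwk[w1, k] + 1; Cdk[d, k] <- Cdk[d, k] + 1
    tot_k[k] <- tot_k[k] + 1; tot_d[d] <- tot_d[d] + 1
  }
  state <- phenotopics:::recount_state(
    list(tokens = tokens, z = z, W = W, K = K)
  )
  expect_equal(log_likelihood(state, hp2), ll_chain, tolerance = 1e-12)
})

test_that("topic relabeling leaves the collapsed likelihood unchanged", {
  cm <- as_count_matrix(rbind(c(3L, 1L, 2L), c(2L, 2L, 1L)))
  hp <- lda_hyperparams(K = 3, n_iterations = 5, n_burnin = 1, seed = 8)
  state <- init_gibbs_state(cm, hp)
  perm <- c(3L, 1L, 2L)
  permuted <- phenotopics:::recount_state(
    list(tokens = state$tokens, z = lapply(state$z, function(x) perm[x]),
         W = state$W, K = state$K)
  )
  expect_equal(log_likelihood(permuted, hp), log_likelihood(state, hp),
               tolerance = 1e-12)
})
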