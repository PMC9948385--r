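# Shared fixtures and independent oracles.

# Small, fast cohort used across tests.
tiny_spec <- function(..., seed = 11L) {
  defaults <- list(n_markers = 2L, n_phenotypes = 2L,
                   patients_per_phenotype = 6L, cells_per_patient = 400L,
                   sigma = 0.1, distance = 1, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_spec, args)
}

# Independent collapsed joint density, written directly from the
# Dirichlet-multinomial normalizers (no package internals): tokens/docs are
# parallel vectors, z a candidate assignment (all 1-based words here).
oracle_log_joint <- function(word, doc, z, D, W, K, alpha, beta) {
  ll <- 0
  for (k in seq_len(K)) {
    nw <- tabulate(word[z == k], nbins = W)
    ll <- ll + lgamma(W * beta) - W * lgamma(beta) +
      sum(lgamma(nw + beta)) - lgamma(sum(nw) + W * beta)
  }
  for (d in seq_len(D)) {
    nk <- tabulate(z[doc == d], nbins = K)
    ll <- ll + lgamma(K * alpha) - K * lgamma(alpha) +
      sum(lgamma(nk + alpha)) - lgamma(sum(nk) + K * alpha)
  }
  ll
}

# Exact posterior co-assignment probabilities by enumeration over all K^T
# topic assignments of a tiny corpus.
oracle_coassignment <- function(counts, K, alpha, beta) {
  tokens <- counts_to_tokens(counts)
  word <- unlist(tokens) + 1L
  doc <- rep.int(seq_along(tokens), lengths(tokens))
  T_ <- length(word)
  stopifnot(K^T_ <= 2^20)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  logp <- apply(grid, 1, function(z) {
    oracle_log_joint(word, doc, z, max(doc), ncol(counts), K, alpha, beta)
  })
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  co <- matrix(0, T_, T_)
  for (r in seq_len(nrow(grid))) {
    same <- outer(grid[r, ], grid[r, ], `==`)
    co <- co + p[r] * same
  }
  co
}

# Draw a corpus from a known 2-topic generative model.
generate_lda_corpus <- function(D, n_tokens, phi, alpha = 0.2, seed = 1L) {
  set.seed(seed)
  K <- nrow(phi); W <- ncol(phi)
  theta <- matrix(stats::rgamma(D * K, alpha), D, K)
  theta <- theta / rowSums(theta)
  counts <- matrix(0L, D, W)
  for (d in seq_len(D)) {
    zd <- sample.int(K, n_tokens, replace = TRUE, prob = theta[d, ])
    for (k in seq_len(K)) {
      nk <- sum(zd == k)
      if (nk > 0) {
        wd <- sample.int(W, nk, replace = TRUE, prob = phi[k, ])
        counts[d, ] <- counts[d, ] + tabulate(wd, nbins = W)
      }
    }
  }
  list(counts = as_count_matrix(counts), theta = theta, phi = phi)
}

total_variation <- function(p, q) 0.5 * sum(abs(p - q))

# Mean majority-vote accuracy of the full pipeline over several seeds.
pipeline_accuracy <- function(n_markers, n_phenotypes, distance, seeds,
                              patients = 20L, cells = 1000L, sigma = 0.25,
                              n_iterations = 500L, n_burnin = 200L) {
  vapply(seeds, function(s) {
    spec <- cohort_spec(n_markers = n_markers, n_phenotypes = n_phenotypes,
                        patients_per_phenotype = patients,
                        cells_per_patient = cells, sigma = sigma,
                        distance = distance, seed = s)
    co <- simulate_cohort(spec)
    res <- double_cluster(co, K_topics = n_phenotypes, seed = s + 1000L,
                          n_iterations = n_iterations, n_burnin = n_burnin)
    majority_vote_accuracy(res$assignments, co$labels)$accuracy
  }, 0)
}
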