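#' Hyperparameters and chain schedule for the collapsed Gibbs LDA
#'
#' `alpha` is the symmetric Dirichlet concentration of the document-topic
#' (patient-phenotype) distributions theta; the larger it is, the more a
#' patient is spread across phenotypes. `beta` is the concentration of the
#' topic-word (phenotype-cell-type) distributions phi; small values favour
#' crisp cell-type signatures per phenotype. Defaults (`alpha = 1`,
#' `beta = 0.1`) suit cohorts of ~100 short "documents" with modest
#' vocabularies. The chain runs `n_iterations` full sweeps; samples after
#' `n_burnin` sweeps, every `thin` sweeps, are averaged into the reported
#' theta/phi estimates.
#'
#' @param K Number of topics (patient clusters), >= 1.
#' @param alpha Document-topic Dirichlet concentration (> 0).
#' @param beta Topic-word Dirichlet concentration (> 0).
#' @param n_iterations Total Gibbs sweeps.
#' @param n_burnin Sweeps discarded before estimates are collected
#'   (`0 <= n_burnin < n_iterations`).
#' @param thin Keep every `thin`-th post-burn-in sweep.
#' @param seed Integer seed driving initialization and sampling.
#' @return An object of class `lda_hyperparams`.
#' @export
lda_hyperparams <- function(K, alpha = 1, beta = 0.1, n_iterations = 500L,
                            n_burnin = 200L, thin = 10L, seed = 1L) {
  stopifnot(K >= 1, K == round(K), alpha > 0, beta > 0, thin >= 1)
  if (!(n_burnin >= 0 && n_burnin < n_iterations)) {
    stop("need 0 <= n_burnin < n_iterations")
  }
  structure(
    list(K = as.integer(K), alpha = alpha, beta = beta,
         n_iterations = as.integer(n_iterations),
         n_burnin = as.integer(n_burnin), thin = as.integer(thin),
         seed = as.integer(seed)),
    class = "lda_hyperparams"
  )
}

#' Expand a count matrix into per-document token lists
#'
#' Document d lists word id `w` (0-based, matching count-matrix column
#' order) repeated `counts[d, w]` times, in ascending word order. The order
#' is canonical but immaterial: tokens are exchangeable under the model.
#'
#' @param counts A `count_matrix`.
#' @return A list of integer vectors, one per document; all-zero rows give
#'   empty documents.
#' @export
counts_to_tokens <- function(counts) {
  counts <- as_count_matrix(counts)
  W <- ncol(counts)
  lapply(seq_len(nrow(counts)), function(d) {
    rep.int(0:(W - 1L), counts[d, ])
  })
}

#' Initialize a Gibbs state with uniform random topic assignments
#'
#' @param counts A `count_matrix`.
#' @param hp An [lda_hyperparams()].
#' @return A `gibbs_state`: `tokens`, `z` (per-token topics, 1-based),
#'   `Cwk` (W x K word-topic counts), `Cdk` (D x K document-topic counts),
#'   `topic_totals`, `doc_totals`.
#' @export
init_gibbs_state <- function(counts, hp) {
  tokens <- counts_to_tokens(counts)
  if (sum(lengths(tokens)) == 0L) stop("corpus is empty: no tokens at all")
  set.seed(hp$seed)
  z <- lapply(tokens, function(tk) {
    sample.int(hp$K, length(tk), replace = TRUE)
  })
  state <- list(tokens = tokens, z = z, W = ncol(counts), K = hp$K,
                doc_ids = rownames(counts))
  recount_state(state)
}

# Rebuild all count matrices from (tokens, z); also the recount oracle used
# by the tests.
recount_state <- function(state) {
  W <- state$W; K <- state$K
  Cwk <- matrix(0L, W, K)
  Cdk <- matrix(0L, length(state$tokens), K)
  for (d in seq_along(state$tokens)) {
    tk <- state$tokens[[d]]; zz <- state$z[[d]]
    for (i in seq_along(tk)) {
      Cwk[tk[i] + 1L, zz[i]] <- Cwk[tk[i] + 1L, zz[i]] + 1L
      Cdk[d, zz[i]] <- Cdk[d, zz[i]] + 1L
    }
  }
  state$Cwk <- Cwk
  state$Cdk <- Cdk
  state$topic_totals <- colSums(Cwk)
  state$doc_totals <- rowSums(Cdk)
  structure(state, class = "gibbs_state")
}

#' Full conditional over topics for one token
#'
#' Evaluates the collapsed-Gibbs full conditional
#' `p(z_i = k | z_-i, w_i = w, d_i = d) ∝`
#' `(Cwk[w,k] + beta) / (topic_totals[k] + W beta) *`
#' `(Cdk[d,k] + alpha) / (doc_totals[d] + K alpha)`,
#' where the counts in `state` must already exclude token i (the caller
#' decrements before evaluating). The document-side denominator is constant
#' in k but kept for clarity; the vector is normalized before returning.
#'
#' @param state A `gibbs_state` with token i removed from the counts.
#' @param d Document index (1-based).
#' @param w Word id (0-based).
#' @param hp An [lda_hyperparams()].
#' @return A length-K probability vector, strictly positive, summing to 1.
#' @export
conditional_topic_probs <- function(state, d, w, hp) {
  if (any(state$Cwk < 0L) || any(state$Cdk < 0L)) {
    stop("negative count in Gibbs state: decrement bookkeeping bug")
  }
  num_w <- (state$Cwk[w + 1L, ] + hp$beta) /
    (state$topic_totals + state$W * hp$beta)
  num_d <- (state$Cdk[d, ] + hp$alpha) /
    (state$doc_totals[d] + hp$K * hp$alpha)
  p <- num_w * num_d
  p / sum(p)
}

#' One full Gibbs sweep over every token (reference implementation)
#'
#' Resamples each token once in deterministic document-major order:
#' decrement its counts, draw a topic from [conditional_topic_probs()],
#' increment. Uses R's global RNG; seed with `set.seed()` for
#' reproducibility. This pure-R sweep is meant for small corpora and
#' testing; [fit_lda()] runs the same algorithm in compiled code.
#'
#' @param state A consistent `gibbs_state`.
#' @param hp An [lda_hyperparams()].
#' @return The updated `gibbs_state`.
#' @export
gibbs_sweep <- function(state, hp) {
  for (d in seq_along(state$tokens)) {
    tk <- state$tokens[[d]]
    for (i in seq_along(tk)) {
      w1 <- tk[i] + 1L
      k_old <- state$z[[d]][i]
      state$Cwk[w1, k_old] <- state$Cwk[w1, k_old] - 1L
      state$Cdk[d, k_old] <- state$Cdk[d, k_old] - 1L
      state$topic_totals[k_old] <- state$topic_totals[k_old] - 1L
      state$doc_totals[d] <- state$doc_totals[d] - 1L
      p <- conditional_topic_probs(state, d, tk[i], hp)
      k_new <- sample.int(hp$K, 1L, prob = p)
      state$z[[d]][i] <- k_new
      state$Cwk[w1, k_new] <- state$Cwk[w1, k_new] + 1L
      state$Cdk[d, k_new] <- state$Cdk[d, k_new] + 1L
      state$topic_totals[k_new] <- state$topic_totals[k_new] + 1L
      state$doc_totals[d] <- state$doc_totals[d] + 1L
    }
  }
  state
}

#' Fit LDA to a count matrix by collapsed Gibbs sampling
#'
#' Initializes topic assignments uniformly at random, runs
#' `hp$n_iterations` full sweeps of the collapsed Gibbs sampler in compiled
#' code, and estimates the conditional distributions from the smoothed
#' counts, `theta[d,k] = (Cdk + alpha) / (n_d + K alpha)` and
#' `phi[k,w] = (Cwk + beta) / (n_k + W beta)`, averaged over the retained
#' post-burn-in samples. Fully reproducible from `hp$seed`.
#'
#' @param counts A `count_matrix` (documents x words).
#' @param hp An [lda_hyperparams()].
#' @return A list with components `model` (class `topic_model`: `theta`
#'   D x K, `phi` K x W, `loglik_trace` of the collapsed joint
#'   log P(w, z | alpha, beta) per sweep) and `state` (the final
#'   `gibbs_state`).
#' @export
#' @examples
#' counts <- as_count_matrix(rbind(c(20, 0), c(0, 20)))
#' fit <- fit_lda(counts, lda_hyperparams(K = 2, n_iterations = 100,
#'                                        n_burnin = 50, seed = 7))
#' round(fit$model$theta, 2)
fit_lda <- function(counts, hp) {
  counts <- as_count_matrix(counts)
  stopifnot(inherits(hp, "lda_hyperparams"))
  tokens <- counts_to_tokens(counts)
  n_tok <- sum(lengths(tokens))
  if (n_tok == 0L) stop("corpus is empty: no tokens at all")
  word <- unlist(tokens)
  doc <- rep.int(seq_along(tokens) - 1L, lengths(tokens))
  set.seed(hp$seed)
  z0 <- sample.int(hp$K, n_tok, replace = TRUE) - 1L
  res <- gibbs_lda_cpp(word, doc, nrow(counts), ncol(counts), hp$K,
                       hp$alpha, hp$beta, hp$n_iterations, hp$n_burnin,
                       hp$thin, z0, FALSE)
  theta <- res$theta
  phi <- res$phi
  rownames(theta) <- rownames(counts)
  colnames(phi) <- colnames(counts)
  model <- structure(
    list(theta = theta, phi = phi, loglik_trace = as.numeric(res$loglik),
         hp = hp),
    class = "topic_model"
  )
  lens <- lengths(tokens)
  z <- vector("list", length(tokens))
  pos <- 0L
  for (d in seq_along(tokens)) {
    z[[d]] <- as.integer(res$z[pos + seq_len(lens[d])]) + 1L
    pos <- pos + lens[d]
  }
  state <- recount_state(list(tokens = tokens, z = z,
                              W = ncol(counts), K = hp$K,
                              doc_ids = rownames(counts)))
  list(model = model, state = state)
}

#' @export
print.topic_model <- function(x, ...) {
  cat(sprintf("LDA topic model: %d documents, %d topics, %d words\n",
              nrow(x$theta), ncol(x$theta), ncol(x$phi)))
  cat(sprintf("  alpha = %.3g, beta = %.3g, %d sweeps (%d burn-in)\n",
              x$hp$alpha, x$hp$beta, x$hp$n_iterations, x$hp$n_burnin))
  invisible(x)
}

#' Collapsed joint log-likelihood log P(w, z | alpha, beta)
#'
#' Product of Dirichlet-multinomial normalizers in log-gamma form: one term
#' per topic for the word counts, one per document for the topic counts.
#' Useful as a convergence monitor for the Gibbs chain.
#'
#' @param state A consistent `gibbs_state`.
#' @param hp An [lda_hyperparams()].
#' @return A finite scalar (0 for an empty corpus).
#' @export
log_likelihood <- function(state, hp) {
  W <- state$W; K <- hp$K
  a <- hp$alpha; b <- hp$beta
  word_term <- sum(vapply(seq_len(K), function(k) {
    lgamma(W * b) - W * lgamma(b) +
      sum(lgamma(state$Cwk[, k] + b)) -
      lgamma(state$topic_totals[k] + W * b)
  }, 0))
  doc_term <- sum(vapply(seq_along(state$doc_totals), function(d) {
    lgamma(K * a) - K * lgamma(a) +
      sum(lgamma(state$Cdk[d, ] + a)) -
      lgamma(state$doc_totals[d] + K * a)
  }, 0))
  word_term + doc_term
}

#' Token co-assignment frequencies under the Gibbs posterior
#'
#' Runs the collapsed Gibbs sampler and records, for every pair of tokens,
#' the fraction of retained samples in which the two tokens carry the same
#' topic. Intended for small corpora (the matrix is tokens x tokens); the
#' result is directly comparable to the exact collapsed posterior obtained
#' by enumerating all `K^T` assignments.
#'
#' @param counts A `count_matrix` with a small grand total.
#' @param hp An [lda_hyperparams()].
#' @return A symmetric tokens x tokens matrix of co-assignment frequencies
#'   (unit diagonal), tokens in document-major ascending-word order.
#' @export
sample_coassignment <- function(counts, hp) {
  counts <- as_count_matrix(counts)
  tokens <- counts_to_tokens(counts)
  n_tok <- sum(lengths(tokens))
  if (n_tok == 0L) stop("corpus is empty: no tokens at all")
  if (n_tok > 200L) stop("co-assignment tracking is for small corpora")
  word <- unlist(tokens)
  doc <- rep.int(seq_along(tokens) - 1L, lengths(tokens))
  set.seed(hp$seed)
  z0 <- sample.int(hp$K, n_tok, replace = TRUE) - 1L
  res <- gibbs_lda_cpp(word, doc, nrow(counts), ncol(counts), hp$K,
                       hp$alpha, hp$beta, hp$n_iterations, hp$n_burnin,
                       hp$thin, z0, TRUE)
  res$coassign
}

#' Serialize a topic model to JSON
#'
#' @param model A `topic_model`.
#' @param path Output JSON path.
#' @export
write_topic_model <- function(model, path) {
  jsonlite::write_json(
    list(theta = model$theta, phi = model$phi,
         loglik_trace = model$loglik_trace,
         hyperparams = unclass(model$hp),
         doc_ids = rownames(model$theta), words = colnames(model$phi)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
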