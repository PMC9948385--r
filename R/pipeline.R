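#' Run the full double-clustering workflow
#'
#' Orchestrates the complete pipeline: per-patient cell matrices are pooled,
#' Z-scored and K-means-clustered into a cell-type vocabulary
#' ([fit_cell_types()]), every cell is assigned and counted per patient
#' ([assign_and_count()]), and the resulting patients x cell-types count
#' matrix is modelled with LDA ([fit_lda()]). Patients are clustered by the
#' argmax of their topic distribution theta (ties go to the lowest topic
#' index), and each cell type receives a posterior distribution over
#' phenotype clusters ([celltype_topic_distribution()]). A count matrix —
#' e.g. a genus abundance table — can be supplied directly, in which case
#' the cell-typing stage is skipped and `cell_model` is `NULL`.
#'
#' @param x A `sim_cohort`, a list of `patient_cells`, or a `count_matrix`.
#' @param K_topics Number of patient clusters (LDA topics).
#' @param W Vocabulary size for the cell-typing stage; defaults to
#'   `2^n_markers`. Ignored for direct count input.
#' @param alpha,beta,n_iterations,n_burnin,thin LDA settings, see
#'   [lda_hyperparams()].
#' @param seed Seed for the LDA chain.
#' @param celltype_seed Seed for the K-means cell typing (defaults to
#'   `seed`); the pair `(celltype_seed, seed)` makes the run end-to-end
#'   reproducible.
#' @return An object of class `double_clustering`: `assignments` (1-based
#'   patient cluster per patient), `theta` (D x K), `phi` (K x W),
#'   `celltype_topic` (W x K, `P(topic | cell type)`), `counts`,
#'   `cell_model` (or `NULL`), `loglik_trace` and `config` (the resolved
#'   settings).
#' @export
#' @examples
#' spec <- cohort_spec(n_markers = 2, n_phenotypes = 2, distance = 1,
#'                     patients_per_phenotype = 5, cells_per_patient = 300,
#'                     sigma = 0.1)
#' res <- double_cluster(simulate_cohort(spec), K_topics = 2,
#'                       n_iterations = 100, n_burnin = 50)
#' table(res$assignments)
double_cluster <- function(x, K_topics, W = NULL, alpha = 1, beta = 0.1,
                           n_iterations = 500L, n_burnin = 200L, thin = 10L,
                           seed = 1L, celltype_seed = seed) {
  cell_model <- NULL
  if (inherits(x, "count_matrix")) {
    counts <- x
  } else {
    patients <- cohort_patients(x)
    if (is.null(W)) W <- 2L^ncol(patients[[1L]]$values)
    cell_model <- fit_cell_types(patients, W = W, seed = celltype_seed)
    counts <- assign_and_count(patients, cell_model)
  }
  if (K_topics > nrow(counts)) {
    stop("more clusters than patients: K_topics must not exceed D")
  }
  hp <- lda_hyperparams(K = K_topics, alpha = alpha, beta = beta,
                        n_iterations = n_iterations, n_burnin = n_burnin,
                        thin = thin, seed = seed)
  fit <- fit_lda(counts, hp)
  theta <- fit$model$theta
  phi <- fit$model$phi
  structure(
    list(
      assignments = max.col(theta, ties.method = "first"),
      theta = theta,
      phi = phi,
      celltype_topic = celltype_topic_distribution(phi, theta, counts),
      counts = counts,
      cell_model = cell_model,
      loglik_trace = fit$model$loglik_trace,
      config = list(K_topics = K_topics, W = ncol(counts), alpha = alpha,
                    beta = beta, n_iterations = n_iterations,
                    n_burnin = n_burnin, thin = thin, seed = seed,
                    celltype_seed = celltype_seed,
                    direct_counts = is.null(cell_model))
    ),
    class = "double_clustering"
  )
}

#' @export
print.double_clustering <- function(x, ...) {
  cat(sprintf("Double clustering: %d patients -> %d clusters over %d %s\n",
              nrow(x$theta), ncol(x$theta), ncol(x$phi),
              if (x$config$direct_counts) "features" else "cell types"))
  print(table(cluster = x$assignments))
  invisible(x)
}

#' Posterior distribution of phenotype clusters per cell type
#'
#' Bayes-inverts the topic-word distributions: `P(topic k | word w) ∝
#' phi[k, w] * m_k`, where `m_k` is the empirical topic mass
#' `sum_d theta[d, k] * n_d / sum_d n_d` (documents weighted by length).
#' Answers "which phenotype cluster does this cell population point to?";
#' the forward distributions `phi` answer the converse.
#'
#' @param phi K x W topic-word matrix.
#' @param theta D x K document-topic matrix.
#' @param counts The `count_matrix` the model was fitted to (supplies
#'   document lengths).
#' @return A W x K matrix with rows summing to 1.
#' @export
celltype_topic_distribution <- function(phi, theta, counts) {
  stopifnot(ncol(theta) == nrow(phi), nrow(theta) == nrow(counts))
  len <- rowSums(counts)
  if (sum(len) == 0) stop("zero total mass: empty corpus")
  m <- colSums(theta * len) / sum(len)
  post <- t(phi) * rep(m, each = ncol(phi))
  post / rowSums(post)
}

#' Topic posterior for a single cell (token)
#'
#' The canonical LDA token posterior `P(z = k | w, d) ∝ phi[k, w] *
#' theta[d, k]`. With a confidence threshold (0.9 by default downstream)
#' this flags cells whose phenotype-cluster assignment is unambiguous, e.g.
#' for highlighting on an embedding.
#'
#' @param d Document (patient) index, 1-based.
#' @param w Word (cell type) id, 0-based.
#' @param theta D x K document-topic matrix.
#' @param phi K x W topic-word matrix.
#' @return A length-K probability vector.
#' @export
cell_topic_posterior <- function(d, w, theta, phi) {
  p <- phi[, w + 1L] * theta[d, ]
  p / sum(p)
}

#' Flag high-confidence cells
#'
#' Applies [cell_topic_posterior()] to every (patient, cell type) pair in a
#' count matrix and reports which cells exceed a posterior confidence
#' threshold for some cluster.
#'
#' @param result A [double_cluster()] result.
#' @param threshold Posterior confidence cutoff (default 0.9).
#' @return A data frame with one row per (patient, cell type) pair holding
#'   nonzero counts: `patient`, `cell_type` (0-based), `n_cells`,
#'   `topic` (argmax cluster), `confidence`, `confident` (logical).
#' @export
confident_cells <- function(result, threshold = 0.9) {
  stopifnot(inherits(result, "double_clustering"))
  counts <- result$counts
  idx <- which(counts > 0, arr.ind = TRUE)
  post <- t(apply(idx, 1, function(ij) {
    cell_topic_posterior(ij[1L], ij[2L] - 1L, result$theta, result$phi)
  }))
  data.frame(
    patient = rownames(counts)[idx[, 1L]],
    cell_type = idx[, 2L] - 1L,
    n_cells = counts[idx],
    topic = max.col(post, ties.method = "first"),
    confidence = apply(post, 1, max),
    confident = apply(post, 1, max) >= threshold,
    row.names = NULL
  )
}
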