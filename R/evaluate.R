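#' Clustering accuracy under the majority-vote mapping
#'
#' Cluster labels from an unsupervised run are arbitrary (the label
#' switching problem), so each predicted cluster is first mapped to the
#' most frequent true label among its members (ties broken toward the label
#' that sorts first); accuracy is the fraction of patients whose mapped
#' label matches the truth. Note the mapping may send two clusters to the
#' same label — for balanced two-class truth this bounds accuracy below at
#' 0.5.
#'
#' @param pred Integer vector of predicted cluster ids.
#' @param truth Vector of true class labels (any type with a sort order).
#' @return An object of class `evaluation_report`: `accuracy`,
#'   `cluster_to_label` (named mapping), `n`.
#' @export
#' @examples
#' majority_vote_accuracy(c(1, 1, 2, 2), c("A", "A", "A", "B"))$accuracy
majority_vote_accuracy <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("pred and truth must have the same length")
  }
  stopifnot(length(pred) >= 1)
  clusters <- sort(unique(pred))
  mapping <- vapply(clusters, function(cl) {
    tab <- table(truth[pred == cl])
    labs <- names(tab)[tab == max(tab)]
    sort(labs)[1L]  # ties -> first label in canonical order
  }, "")
  names(mapping) <- as.character(clusters)
  mapped <- mapping[as.character(pred)]
  structure(
    list(accuracy = mean(mapped == as.character(truth)),
         cluster_to_label = mapping,
         n = length(pred)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Majority-vote accuracy: %.3f (n = %d)\n", x$accuracy, x$n))
  if (!is.null(x$per_fold_accuracies)) {
    cat(sprintf("  %d folds, per-fold sd %.3f\n", x$n_folds,
                stats::sd(x$per_fold_accuracies)))
  }
  invisible(x)
}

#' Balanced repeated-subsampling evaluation
#'
#' For each of `n_folds` repetitions, draws an equal number of patients per
#' class (the minority-class size) uniformly without replacement, runs LDA
#' clustering on the subsample's count rows and scores its majority-vote
#' accuracy. This balances unequal class sizes; folds are independent
#' resamples, not a partition, and the clustering is scored on the sampled
#' set itself (unsupervised — there is no held-out prediction).
#'
#' @param counts A `count_matrix`.
#' @param labels True class per patient (length D).
#' @param K_topics Number of LDA topics per fold.
#' @param n_folds Number of repetitions (default 20).
#' @param seed Integer seed; fold subsamples and chains derive from it.
#' @param ... Further LDA settings passed to [lda_hyperparams()].
#' @return An `evaluation_report` with mean `accuracy`,
#'   `per_fold_accuracies` and `n_folds`.
#' @export
balanced_cv <- function(counts, labels, K_topics, n_folds = 20L, seed = 1L,
                        ...) {
  counts <- as_count_matrix(counts)
  stopifnot(length(labels) == nrow(counts))
  tab <- table(labels)
  if (length(tab) < 2L) stop("need at least 2 classes")
  if (min(tab) < 2L) stop("every class needs at least 2 members")
  m <- min(tab)
  classes <- names(tab)
  acc <- vapply(seq_len(n_folds), function(f) {
    fold_seed <- derive_seed(seed, f)
    set.seed(fold_seed)
    idx <- unlist(lapply(classes, function(cl) {
      sample(which(as.character(labels) == cl), m)
    }))
    hp <- lda_hyperparams(K = K_topics, seed = fold_seed, ...)
    fit <- fit_lda(counts[idx, , drop = FALSE], hp)
    pred <- max.col(fit$model$theta, ties.method = "first")
    majority_vote_accuracy(pred, labels[idx])$accuracy
  }, 0)
  structure(
    list(accuracy = mean(acc), cluster_to_label = NULL,
         per_fold_accuracies = acc, n_folds = as.integer(n_folds),
         n = as.integer(length(classes) * m)),
    class = "evaluation_report"
  )
}

#' K-means baseline for patient clustering
#'
#' The comparison arm: instead of LDA, cluster patients directly by K-means
#' on their cell-type frequency profiles (rows of the count matrix
#' normalized to sum to 1, removing the nuisance of unequal cell totals;
#' set `normalize = FALSE` to cluster raw counts).
#'
#' @param counts A `count_matrix` with D >= K rows.
#' @param K Number of patient clusters.
#' @param seed Integer seed.
#' @param normalize Divide each row by its total first (default TRUE).
#' @return Integer vector of 1-based cluster ids, one per patient, suitable
#'   for [majority_vote_accuracy()].
#' @export
kmeans_patient_baseline <- function(counts, K, seed = 1L, normalize = TRUE) {
  counts <- as_count_matrix(counts)
  if (nrow(counts) < K) stop("D < K: fewer patients than clusters")
  x <- unclass(counts)
  storage.mode(x) <- "double"
  if (normalize) {
    len <- rowSums(x)
    len[len == 0] <- 1
    x <- x / len
  }
  set.seed(seed)
  stats::kmeans(x, centers = K, nstart = 10L, iter.max = 300L)$cluster
}
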