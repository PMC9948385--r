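#' Patient co-assignment frequency matrix
#'
#' Given the cluster assignments from repeated runs, entry (i, j) is the
#' fraction of runs in which patients i and j landed in the same cluster.
#' The matrix is symmetric with unit diagonal and is the similarity that
#' underlies the consensus network.
#'
#' @param runs List of equal-length integer assignment vectors, one per run.
#' @return A D x D numeric matrix with entries in `[0, 1]`.
#' @export
coassignment_matrix <- function(runs) {
  stopifnot(length(runs) >= 1)
  lens <- lengths(runs)
  if (length(unique(lens)) != 1L) {
    stop("all runs must assign the same patients (ragged lengths)")
  }
  D <- lens[1L]
  freq <- matrix(0, D, D)
  for (r in runs) {
    same <- outer(r, r, `==`)
    freq <- freq + same
  }
  freq <- freq / length(runs)
  diag(freq) <- 1
  freq
}

#' Threshold a co-assignment matrix into a consensus network
#'
#' Keeps an edge between two patients when their co-assignment frequency is
#' at least `threshold` (pairs co-clustered in less than that fraction of
#' runs are removed; the boundary value itself is kept). Node degree is
#' recorded for degree-scaled rendering downstream.
#'
#' @param freq Symmetric co-assignment matrix from [coassignment_matrix()].
#' @param threshold Retention cutoff in `[0, 1]` (default 0.30).
#' @param labels Optional per-patient metadata vector (e.g. clinical
#'   condition or enterotype) attached to the nodes.
#' @return An object of class `consensus_network`: `freq`, `threshold`,
#'   `edges` (data frame `i`, `j`, `weight` with `i < j`), `degrees`,
#'   `labels`.
#' @export
build_network <- function(freq, threshold = 0.30, labels = NULL) {
  stopifnot(is.matrix(freq), nrow(freq) == ncol(freq))
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  D <- nrow(freq)
  keep <- which(upper.tri(freq) & freq >= threshold, arr.ind = TRUE)
  edges <- data.frame(i = keep[, 1L], j = keep[, 2L],
                      weight = freq[keep])
  degrees <- tabulate(c(edges$i, edges$j), nbins = D)
  structure(
    list(freq = freq, threshold = threshold, edges = edges,
         degrees = degrees,
         labels = labels %||% rownames(freq) %||% as.character(seq_len(D))),
    class = "consensus_network"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.consensus_network <- function(x, ...) {
  cat(sprintf(
    "Consensus network: %d patients, %d edges at threshold %.2f\n",
    nrow(x$freq), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Build a consensus network from repeated double-clustering runs
#'
#' Executes [double_cluster()] `n_runs` times with consecutive derived
#' seeds (both the K-means and the LDA seed vary by default; set
#' `freeze_cell_typing` to keep one shared vocabulary, which is also the
#' behaviour for direct count input where no cell typing exists), collects
#' the assignment vectors, and thresholds the co-assignment frequencies
#' into a network.
#'
#' @param x Pipeline input: cohort or `count_matrix` (see
#'   [double_cluster()]).
#' @param K_topics Number of topics per run.
#' @param n_runs Number of repeated runs (default 40).
#' @param base_seed First seed; run r uses `base_seed + r - 1`.
#' @param threshold Edge retention cutoff (default 0.30).
#' @param labels Optional node metadata (true condition, enterotype, ...).
#' @param freeze_cell_typing Fit the cell-type vocabulary once with
#'   `base_seed` and reuse it across runs (default FALSE).
#' @param ... Further settings passed to [double_cluster()].
#' @return A `consensus_network`; the per-run assignments are attached as
#'   attribute `"runs"`.
#' @export
run_consensus <- function(x, K_topics, n_runs = 40L, base_seed = 1L,
                          threshold = 0.30, labels = NULL,
                          freeze_cell_typing = FALSE, ...) {
  stopifnot(n_runs >= 1)
  input <- x
  if (freeze_cell_typing && !inherits(x, "count_matrix")) {
    patients <- cohort_patients(x)
    W <- 2L^ncol(patients[[1L]]$values)
    model <- fit_cell_types(patients, W = W, seed = base_seed)
    input <- assign_and_count(patients, model)
  }
  runs <- lapply(seq_len(n_runs), function(r) {
    double_cluster(input, K_topics = K_topics,
                   seed = base_seed + r - 1L, ...)$assignments
  })
  freq <- coassignment_matrix(runs)
  ids <- if (inherits(input, "count_matrix")) rownames(input)
         else vapply(cohort_patients(input), `[[`, "", "patient_id")
  dimnames(freq) <- list(ids, ids)
  net <- build_network(freq, threshold = threshold, labels = labels)
  attr(net, "runs") <- runs
  net
}

#' Connected components of a consensus network
#'
#' @param net A `consensus_network`.
#' @return Integer component membership per patient.
#' @export
network_components <- function(net) {
  g <- consensus_igraph(net)
  igraph::components(g)$membership
}

# Internal: consensus_network -> igraph with node metadata.
consensus_igraph <- function(net) {
  D <- nrow(net$freq)
  g <- igraph::make_empty_graph(n = D, directed = FALSE)
  igraph::V(g)$name <- rownames(net$freq) %||% as.character(seq_len(D))
  igraph::V(g)$label <- as.character(net$labels)
  igraph::V(g)$degree_scaled <- net$degrees
  if (nrow(net$edges) > 0) {
    g <- igraph::add_edges(g, rbind(net$edges$i, net$edges$j),
                           weight = net$edges$weight)
  }
  g
}

#' Export a consensus network
#'
#' Writes GraphML (node attributes: id, label, degree; edge weights) via
#' igraph, plus a plain edge-list TSV (`i`, `j`, `weight`) and the full
#' frequency matrix as TSV.
#'
#' @param net A `consensus_network`.
#' @param prefix Output path prefix; writes `<prefix>.graphml`,
#'   `<prefix>_edges.tsv`, `<prefix>_freq.tsv`.
#' @return Invisibly, the GraphML path.
#' @export
write_network <- function(net, prefix) {
  g <- consensus_igraph(net)
  graphml <- paste0(prefix, ".graphml")
  igraph::write_graph(g, graphml, format = "graphml")
  utils::write.table(net$edges, paste0(prefix, "_edges.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(net$freq, paste0(prefix, "_freq.tsv"), sep = "\t",
                     quote = FALSE)
  invisible(graphml)
}
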