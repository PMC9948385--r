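#' Fit a shared cell-type vocabulary by pooled K-means
#'
#' Concatenates the cells of all patients, standardizes every marker with a
#' pooled Z-score (mean and standard deviation computed over the pooled
#' cells of the whole cohort, not per patient), and partitions the
#' standardized cells into exactly `W` clusters with K-means. The resulting
#' clusters are the cell-type "words" used downstream; `W` is normally
#' `2^N` for an N-marker panel.
#'
#' @param cohort A `sim_cohort` or a plain list of `patient_cells` objects
#'   sharing the same marker columns.
#' @param W Number of cell types (clusters) to fit.
#' @param seed Integer seed making the K-means restarts deterministic.
#' @param nstart,iter.max K-means restart count and iteration cap.
#' @return An object of class `cell_type_model`: `marker_means`,
#'   `marker_stds` (pooled Z-score parameters), `centroids` (`W x N`, in
#'   standardized space) and `W`.
#' @export
fit_cell_types <- function(cohort, W, seed = 1L, nstart = 10L,
                           iter.max = 300L) {
  patients <- cohort_patients(cohort)
  pooled <- do.call(rbind, lapply(patients, `[[`, "values"))
  if (nrow(pooled) < W) stop("W exceeds the number of pooled cells")
  marker_means <- colMeans(pooled)
  marker_stds <- apply(pooled, 2, stats::sd)
  if (any(marker_stds == 0)) {
    stop("constant marker: zero pooled variance in column(s) ",
         paste(which(marker_stds == 0), collapse = ", "))
  }
  z <- scale(pooled, center = marker_means, scale = marker_stds)
  set.seed(seed)
  km <- tryCatch(
    stats::kmeans(z, centers = W, nstart = nstart, iter.max = iter.max,
                  algorithm = "MacQueen"),
    error = function(e) {
      if (grepl("distinct", conditionMessage(e)))
        stop("W exceeds the number of distinct pooled cells")
      stop(e)
    }
  )
  structure(
    list(marker_means = marker_means, marker_stds = marker_stds,
         centroids = km$centers, W = as.integer(W)),
    class = "cell_type_model"
  )
}

#' @export
print.cell_type_model <- function(x, ...) {
  cat(sprintf("Cell-type model: %d types over %d markers (pooled Z-score)\n",
              x$W, length(x$marker_means)))
  invisible(x)
}

# Accept either a sim_cohort or a bare list of patient_cells.
cohort_patients <- function(cohort) {
  patients <- if (inherits(cohort, "sim_cohort")) cohort$patients else cohort
  if (!length(patients) || !all(vapply(patients, inherits, TRUE,
                                       "patient_cells"))) {
    stop("cohort must be a sim_cohort or a list of patient_cells")
  }
  n_col <- vapply(patients, function(p) ncol(p$values), 0L)
  if (length(unique(n_col)) != 1L) {
    stop("all patients must share the same marker columns")
  }
  patients
}

#' Assign every cell to its nearest cell type and count per patient
#'
#' Standardizes each patient's cells with the model's pooled Z-score
#' parameters, assigns every cell to the nearest centroid (Euclidean
#' distance, ties broken by the lowest cluster index), and tabulates a
#' patients x cell-types count matrix — the LDA corpus. Clusters with no
#' cells in a given patient contribute legitimate zero counts; no column is
#' ever pruned.
#'
#' @param cohort A `sim_cohort` or list of `patient_cells`.
#' @param model A [fit_cell_types()] model fitted on compatible markers.
#' @return A `count_matrix`: integer matrix, one row per patient (rownames =
#'   patient ids), one column per cell type; row sums equal cell counts.
#' @export
assign_and_count <- function(cohort, model) {
  stopifnot(inherits(model, "cell_type_model"))
  patients <- cohort_patients(cohort)
  if (ncol(patients[[1L]]$values) != ncol(model$centroids)) {
    stop("marker dimension mismatch between cohort and cell-type model")
  }
  counts <- t(vapply(patients, function(p) {
    tabulate(assign_cells(p$values, model), nbins = model$W)
  }, integer(model$W)))
  rownames(counts) <- vapply(patients, `[[`, "", "patient_id")
  colnames(counts) <- paste0("type", seq_len(model$W))
  as_count_matrix(counts)
}

#' Nearest-centroid cell assignment
#'
#' @param values Cells x markers numeric matrix (raw scale).
#' @param model A `cell_type_model`.
#' @return Integer vector of 1-based cluster ids, one per cell.
#' @export
assign_cells <- function(values, model) {
  z <- scale(values, center = model$marker_means, scale = model$marker_stds)
  cross <- z %*% t(model$centroids)
  d2 <- outer(rep(1, nrow(z)), rowSums(model$centroids^2)) - 2 * cross
  max.col(-d2, ties.method = "first")
}

#' Validate and tag a patients x cell-types count matrix
#'
#' @param counts Matrix of nonnegative integers; rownames are patient ids.
#' @return The matrix, integer storage, with class `count_matrix`.
#' @export
as_count_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (any(is.na(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("not a count table: entries must be nonnegative integers")
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("D", seq_len(nrow(counts)))
  }
  if (anyDuplicated(rownames(counts))) stop("duplicated patient IDs")
  storage.mode(counts) <- "integer"
  class(counts) <- c("count_matrix", "matrix", "array")
  counts
}

#' Read a patients x features count table
#'
#' Reads a CSV/TSV whose first column holds patient IDs and whose remaining
#' columns are nonnegative integer feature counts (cell types, genera, ...).
#' This is the entry point for data that already comes as counts — e.g. 16S
#' genus abundance tables — which bypasses the cell-typing stage entirely.
#'
#' @param path File path; comma-separated for `.csv`, otherwise tab.
#' @return A `count_matrix` with feature names preserved.
#' @export
read_count_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count table needs an ID column plus features")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicated patient IDs")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("not a count table: non-numeric entries")
  rownames(m) <- ids
  as_count_matrix(m)
}

#' Write a count table as TSV
#'
#' Inverse of [read_count_table()]: first column `patient_id`, then one
#' column per feature.
#'
#' @param counts A `count_matrix`.
#' @param path Output TSV path.
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(patient_id = rownames(counts),
                   as.data.frame(unclass(counts)), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a cell-type model to JSON
#'
#' @param model A `cell_type_model`.
#' @param path Output JSON path.
#' @export
write_cell_type_model <- function(model, path) {
  jsonlite::write_json(
    list(marker_means = model$marker_means, marker_stds = model$marker_stds,
         centroids = model$centroids, W = model$W),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a cell-type model written by [write_cell_type_model()]
#'
#' @param path JSON path.
#' @return A `cell_type_model`.
#' @export
read_cell_type_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(marker_means = as.numeric(j$marker_means),
         marker_stds = as.numeric(j$marker_stds),
         centroids = matrix(as.numeric(j$centroids), nrow = j$W),
         W = as.integer(j$W)),
    class = "cell_type_model"
  )
}
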