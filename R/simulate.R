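#' Specify a synthetic cytometry cohort
#'
#' Bundles every knob of the synthetic cohort generator into one validated
#' object. A cohort has `n_phenotypes` patient classes, each with
#' `patients_per_phenotype` patients carrying `cells_per_patient` cells
#' measured on `n_markers` fluorescence markers. Each marker is a
#' two-component Gaussian mixture: a cell in the "low" state for marker j
#' emits `Normal(mu_low, sigma)`, in the "high" state `Normal(mu_high,
#' sigma)`. The binary low/high pattern across the N markers encodes the
#' cell's type, so there are `W = 2^n_markers` possible cell types.
#'
#' `sigma` is the robustness knob: the larger it is, the more the low and
#' high mixture components overlap and the harder cell typing becomes.
#' `distance` sets the exact pairwise Euclidean distance between the
#' phenotype-specific cell-type probability vectors (see
#' [make_phenotype_vectors()]); it controls how separable the patient
#' classes are.
#'
#' @param n_markers Number of fluorescence markers N (positive integer).
#' @param n_phenotypes Number of patient classes (positive integer).
#' @param patients_per_phenotype Patients simulated per class.
#' @param cells_per_patient Cells measured per patient.
#' @param mu_low,mu_high Means of the low/high marker states
#'   (`mu_high > mu_low`).
#' @param sigma Shared marker standard deviation (> 0).
#' @param distance Target pairwise Euclidean distance between the class
#'   cell-type probability vectors (>= 0).
#' @param seed Integer root seed; the cohort is a pure function of the spec.
#' @return An object of class `cohort_spec`.
#' @seealso [simulate_cohort()], [make_phenotype_vectors()]
#' @export
#' @examples
#' spec <- cohort_spec(n_markers = 2, n_phenotypes = 2, distance = 1,
#'                     patients_per_phenotype = 5, cells_per_patient = 500)
#' cohort <- simulate_cohort(spec)
cohort_spec <- function(n_markers,
                        n_phenotypes,
                        patients_per_phenotype = 50L,
                        cells_per_patient = 10000L,
                        mu_low = 0,
                        mu_high = 1,
                        sigma = 0.25,
                        distance = 1,
                        seed = 1L) {
  stopifnot(
    is.numeric(n_markers), length(n_markers) == 1L, n_markers >= 1,
    n_markers == round(n_markers),
    is.numeric(n_phenotypes), n_phenotypes >= 1,
    n_phenotypes == round(n_phenotypes),
    patients_per_phenotype >= 1, cells_per_patient >= 1
  )
  if (!(mu_high > mu_low)) stop("mu_high must be greater than mu_low")
  if (!(sigma > 0)) stop("sigma must be positive")
  if (distance < 0) stop("distance must be nonnegative")
  structure(
    list(
      n_markers = as.integer(n_markers),
      n_phenotypes = as.integer(n_phenotypes),
      patients_per_phenotype = as.integer(patients_per_phenotype),
      cells_per_patient = as.integer(cells_per_patient),
      mu_low = mu_low,
      mu_high = mu_high,
      sigma = sigma,
      distance = distance,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat(sprintf("  markers: %d (W = %d cell types)\n",
              x$n_markers, 2L^x$n_markers))
  cat(sprintf("  phenotypes: %d x %d patients, %d cells each\n",
              x$n_phenotypes, x$patients_per_phenotype, x$cells_per_patient))
  cat(sprintf("  marker mixture: low %.3g / high %.3g, sigma %.3g\n",
              x$mu_low, x$mu_high, x$sigma))
  cat(sprintf("  class vector distance: %.3g, seed %d\n", x$distance, x$seed))
  invisible(x)
}

# Deterministic per-stream seed derivation so patient i's data does not
# depend on cohort size (all arithmetic stays below 2^53, exact in doubles).
derive_seed <- function(root, index) {
  as.integer((abs(as.numeric(root)) * 48271 + as.numeric(index) * 83492791) %%
               2147483647)
}

#' Construct equidistant phenotype probability vectors
#'
#' Builds one cell-type probability vector per patient class such that every
#' pair of vectors is exactly `distance` apart in Euclidean norm. Each class
#' vector is a blend of the uniform distribution over the `W` cell types and
#' a one-hot "signature" type specific to the class:
#' `v_c = (1 - t) * u + t * e_c` with `t = distance / sqrt(2)`. Because the
#' signature types are distinct, `||v_i - v_j|| = t * sqrt(2) = distance`
#' for every pair, entries are never negative, and any distance in
#' `[0, sqrt(2))` is achievable at any vocabulary size. Scientifically this
#' mimics each patient class being enriched for one characteristic cell
#' population over a shared background repertoire.
#'
#' @param n_phenotypes Number of classes (>= 1).
#' @param W Vocabulary size (number of cell types, `W >= n_phenotypes`).
#' @param distance Target pairwise Euclidean distance, in `[0, sqrt(2))`.
#' @param seed Integer seed; picks which cell types act as class signatures.
#' @return A list of `n_phenotypes` numeric probability vectors of length
#'   `W`, each summing to 1.
#' @export
#' @examples
#' v <- make_phenotype_vectors(2, 4, distance = 0.2, seed = 1)
#' sqrt(sum((v[[1]] - v[[2]])^2))  # 0.2
make_phenotype_vectors <- function(n_phenotypes, W, distance, seed = 1L) {
  stopifnot(n_phenotypes >= 1, W >= 1, distance >= 0)
  if (W < n_phenotypes) {
    stop("W must be at least n_phenotypes (one signature type per class)")
  }
  t <- distance / sqrt(2)
  if (t >= 1) {
    stop("distance not achievable at this W: must be below sqrt(2)")
  }
  u <- rep(1 / W, W)
  if (distance == 0) {
    return(replicate(n_phenotypes, u, simplify = FALSE))
  }
  set.seed(derive_seed(seed, 0L))
  signatures <- sample.int(W, n_phenotypes)
  lapply(signatures, function(s) {
    v <- (1 - t) * u
    v[s] <- v[s] + t
    v
  })
}

#' Simulate one patient's cell-by-marker matrix
#'
#' Draws `spec$cells_per_patient` cell types i.i.d. from the class
#' probability vector, decodes each type `t` in `[0, 2^N)` into its N-bit
#' binary low/high pattern (bit j of `t` is marker j's state, marker order =
#' column order), and emits marker values from the corresponding Gaussian
#' component.
#'
#' @param vec Probability vector of length `2^spec$n_markers` over cell
#'   types.
#' @param spec A [cohort_spec()].
#' @param patient_id Character id for the patient.
#' @param seed Integer seed for this patient's draw.
#' @param phenotype Optional integer class label stored as ground truth.
#' @return An object of class `patient_cells`: a list with `patient_id`,
#'   `values` (cells x markers numeric matrix), `true_cell_types` (0-based
#'   type codes) and `true_phenotype`.
#' @export
simulate_patient <- function(vec, spec, patient_id, seed = spec$seed,
                             phenotype = NA_integer_) {
  W <- 2L^spec$n_markers
  if (length(vec) != W) {
    stop("phenotype vector length must equal 2^n_markers")
  }
  if (any(vec < 0) || abs(sum(vec) - 1) > 1e-8) {
    stop("phenotype vector must be a probability distribution")
  }
  n <- spec$cells_per_patient
  N <- spec$n_markers
  set.seed(seed)
  types <- sample.int(W, n, replace = TRUE, prob = vec) - 1L
  bits <- vapply(seq_len(N) - 1L,
                 function(j) bitwAnd(bitwShiftR(types, j), 1L),
                 integer(n))
  bits <- matrix(bits, nrow = n, ncol = N)
  values <- spec$mu_low + bits * (spec$mu_high - spec$mu_low) +
    matrix(stats::rnorm(n * N, 0, spec$sigma), n, N)
  colnames(values) <- paste0("marker", seq_len(N))
  structure(
    list(
      patient_id = patient_id,
      values = values,
      true_cell_types = types,
      true_phenotype = phenotype
    ),
    class = "patient_cells"
  )
}

#' @export
print.patient_cells <- function(x, ...) {
  cat(sprintf("Patient %s: %d cells x %d markers%s\n",
              x$patient_id, nrow(x$values), ncol(x$values),
              if (is.na(x$true_phenotype)) ""
              else sprintf(" (phenotype %d)", x$true_phenotype)))
  invisible(x)
}

#' Simulate a full synthetic cohort
#'
#' Generates a balanced cohort: `patients_per_phenotype` patients for each
#' of the `n_phenotypes` classes, with class probability vectors from
#' [make_phenotype_vectors()]. Each patient uses its own RNG stream derived
#' deterministically from `spec$seed` and the patient's global index, so a
#' given patient's cells are invariant to cohort size and the whole cohort
#' is bitwise reproducible from the spec.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `sim_cohort`: a list with `patients` (list of
#'   [simulate_patient()] results), `labels` (integer class per patient,
#'   1-based), `vectors` (the class probability vectors) and `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  W <- 2L^spec$n_markers
  vectors <- make_phenotype_vectors(spec$n_phenotypes, W, spec$distance,
                                    seed = spec$seed)
  n_total <- spec$n_phenotypes * spec$patients_per_phenotype
  patients <- vector("list", n_total)
  labels <- integer(n_total)
  idx <- 0L
  for (cls in seq_len(spec$n_phenotypes)) {
    for (i in seq_len(spec$patients_per_phenotype)) {
      idx <- idx + 1L
      patients[[idx]] <- simulate_patient(
        vectors[[cls]], spec,
        patient_id = sprintf("P%04d", idx),
        seed = derive_seed(spec$seed, idx),
        phenotype = cls
      )
      labels[idx] <- cls
    }
  }
  structure(
    list(patients = patients, labels = labels, vectors = vectors,
         spec = spec),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients (%d phenotypes), %d markers\n",
              length(x$patients), x$spec$n_phenotypes, x$spec$n_markers))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes one CSV per patient (cells x markers, header = marker names), a
#' cohort manifest TSV (`patient_id`, `phenotype`, `file`) and a
#' ground-truth TSV of per-cell type codes.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(length(cohort$patients))
  for (i in seq_along(cohort$patients)) {
    p <- cohort$patients[[i]]
    files[i] <- file.path(dir, paste0(p$patient_id, ".csv"))
    utils::write.csv(as.data.frame(p$values), files[i], row.names = FALSE)
  }
  manifest <- data.frame(
    patient_id = vapply(cohort$patients, `[[`, "", "patient_id"),
    phenotype = cohort$labels,
    file = files,
    stringsAsFactors = FALSE
  )
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  truth <- data.frame(
    patient_id = rep(manifest$patient_id,
                     vapply(cohort$patients, function(p) nrow(p$values), 0L)),
    cell_type = unlist(lapply(cohort$patients, `[[`, "true_cell_types"))
  )
  utils::write.table(truth, file.path(dir, "cell_types.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read a cohort of patient cell matrices from a manifest
#'
#' Reads the manifest TSV written by [write_cohort()] (columns
#' `patient_id`, `phenotype`, `file`; `phenotype` may be absent) and loads
#' each per-patient CSV/TSV into a `patient_cells` object.
#'
#' @param manifest_path Path to the manifest TSV.
#' @return A `sim_cohort`-like list with `patients` and `labels` (NA when
#'   the manifest carries no phenotype column).
#' @export
read_cohort <- function(manifest_path) {
  manifest <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "file") %in% names(manifest))) {
    stop("manifest must have patient_id and file columns")
  }
  base <- dirname(manifest_path)
  patients <- lapply(seq_len(nrow(manifest)), function(i) {
    path <- manifest$file[i]
    if (!file.exists(path)) path <- file.path(base, basename(path))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    values <- as.matrix(utils::read.table(path, header = TRUE, sep = sep))
    structure(
      list(patient_id = as.character(manifest$patient_id[i]), values = values,
           true_cell_types = NULL,
           true_phenotype = if ("phenotype" %in% names(manifest))
             manifest$phenotype[i] else NA_integer_),
      class = "patient_cells"
    )
  })
  labels <- if ("phenotype" %in% names(manifest)) manifest$phenotype
            else rep(NA_integer_, nrow(manifest))
  structure(list(patients = patients, labels = labels, vectors = NULL,
                 spec = NULL),
            class = "sim_cohort")
}
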