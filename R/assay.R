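#' Construct an assay matrix
#'
#' The central measurement container: replicate-mean optical densities for
#' every (sample, antigen, coating concentration) cell, together with the
#' sample metadata. Missing cells are stored as `NA` and handled (excluded
#' with a count) by the downstream panel arithmetic.
#'
#' @param samples Data frame with at least `sample_id` and `status`
#'   (`"cancer"` / `"control"`); `sample_id` must be unique.
#' @param od Numeric array, samples x antigens x concentrations, with
#'   dimnames `(sample_id, antigen, concentration)`; all non-missing values
#'   must be non-negative.
#' @param provenance Either `"htpa"` (abridged 2-point high-throughput
#'   assay) or `"rnd"` (5-point titration assay).
#'
#' @return An object of class `"assay_matrix"` with elements `samples`,
#'   `od`, `antigens`, `concentrations`, `provenance`.
#' @export
assay_matrix <- function(samples, od, provenance = c("rnd", "htpa")) {
  provenance <- match.arg(provenance)
  if (!is.data.frame(samples) || !all(c("sample_id", "status") %in% names(samples))) {
    stop_arg("`samples` must contain sample_id and status columns")
  }
  if (anyDuplicated(samples$sample_id)) stop_arg("sample_id values must be unique")
  if (!all(samples$status %in% c("cancer", "control"))) {
    stop_arg("status must be 'cancer' or 'control'")
  }
  if (!is.array(od) || length(dim(od)) != 3L) {
    stop_arg("`od` must be a 3-d array (samples x antigens x concentrations)")
  }
  dn <- dimnames(od)
  if (is.null(dn) || !identical(dn[[1]], samples$sample_id)) {
    stop_arg("rows of `od` must match samples$sample_id")
  }
  if (any(od < 0, na.rm = TRUE)) stop_arg("optical densities must be non-negative")
  structure(
    list(samples = samples, od = od,
         antigens = dn[[2]],
         concentrations = as.numeric(dn[[3]]),
         provenance = provenance),
    class = "assay_matrix"
  )
}

#' Convert a simulated cohort to an assay matrix
#'
#' @param sim A `"sim_cohort"` object.
#' @param provenance Assay provenance label, `"rnd"` or `"htpa"`.
#' @return An [assay_matrix()].
#' @export
as_assay_matrix <- function(sim, provenance = c("rnd", "htpa")) {
  if (!inherits(sim, "sim_cohort")) stop_arg("`sim` must be a sim_cohort object")
  assay_matrix(sim$samples, sim$od, match.arg(provenance))
}

#' Read assay measurements from CSV files
#'
#' Reads the `samples.csv` / `measurements.csv` pair written by
#' [write_cohort()] (or prepared externally in the same schema), averages
#' replicate wells per (sample, antigen, concentration) and returns an
#' [assay_matrix()]. Cells absent from the measurement table are stored as
#' missing and their count reported via `message()`.
#'
#' @param samples_path Path to the sample table
#'   (`sample_id, cohort, status, match_id, age, gender, smoking`).
#' @param measurements_path Path to the long measurement table
#'   (`sample_id, antigen, concentration_nM, replicate_index, od`).
#' @param provenance Assay provenance label, `"rnd"` or `"htpa"`.
#'
#' @return An [assay_matrix()] of replicate-mean ODs.
#' @export
read_measurements <- function(samples_path, measurements_path,
                              provenance = c("rnd", "htpa")) {
  provenance <- match.arg(provenance)
  if (!file.exists(samples_path)) stop_arg("sample file not found: ", samples_path)
  if (!file.exists(measurements_path)) {
    stop_arg("measurement file not found: ", measurements_path)
  }
  samples <- utils::read.csv(samples_path, stringsAsFactors = FALSE)
  need_s <- c("sample_id", "status")
  if (!all(need_s %in% names(samples))) {
    stop_arg("sample table must contain columns: ", paste(need_s, collapse = ", "))
  }
  meas <- utils::read.csv(measurements_path, stringsAsFactors = FALSE)
  need_m <- c("sample_id", "antigen", "concentration_nM", "replicate_index", "od")
  if (!all(need_m %in% names(meas))) {
    stop_arg("measurement table must contain columns: ",
             paste(need_m, collapse = ", "))
  }
  bad <- which(!is.finite(meas$od))
  if (length(bad)) {
    stop_arg("non-numeric or missing OD in measurement row ", bad[1])
  }
  neg <- which(meas$od < 0)
  if (length(neg)) {
    stop_arg("negative OD in measurement row ", neg[1],
             " (sample ", meas$sample_id[neg[1]], ")")
  }
  unknown <- setdiff(unique(meas$sample_id), samples$sample_id)
  if (length(unknown)) {
    stop_arg("measurements reference unknown sample_id(s): ",
             paste(utils::head(unknown, 5), collapse = ", "))
  }

  s_f <- factor(meas$sample_id, levels = samples$sample_id)
  a_f <- factor(meas$antigen, levels = unique(meas$antigen))
  c_lev <- sort(unique(meas$concentration_nM), decreasing = TRUE)
  c_f <- factor(meas$concentration_nM, levels = c_lev)
  od <- tapply(meas$od, list(s_f, a_f, c_f), mean)
  dimnames(od) <- list(samples$sample_id, levels(a_f), as.character(c_lev))

  n_missing <- sum(is.na(od))
  if (n_missing > 0) {
    message(n_missing, " missing (sample, antigen, concentration) cell(s)")
  }
  assay_matrix(samples, od, provenance)
}

#' Extract cancer and control OD vectors for one antigen and concentration
#'
#' Returns the per-group replicate-mean OD vectors for a single (antigen,
#' concentration) cell of an assay matrix, excluding samples missing that
#' cell and reporting the exclusion counts.
#'
#' @param x An [assay_matrix()].
#' @param antigen Antigen name present in `x`.
#' @param concentration Coating concentration (nM) present in `x`.
#'
#' @return A list with `cancer` and `control` numeric vectors and
#'   `n_excluded_cancer` / `n_excluded_control` counts.
#' @export
select_view <- function(x, antigen, concentration) {
  if (!inherits(x, "assay_matrix")) stop_arg("`x` must be an assay_matrix")
  if (!antigen %in% x$antigens) stop_arg("unknown antigen: ", antigen)
  ckey <- as.character(concentration)
  if (!ckey %in% dimnames(x$od)[[3]]) {
    stop_arg("concentration ", concentration, " nM not present in matrix")
  }
  v <- x$od[, antigen, ckey]
  is_cancer <- x$samples$status == "cancer"
  list(
    cancer = unname(v[is_cancer & !is.na(v)]),
    control = unname(v[!is_cancer & !is.na(v)]),
    n_excluded_cancer = sum(is_cancer & is.na(v)),
    n_excluded_control = sum(!is_cancer & is.na(v))
  )
}

#' @export
print.assay_matrix <- function(x, ...) {
  cat(sprintf("Assay matrix (%s): %d samples (%d cancer / %d control), %d antigens, %d concentration(s)\n",
              x$provenance, nrow(x$samples),
              sum(x$samples$status == "cancer"),
              sum(x$samples$status == "control"),
              length(x$antigens), length(x$concentrations)))
  if (anyNA(x$od)) cat(sprintf("  %d missing cell(s)\n", sum(is.na(x$od))))
  invisible(x)
}
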