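#' Two-sample Kolmogorov-Smirnov distance
#'
#' Computes the K-S distance `D`: the supremum over the pooled observed
#' values of the absolute difference between the right-continuous empirical
#' CDFs of the two samples. Used here as a discrimination score between
#' cancer and control OD distributions, not as a hypothesis test; no
#' p-value is attached. Ties are handled exactly by evaluating both ECDFs
#' at the pooled unique points.
#'
#' `D` is symmetric in its arguments, lies in `[0, 1]`, and is invariant
#' under any common strictly increasing transform of both samples.
#'
#' @param cancer_ods,control_ods Non-empty numeric vectors.
#' @return The K-S distance, a number in `[0, 1]`.
#' @export
#' @examples
#' ks_statistic(c(1, 2, 3, 4), c(2, 3, 4, 5))  # 0.25
ks_statistic <- function(cancer_ods, control_ods) {
  if (!is.numeric(cancer_ods) || length(cancer_ods) == 0L ||
      !is.numeric(control_ods) || length(control_ods) == 0L) {
    stop_arg("both samples must be non-empty numeric vectors")
  }
  if (any(!is.finite(cancer_ods)) || any(!is.finite(control_ods))) {
    stop_arg("samples must not contain missing or infinite values")
  }
  pooled <- sort(unique(c(cancer_ods, control_ods)))
  fx <- findInterval(pooled, sort(cancer_ods)) / length(cancer_ods)
  fy <- findInterval(pooled, sort(control_ods)) / length(control_ods)
  max(abs(fx - fy))
}

#' Screen antigens for cancer/control discrimination
#'
#' Computes the K-S distance for every antigen at each listed coating
#' concentration and flags antigens as selected leads. With `rule = "any"`
#' an antigen is selected iff its distance reaches `threshold` at one or
#' more listed concentrations; with `rule = "all"`, at every listed
#' concentration. The comparison is inclusive (`d >= threshold`).
#'
#' Typical use is a permissive first-pass screen (threshold 0.13 on a
#' 2-point abridged assay at 100/50 nM) followed by a stricter confirmation
#' (threshold 0.2 on the titration assay).
#'
#' @param x An [assay_matrix()].
#' @param threshold K-S distance threshold in `[0, 1]`.
#' @param concentrations Concentrations (nM) to score; default all in `x`.
#' @param rule `"any"` (default) or `"all"`.
#'
#' @return A data frame with one row per (antigen, concentration):
#'   `antigen`, `concentration_nM`, `d`, `n_cancer`, `n_control`, `d_max`
#'   (per antigen), `selected`; sorted by `d_max` descending.
#' @export
screen_leads <- function(x, threshold, concentrations = NULL,
                         rule = c("any", "all")) {
  if (!inherits(x, "assay_matrix")) stop_arg("`x` must be an assay_matrix")
  rule <- match.arg(rule)
  if (!is_fraction(threshold)) stop_arg("`threshold` must lie in [0, 1]")
  if (is.null(concentrations)) concentrations <- x$concentrations
  miss <- setdiff(concentrations, x$concentrations)
  if (length(miss)) {
    stop_arg("concentration(s) not present in matrix: ",
             paste(miss, collapse = ", "))
  }
  rows <- list()
  for (a in x$antigens) {
    for (cc in concentrations) {
      v <- select_view(x, a, cc)
      rows[[length(rows) + 1L]] <- data.frame(
        antigen = a, concentration_nM = cc,
        d = ks_statistic(v$cancer, v$control),
        n_cancer = length(v$cancer), n_control = length(v$control),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  dmax <- tapply(out$d, out$antigen, max)
  dmin <- tapply(out$d, out$antigen, min)
  out$d_max <- as.numeric(dmax[out$antigen])
  crit <- if (rule == "any") dmax else dmin
  out$selected <- as.numeric(crit[out$antigen]) >= threshold
  out <- out[order(-out$d_max, out$antigen, -out$concentration_nM), ]
  rownames(out) <- NULL
  out
}

#' Descriptive statistics of OD by disease group
#'
#' @param x An [assay_matrix()].
#' @param antigen Antigen name.
#' @param concentration Coating concentration (nM).
#' @return A data frame with one row per group (`cancer`, `control`):
#'   `n`, `mean`, `sd`, `min`, `q25`, `median`, `q75`, `max`.
#' @export
group_summaries <- function(x, antigen, concentration) {
  v <- select_view(x, antigen, concentration)
  summ <- function(z) {
    q <- stats::quantile(z, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(n = length(z), mean = mean(z), sd = stats::sd(z),
               min = q[1], q25 = q[2], median = q[3], q75 = q[4], max = q[5])
  }
  out <- rbind(summ(v$cancer), summ(v$control))
  out <- cbind(group = c("cancer", "control"), out)
  out$sd[out$n == 1L] <- 0  # single observation: no spread
  out
}
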