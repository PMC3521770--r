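#' Per-sample positivity flags for a panel
#'
#' Applies a cut-off vector to an assay matrix: a sample is positive for an
#' antigen when its replicate-mean OD strictly exceeds the antigen's
#' cut-off (at the cut-off's working concentration), and panel-positive
#' when positive for at least one panel antigen (the OR rule). Samples
#' missing any panel cell are excluded and counted.
#'
#' @param x An [assay_matrix()].
#' @param cutoffs A `"cutoff_vector"` (see [optimize_joint()]).
#' @param panel Antigen names to evaluate; default all antigens covered by
#'   `cutoffs`.
#'
#' @return A data frame with `sample_id`, `status`, one logical column per
#'   panel antigen, and `panel_pos`; the excluded sample ids are attached
#'   as attribute `"excluded"`.
#' @export
panel_positivity <- function(x, cutoffs, panel = names(cutoffs$cutoffs)) {
  if (!inherits(x, "assay_matrix")) stop_arg("`x` must be an assay_matrix")
  if (!inherits(cutoffs, "cutoff_vector")) {
    stop_arg("`cutoffs` must be a cutoff_vector")
  }
  nocut <- setdiff(panel, names(cutoffs$cutoffs))
  if (length(nocut)) {
    stop_arg("no cut-off configured for antigen(s): ",
             paste(nocut, collapse = ", "))
  }
  absent <- setdiff(panel, x$antigens)
  if (length(absent)) {
    stop_arg("panel antigen(s) absent from matrix: ",
             paste(absent, collapse = ", "))
  }
  n <- nrow(x$samples)
  if (length(panel) == 0L) {
    out <- data.frame(sample_id = x$samples$sample_id,
                      status = x$samples$status,
                      panel_pos = rep(FALSE, n),
                      stringsAsFactors = FALSE)
    attr(out, "excluded") <- character(0)
    return(out)
  }
  ckeys <- as.character(cutoffs$concentration_nM[panel])
  bad <- panel[!ckeys %in% dimnames(x$od)[[3]]]
  if (length(bad)) {
    stop_arg("matrix lacks the working concentration for antigen(s): ",
             paste(bad, collapse = ", "))
  }
  M <- sapply(seq_along(panel),
              function(j) x$od[, panel[j], ckeys[j]])
  M <- matrix(M, ncol = length(panel),
              dimnames = list(x$samples$sample_id, panel))
  keep <- stats::complete.cases(M)
  flags <- M[keep, , drop = FALSE] >
    rep(cutoffs$cutoffs[panel], each = sum(keep))
  out <- data.frame(sample_id = x$samples$sample_id[keep],
                    status = x$samples$status[keep],
                    stringsAsFactors = FALSE)
  fl <- as.data.frame(flags, optional = TRUE)
  names(fl) <- colnames(flags)  # keep antigen names verbatim (e.g. "NY-ESO-1")
  out <- cbind(out, fl)
  out$panel_pos <- rowSums(flags) > 0
  attr(out, "excluded") <- x$samples$sample_id[!keep]
  out
}

#' OR-rule panel performance
#'
#' Confusion counts and sensitivity/specificity of a panel at fixed
#' cut-offs. An empty panel calls no one positive, giving sensitivity 0
#' and specificity 1 by convention (so the base row of a
#' [combination_scan()] is well defined). Fractions are kept raw; rounding
#' happens only at reporting.
#'
#' @inheritParams panel_positivity
#' @return An object of class `"panel_performance"`: `tp`, `fp`, `tn`,
#'   `fn`, `sens`, `spec`, `n_excluded`.
#' @export
panel_performance <- function(x, cutoffs, panel = names(cutoffs$cutoffs)) {
  flags <- panel_positivity(x, cutoffs, panel)
  if (nrow(flags) == 0L) stop_arg("no evaluable samples")
  is_cancer <- flags$status == "cancer"
  if (!any(is_cancer) || !any(!is_cancer)) {
    stop_arg("no evaluable samples in one disease group")
  }
  tp <- sum(flags$panel_pos & is_cancer)
  fn <- sum(!flags$panel_pos & is_cancer)
  fp <- sum(flags$panel_pos & !is_cancer)
  tn <- sum(!flags$panel_pos & !is_cancer)
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         sens = tp / (tp + fn), spec = tn / (tn + fp),
         n_excluded = length(attr(flags, "excluded"))),
    class = "panel_performance"
  )
}

#' @export
print.panel_performance <- function(x, ...) {
  cat(sprintf("Panel performance: sens %s (%d/%d), spec %s (%d/%d)",
              format_pct(x$sens), x$tp, x$tp + x$fn,
              format_pct(x$spec), x$tn, x$tn + x$fp))
  if (x$n_excluded > 0) cat(sprintf("; %d sample(s) excluded", x$n_excluded))
  cat("\n")
  invisible(x)
}

#' Additive positivity of a candidate lead over a base panel
#'
#' Splits a lead's positives into "non-additive" (also positive for the
#' base panel) and "additive" (missed by every base-panel antigen).
#' Overall positivity is the fraction of each group positive for the lead;
#' additive positivity is the fraction positive for the lead and negative
#' for the whole base panel; the net additive gain is the additive
#' positivity in cancers minus that in controls. Samples missing any cell
#' of the base panel or the lead are excluded from all fractions.
#'
#' @inheritParams panel_positivity
#' @param base_panel Antigen names of the existing panel.
#' @param lead A single candidate antigen, not in `base_panel`.
#' @return An object of class `"additivity_result"` (see
#'   [additivity_result()]), with counts and group sizes attached.
#' @export
additive_analysis <- function(x, cutoffs, base_panel, lead) {
  if (length(lead) != 1L) stop_arg("`lead` must be a single antigen")
  if (lead %in% base_panel) stop_arg("`lead` must not be part of `base_panel`")
  flags <- panel_positivity(x, cutoffs, c(base_panel, lead))
  is_cancer <- flags$status == "cancer"
  n_can <- sum(is_cancer)
  n_con <- sum(!is_cancer)
  if (n_can == 0L || n_con == 0L) stop_arg("no evaluable samples in one group")
  lead_pos <- flags[[lead]]
  base_pos <- if (length(base_panel)) {
    rowSums(as.matrix(flags[base_panel])) > 0
  } else {
    rep(FALSE, nrow(flags))
  }
  res <- additivity_result(
    lead = lead,
    overall_pos_cancer = sum(lead_pos & is_cancer) / n_can,
    overall_pos_control = sum(lead_pos & !is_cancer) / n_con,
    additive_pos_cancer = sum(lead_pos & !base_pos & is_cancer) / n_can,
    additive_pos_control = sum(lead_pos & !base_pos & !is_cancer) / n_con
  )
  res$n_cancer <- n_can
  res$n_control <- n_con
  res$additive_cancer_count <- as.integer(sum(lead_pos & !base_pos & is_cancer))
  res$n_excluded <- length(attr(flags, "excluded"))
  res
}

#' Construct an additivity result from positivity fractions
#'
#' Validates the defining inequalities (additive positivity cannot exceed
#' overall positivity in either group) and computes the net additive gain,
#' `additive_pos_cancer - additive_pos_control`. Used both by
#' [additive_analysis()] and to recompute net gains from published
#' positivity tables.
#'
#' @param lead Antigen name.
#' @param overall_pos_cancer,overall_pos_control Fractions of each group
#'   positive for the lead.
#' @param additive_pos_cancer,additive_pos_control Fractions of each group
#'   positive for the lead and negative for the whole base panel.
#' @return An object of class `"additivity_result"` with the five input
#'   fields plus `net_additive_gain`.
#' @export
#' @examples
#' additivity_result("p53-EP", 0.07, 0, 0.05, 0)$net_additive_gain  # 0.05
additivity_result <- function(lead, overall_pos_cancer, overall_pos_control,
                              additive_pos_cancer, additive_pos_control) {
  for (v in list(overall_pos_cancer, overall_pos_control,
                 additive_pos_cancer, additive_pos_control)) {
    if (!is_fraction(v)) stop_arg("positivities must be fractions in [0, 1]")
  }
  if (additive_pos_cancer > overall_pos_cancer + 1e-12 ||
      additive_pos_control > overall_pos_control + 1e-12) {
    stop_arg("additive positivity cannot exceed overall positivity")
  }
  structure(
    list(lead = lead,
         overall_pos_cancer = overall_pos_cancer,
         overall_pos_control = overall_pos_control,
         additive_pos_cancer = additive_pos_cancer,
         additive_pos_control = additive_pos_control,
         net_additive_gain = additive_pos_cancer - additive_pos_control),
    class = "additivity_result"
  )
}

#' @export
print.additivity_result <- function(x, ...) {
  cat(sprintf("%s: overall %s / %s, additive %s / %s, net gain %s\n",
              x$lead,
              format_pct(x$overall_pos_cancer, 0),
              format_pct(x$overall_pos_control, 0),
              format_pct(x$additive_pos_cancer, 0),
              format_pct(x$additive_pos_control, 0),
              format_pct(x$net_additive_gain, 0)))
  invisible(x)
}

#' Scan combinations of candidate leads added to a base panel
#'
#' Evaluates OR-rule performance for `base_panel` extended by every subset
#' of `leads` of size at most `max_k`, including the empty subset (base
#' panel alone). Cut-offs stay fixed throughout, so along the scan
#' sensitivity can only rise and specificity only fall as leads are added.
#'
#' @inheritParams panel_positivity
#' @param base_panel Antigen names of the existing panel.
#' @param leads Candidate lead antigens.
#' @param max_k Largest subset size to scan; at least 1.
#' @return A data frame with one row per subset: `leads_added` (comma
#'   separated, `""` for the base panel), `k`, `tp`, `fp`, `tn`, `fn`,
#'   `sens`, `spec`, `sens_pct`, `spec_pct` (1-decimal strings).
#' @export
combination_scan <- function(x, cutoffs, base_panel, leads, max_k = 3L) {
  if (!is_scalar_number(max_k) || max_k < 1) stop_arg("`max_k` must be >= 1")
  max_k <- min(as.integer(max_k), length(leads))
  subsets <- list(character(0))
  for (k in seq_len(max_k)) {
    cmb <- utils::combn(leads, k, simplify = FALSE)
    subsets <- c(subsets, cmb)
  }
  rows <- lapply(subsets, function(s) {
    perf <- panel_performance(x, cutoffs, c(base_panel, s))
    data.frame(leads_added = paste(s, collapse = ","), k = length(s),
               tp = perf$tp, fp = perf$fp, tn = perf$tn, fn = perf$fn,
               sens = perf$sens, spec = perf$spec,
               sens_pct = format_pct(perf$sens), spec_pct = format_pct(perf$spec),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Validate frozen cut-offs on an independent cohort
#'
#' Pure application of a cut-off vector fitted on one cohort to the assay
#' matrix of another: no re-fitting, identical code path as
#' [panel_performance()]. Errors if the validation matrix lacks any panel
#' antigen or its working concentration.
#'
#' @param cutoffs A `"cutoff_vector"` fitted on the training cohort.
#' @param matrix_b An [assay_matrix()] for the independent cohort.
#' @param panel Antigen names to evaluate; default all covered by
#'   `cutoffs`.
#' @return A `"panel_performance"` object.
#' @export
validate_external <- function(cutoffs, matrix_b,
                              panel = names(cutoffs$cutoffs)) {
  if (!inherits(matrix_b, "assay_matrix")) {
    stop_arg("`matrix_b` must be an assay_matrix")
  }
  panel_performance(matrix_b, cutoffs, panel)
}

#' Positive predictive value at a stated prevalence
#'
#' Bayes' formula for the probability of disease given a positive panel
#' result in a population with the stated prevalence:
#' \deqn{PPV = \frac{sens \cdot prev}{sens \cdot prev + (1 - spec)(1 - prev)}}
#' Reported both as a fraction and in the screening idiom "1 in N", where
#' N is `1 / PPV` rounded half away from zero.
#'
#' @param sens,spec,prevalence Fractions in `[0, 1]`.
#' @return An object of class `"ppv_result"`: `sens`, `spec`,
#'   `prevalence`, `ppv`, `one_in_n`.
#' @export
#' @examples
#' ppv(0.38, 0.86, 0.024)$one_in_n  # 16
#' ppv(0.49, 0.93, 0.024)$one_in_n  # 7
ppv <- function(sens, spec, prevalence) {
  if (!is_fraction(sens) || !is_fraction(spec) || !is_fraction(prevalence)) {
    stop_arg("`sens`, `spec` and `prevalence` must be fractions in [0, 1]")
  }
  denom <- sens * prevalence + (1 - spec) * (1 - prevalence)
  if (denom <= 0) {
    stop_arg("PPV undefined: the test calls no one positive ",
             "(sens * prev + (1 - spec) * (1 - prev) = 0)")
  }
  p <- sens * prevalence / denom
  structure(
    list(sens = sens, spec = spec, prevalence = prevalence, ppv = p,
         one_in_n = as.integer(round_half_away(1 / p))),
    class = "ppv_result"
  )
}

#' @export
print.ppv_result <- function(x, ...) {
  cat(sprintf("PPV %.3f (1 in %d) at prevalence %s (sens %s, spec %s)\n",
              x$ppv, x$one_in_n, format_pct(x$prevalence),
              format_pct(x$sens, 0), format_pct(x$spec, 0)))
  invisible(x)
}
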