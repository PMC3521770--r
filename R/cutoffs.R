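#' Candidate cut-off grid for one antigen
#'
#' Returns the finite set of thresholds that realizes every achievable
#' confusion table exactly once: the midpoints between consecutive sorted
#' unique OD values, plus one point below the minimum and one above the
#' maximum. The outer offsets are half the smallest gap between unique
#' values (or 0.5 absolute when there is a single unique value), so grid
#' points never coincide with observed ODs and strict (`OD > cutoff`)
#' positivity is unambiguous.
#'
#' @param ods Non-empty numeric vector of observed ODs (both groups pooled).
#' @return Sorted numeric vector of candidate cut-offs (length = number of
#'   unique values + 1).
#' @export
#' @examples
#' candidate_grid(c(1, 2))  # 0.5 1.5 2.5
candidate_grid <- function(ods) {
  if (!is.numeric(ods) || length(ods) == 0L || any(!is.finite(ods))) {
    stop_arg("`ods` must be a non-empty numeric vector without missing values")
  }
  u <- sort(unique(ods))
  if (length(u) == 1L) return(c(u - 0.5, u + 0.5))
  gaps <- diff(u)
  off <- min(gaps) / 2
  c(u[1] - off, u[-length(u)] + gaps / 2, u[length(u)] + off)
}

#' Objective for cut-off optimization
#'
#' Two interpretations of "maximize the number of positive cancers and
#' negative controls" are provided:
#'
#' * `youden_sum` (default): maximize `w_sens * sens + w_spec * spec`
#'   (with equal cohort sizes and unit weights this equals maximizing
#'   TP + TN, i.e. the Youden-type sum).
#' * `sens_at_spec_floor`: maximize sensitivity subject to specificity at
#'   least `spec_floor`. For search and cross-method comparison this is
#'   scored as the scalar `sens - 1000 * max(0, spec_floor - spec)`, a
#'   penalty steep enough that any feasible point beats every infeasible
#'   one.
#'
#' @param kind `"youden_sum"` or `"sens_at_spec_floor"`.
#' @param spec_floor Specificity floor in `[0, 1]` (floor variant only).
#' @param w_sens,w_spec Positive weights for the `youden_sum` variant.
#' @return An object of class `"objective"`.
#' @export
objective_spec <- function(kind = c("youden_sum", "sens_at_spec_floor"),
                           spec_floor = 0.95, w_sens = 1, w_spec = 1) {
  kind <- match.arg(kind)
  if (!is_fraction(spec_floor)) stop_arg("`spec_floor` must lie in [0, 1]")
  if (!is_scalar_number(w_sens) || w_sens <= 0 ||
      !is_scalar_number(w_spec) || w_spec <= 0) {
    stop_arg("weights must be strictly positive")
  }
  structure(list(kind = kind, spec_floor = spec_floor,
                 w_sens = w_sens, w_spec = w_spec),
            class = "objective")
}

objective_score <- function(sens, spec, objective) {
  switch(objective$kind,
    youden_sum = objective$w_sens * sens + objective$w_spec * spec,
    sens_at_spec_floor = sens - 1000 * pmax(0, objective$spec_floor - spec)
  )
}

#' Optimize the positivity cut-off for a single antigen
#'
#' Sweeps the [candidate_grid()] of the pooled ODs and returns the cut-off
#' maximizing the objective, with positivity defined strictly as
#' `OD > cutoff`. Among ties the largest cut-off is returned, biasing
#' toward specificity (false positives are the costly error in a screening
#' application).
#'
#' @param cancer_ods,control_ods Non-empty numeric OD vectors.
#' @param objective An [objective_spec()]; default unweighted `youden_sum`.
#' @return A list: `cutoff`, `sens`, `spec`, `objective_value`.
#' @export
#' @examples
#' optimize_single(c(0.2, 0.9, 1.1), c(0.1, 0.3, 0.4))
optimize_single <- function(cancer_ods, control_ods,
                            objective = objective_spec()) {
  if (!inherits(objective, "objective")) {
    stop_arg("`objective` must be an objective_spec() object")
  }
  if (length(cancer_ods) == 0L || length(control_ods) == 0L) {
    stop_arg("both groups must be non-empty")
  }
  grid <- candidate_grid(c(cancer_ods, control_ods))
  sc <- sort(cancer_ods)
  sn <- sort(control_ods)
  sens <- (length(sc) - findInterval(grid, sc)) / length(sc)
  spec <- findInterval(grid, sn) / length(sn)
  score <- objective_score(sens, spec, objective)
  # grid ascending + ">=" keeps the largest cut-off among ties
  best <- 1L
  for (i in seq_along(grid)) if (score[i] >= score[best]) best <- i
  list(cutoff = grid[best], sens = sens[best], spec = spec[best],
       objective_value = score[best])
}

#' Pick the working concentration for each antigen
#'
#' For each antigen, returns the coating concentration with the larger K-S
#' distance between cancer and control ODs, falling back to the highest
#' concentration on ties. This is the concentration at which positivity is
#' subsequently called.
#'
#' @param x An [assay_matrix()].
#' @param antigens Antigen names; default all in `x`.
#' @param concentrations Candidate concentrations; default all in `x`.
#' @return Named numeric vector: antigen -> concentration (nM).
#' @export
choose_concentrations <- function(x, antigens = x$antigens,
                                  concentrations = x$concentrations) {
  if (!inherits(x, "assay_matrix")) stop_arg("`x` must be an assay_matrix")
  out <- numeric(length(antigens))
  names(out) <- antigens
  concs <- sort(concentrations, decreasing = TRUE)
  for (a in antigens) {
    d <- vapply(concs, function(cc) {
      v <- select_view(x, a, cc)
      ks_statistic(v$cancer, v$control)
    }, numeric(1))
    out[a] <- concs[which.max(d)]  # which.max: first (= highest conc) on ties
  }
  out
}

#' Jointly optimize cut-offs for an OR-rule panel
#'
#' Optimizes one cut-off per panel antigen so that the panel-level
#' objective is maximized, where a sample is panel-positive iff its OD
#' exceeds the cut-off for at least one panel antigen. Three search
#' methods:
#'
#' * `"coordinate"`: cyclic single-antigen sweeps over each antigen's
#'   [candidate_grid()] holding the others fixed, starting from the
#'   independently optimized single-antigen cut-offs, until a full sweep
#'   makes no change. The objective never decreases between sweeps and the
#'   search terminates in finitely many sweeps.
#' * `"restart"` (default): `n_restarts` coordinate runs from random grid
#'   initializations (seeded) in addition to the warm start; the best
#'   result is kept. A `seed` is mandatory.
#' * `"exhaustive"`: global optimum by full enumeration of the grid
#'   product; only permitted when the product of grid sizes is at most
#'   `budget`.
#'
#' Samples missing any panel cell at its working concentration are
#' excluded from the optimization (count recorded).
#'
#' @param x An [assay_matrix()].
#' @param panel Character vector of panel antigen names.
#' @param objective An [objective_spec()].
#' @param method `"restart"`, `"coordinate"`, or `"exhaustive"`.
#' @param n_restarts Number of random restarts (restart method); default 25.
#' @param seed Integer seed, required for `method = "restart"`.
#' @param concentrations Optional named vector antigen -> concentration
#'   (nM); default chosen by [choose_concentrations()].
#' @param budget Maximum grid-product size for exhaustive search.
#'
#' @return An object of class `"cutoff_vector"`: named `cutoffs`, named
#'   `concentration_nM`, `objective_value`, achieved `sens`/`spec`,
#'   `provenance` (one of `single`, `joint-coordinate`, `joint-exhaustive`,
#'   `joint-restart`), `objective`, `n_excluded`.
#' @export
optimize_joint <- function(x, panel,
                           objective = objective_spec(),
                           method = c("restart", "coordinate", "exhaustive"),
                           n_restarts = 25L, seed = NULL,
                           concentrations = NULL, budget = 250000) {
  if (!inherits(x, "assay_matrix")) stop_arg("`x` must be an assay_matrix")
  method <- match.arg(method)
  if (!inherits(objective, "objective")) {
    stop_arg("`objective` must be an objective_spec() object")
  }
  if (length(panel) == 0L) stop_arg("`panel` must contain at least one antigen")
  miss <- setdiff(panel, x$antigens)
  if (length(miss)) stop_arg("panel antigen(s) absent from matrix: ",
                             paste(miss, collapse = ", "))
  if (method == "restart" && is.null(seed)) {
    stop_arg("`seed` is required for method = 'restart'")
  }
  if (is.null(concentrations)) {
    concentrations <- choose_concentrations(x, panel)
  } else {
    if (is.null(names(concentrations)) || !all(panel %in% names(concentrations))) {
      stop_arg("`concentrations` must be a named vector covering the panel")
    }
    concentrations <- concentrations[panel]
  }

  # OD matrix at working concentrations; drop samples with missing cells
  p <- length(panel)
  M <- sapply(panel, function(a) x$od[, a, as.character(concentrations[[a]])])
  M <- matrix(M, ncol = p, dimnames = list(x$samples$sample_id, panel))
  keep <- stats::complete.cases(M)
  n_excluded <- sum(!keep)
  M <- M[keep, , drop = FALSE]
  is_cancer <- x$samples$status[keep] == "cancer"
  if (!any(is_cancer) || all(is_cancer)) {
    stop_arg("need evaluable samples in both disease groups")
  }
  grids <- lapply(seq_len(p), function(j) candidate_grid(M[, j]))

  fit <- switch(method,
    coordinate = joint_coordinate(M, is_cancer, grids, objective, warm = TRUE),
    restart = with_seed(seed, joint_restart(M, is_cancer, grids, objective,
                                            n_restarts)),
    exhaustive = joint_exhaustive(M, is_cancer, grids, objective, budget)
  )

  structure(
    list(cutoffs = stats::setNames(fit$cut, panel),
         concentration_nM = stats::setNames(as.numeric(concentrations[panel]), panel),
         objective_value = fit$score, sens = fit$sens, spec = fit$spec,
         provenance = paste0("joint-", method),
         objective = objective, n_excluded = n_excluded),
    class = "cutoff_vector"
  )
}

# panel-level (sens, spec, score) for one cut-off assignment
joint_eval <- function(M, is_cancer, cut, objective) {
  pos <- M > rep(cut, each = nrow(M))
  panelpos <- rowSums(pos) > 0
  sens <- sum(panelpos & is_cancer) / sum(is_cancer)
  spec <- sum(!panelpos & !is_cancer) / sum(!is_cancer)
  list(sens = sens, spec = spec,
       score = objective_score(sens, spec, objective))
}

# one full cyclic coordinate-ascent run from the given starting cut-offs
joint_coordinate_from <- function(M, is_cancer, grids, objective, cut) {
  n_can <- sum(is_cancer)
  n_con <- sum(!is_cancer)
  repeat {
    changed <- FALSE
    for (j in seq_along(grids)) {
      if (length(grids) == 1L) {
        rest <- rep(FALSE, nrow(M))
      } else {
        others <- M[, -j, drop = FALSE] >
          rep(cut[-j], each = nrow(M))
        rest <- rowSums(others) > 0
      }
      free_c <- sort(M[!rest & is_cancer, j])
      free_n <- sort(M[!rest & !is_cancer, j])
      base_tp <- sum(rest & is_cancer)
      base_fp <- sum(rest & !is_cancer)
      g <- grids[[j]]
      tp <- base_tp + (length(free_c) - findInterval(g, free_c))
      fp <- base_fp + (length(free_n) - findInterval(g, free_n))
      sens <- tp / n_can
      spec <- (n_con - fp) / n_con
      score <- objective_score(sens, spec, objective)
      # score at the current cut-off (which may not lie on the grid when
      # the run was randomly initialized)
      cur_tp <- base_tp + sum(free_c > cut[j])
      cur_fp <- base_fp + sum(free_n > cut[j])
      cur_score <- objective_score(cur_tp / n_can, (n_con - cur_fp) / n_con,
                                   objective)
      # accept only strict improvements; among improving ties take the
      # largest cut-off. Score-neutral moves are rejected so cut-offs do
      # not drift above seropositive samples that other panel antigens
      # happen to cover in the training cohort.
      best <- which.max(score)
      ties <- which(score == score[best])
      best <- ties[length(ties)]  # grid ascending: largest cut-off
      if (score[best] > cur_score) {
        cut[j] <- g[best]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  ev <- joint_eval(M, is_cancer, cut, objective)
  list(cut = cut, sens = ev$sens, spec = ev$spec, score = ev$score)
}

joint_coordinate <- function(M, is_cancer, grids, objective, warm = TRUE) {
  # warm start: per-antigen single optima
  cut0 <- vapply(seq_along(grids), function(j) {
    optimize_single(M[is_cancer, j], M[!is_cancer, j], objective)$cutoff
  }, numeric(1))
  joint_coordinate_from(M, is_cancer, grids, objective, cut0)
}

joint_restart <- function(M, is_cancer, grids, objective, n_restarts) {
  best <- joint_coordinate(M, is_cancer, grids, objective)
  for (r in seq_len(n_restarts)) {
    cut0 <- vapply(grids, function(g) g[sample.int(length(g), 1L)], numeric(1))
    fit <- joint_coordinate_from(M, is_cancer, grids, objective, cut0)
    if (fit$score > best$score) best <- fit
  }
  best
}

joint_exhaustive <- function(M, is_cancer, grids, objective, budget) {
  sizes <- lengths(grids)
  total <- prod(sizes)
  if (total > budget) {
    stop_arg("exhaustive search needs ", format(total, big.mark = ","),
             " evaluations (budget ", format(budget, big.mark = ","),
             "); use method = 'coordinate' or 'restart'")
  }
  idx <- as.matrix(expand.grid(lapply(sizes, seq_len), KEEP.OUT.ATTRS = FALSE))
  best <- NULL
  for (i in seq_len(nrow(idx))) {
    cut <- vapply(seq_along(grids), function(j) grids[[j]][idx[i, j]], numeric(1))
    ev <- joint_eval(M, is_cancer, cut, objective)
    # ">=" with indices enumerated in increasing order biases ties toward
    # larger cut-offs (matching the single-antigen tie-break)
    if (is.null(best) || ev$score >= best$score) {
      best <- list(cut = cut, sens = ev$sens, spec = ev$spec, score = ev$score)
    }
  }
  best
}

#' Write / read a cut-off vector as JSON
#'
#' The JSON schema is `{antigen: {cutoff, concentration_nM}}` plus an
#' `.objective` metadata block (`objective_value`, `sens`, `spec`,
#' `provenance`, objective kind).
#'
#' @param cutoffs A `"cutoff_vector"` from [optimize_joint()].
#' @param path Output file path.
#' @return `write_cutoffs()`: invisibly, `path`. `read_cutoffs()`: a
#'   `"cutoff_vector"` object.
#' @export
write_cutoffs <- function(cutoffs, path) {
  if (!inherits(cutoffs, "cutoff_vector")) {
    stop_arg("`cutoffs` must be a cutoff_vector")
  }
  body <- lapply(names(cutoffs$cutoffs), function(a) {
    list(cutoff = cutoffs$cutoffs[[a]],
         concentration_nM = cutoffs$concentration_nM[[a]])
  })
  names(body) <- names(cutoffs$cutoffs)
  body$.objective <- list(
    objective_value = cutoffs$objective_value,
    sens = cutoffs$sens, spec = cutoffs$spec,
    provenance = cutoffs$provenance,
    kind = cutoffs$objective$kind
  )
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cutoffs
#' @export
read_cutoffs <- function(path) {
  body <- jsonlite::read_json(path, simplifyVector = TRUE)
  meta <- body$.objective
  body$.objective <- NULL
  ants <- names(body)
  structure(
    list(cutoffs = stats::setNames(vapply(body, `[[`, numeric(1), "cutoff"), ants),
         concentration_nM = stats::setNames(
           vapply(body, `[[`, numeric(1), "concentration_nM"), ants),
         objective_value = meta$objective_value,
         sens = meta$sens, spec = meta$spec,
         provenance = meta$provenance,
         objective = objective_spec(meta$kind),
         n_excluded = NA_integer_),
    class = "cutoff_vector"
  )
}

#' @export
print.cutoff_vector <- function(x, ...) {
  cat(sprintf("Cut-off vector (%s), objective %.4f (sens %s, spec %s)\n",
              x$provenance, x$objective_value,
              format_pct(x$sens), format_pct(x$spec)))
  df <- data.frame(antigen = names(x$cutoffs),
                   cutoff = round(unname(x$cutoffs), 4),
                   concentration_nM = unname(x$concentration_nM[names(x$cutoffs)]))
  print(df, row.names = FALSE)
  invisible(x)
}
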