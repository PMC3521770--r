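# Independent oracles and small fixture builders shared across tests.

# Brute-force two-sample K-S distance via stats::ecdf evaluated at every
# pooled point (independent of the package's findInterval implementation).
ks_brute <- function(x, y) {
  fx <- stats::ecdf(x)
  fy <- stats::ecdf(y)
  pts <- sort(unique(c(x, y)))
  max(abs(fx(pts) - fy(pts)))
}

# Build a one-antigen assay matrix from raw cancer/control OD vectors.
toy_matrix <- function(cancer, control, antigen = "A", conc = 100) {
  n <- length(cancer) + length(control)
  samples <- data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    status = rep(c("cancer", "control"), c(length(cancer), length(control))),
    stringsAsFactors = FALSE
  )
  od <- array(c(cancer, control), dim = c(n, 1, 1),
              dimnames = list(samples$sample_id, antigen, as.character(conc)))
  assay_matrix(samples, od)
}

# Build a multi-antigen assay matrix from cancer/control OD matrices
# (rows = samples, columns = antigens).
multi_matrix <- function(mc, mn, antigens = colnames(mc), conc = 100) {
  if (is.null(antigens)) antigens <- sprintf("ag%d", seq_len(ncol(mc)))
  n <- nrow(mc) + nrow(mn)
  samples <- data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    status = rep(c("cancer", "control"), c(nrow(mc), nrow(mn))),
    stringsAsFactors = FALSE
  )
  od <- array(rbind(mc, mn), dim = c(n, ncol(mc), 1),
              dimnames = list(samples$sample_id, antigens, as.character(conc)))
  assay_matrix(samples, od)
}

# Hand-rolled cut-off vector (bypasses the optimizer) for fixture tests.
manual_cutoffs <- function(cutoffs, conc = 100) {
  structure(
    list(cutoffs = cutoffs,
         concentration_nM = stats::setNames(rep(conc, length(cutoffs)),
                                            names(cutoffs)),
         objective_value = NA_real_, sens = NA_real_, spec = NA_real_,
         provenance = "manual", objective = objective_spec(),
         n_excluded = 0L),
    class = "cutoff_vector"
  )
}

# Independent exhaustive joint-panel oracle: enumerate the full grid
# product with its own (apply/any-based) OR-rule evaluation.
joint_brute <- function(mc, mn, objective = objective_spec()) {
  p <- ncol(mc)
  grids <- lapply(seq_len(p), function(j) candidate_grid(c(mc[, j], mn[, j])))
  combos <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  best <- -Inf
  for (i in seq_len(nrow(combos))) {
    cut <- combos[i, ]
    pos_c <- apply(mc, 1, function(r) any(r > cut))
    pos_n <- apply(mn, 1, function(r) any(r > cut))
    sens <- mean(pos_c)
    spec <- mean(!pos_n)
    sc <- switch(objective$kind,
                 youden_sum = objective$w_sens * sens + objective$w_spec * spec,
                 sens_at_spec_floor =
                   sens - 1000 * max(0, objective$spec_floor - spec))
    if (sc > best) best <- sc
  }
  best
}

# Random joint-optimization instance with coarse grids: values on a 0.1
# lattice spanning 0.1-0.8, so each antigen has at most 8 unique pooled
# values and hence a candidate grid of at most 9 points.
random_coarse_instance <- function(n = 8, p = 3) {
  mc <- matrix(sample(seq(0.1, 0.7, by = 0.1), n * p, replace = TRUE), n, p)
  mc <- mc + matrix(sample(c(0, 0.1), n * p, replace = TRUE), n, p)
  mn <- matrix(sample(seq(0.1, 0.8, by = 0.1), n * p, replace = TRUE), n, p)
  colnames(mc) <- colnames(mn) <- sprintf("ag%d", seq_len(p))
  list(mc = mc, mn = mn)
}
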