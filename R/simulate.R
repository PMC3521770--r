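#' Simulation specification for one antigen
#'
#' Describes the generative model for a single antigen's ELISA signal in a
#' synthetic case-control cohort. Optical densities follow a two-component
#' lognormal mixture: every control, and every non-seropositive cancer,
#' draws its signal from a common lognormal background, while a fraction
#' `pi` of cancers are seropositive and draw from a higher lognormal
#' component. Signals saturate at `od_max` and scale across plate coating
#' concentrations with a hyperbolic binding curve with half-maximal
#' concentration `k_half` (see [titration_signal()]).
#'
#' @param name Antigen name (unique within a [sim_params()] object).
#' @param pi Seropositivity probability among cancers, in `[0, 1]`.
#' @param background_log_mean,background_log_sd Log-scale mean and sd of the
#'   background OD component shared by controls and seronegative cancers.
#' @param positive_log_mean,positive_log_sd Log-scale mean and sd of the
#'   seropositive OD component; `positive_log_mean` must exceed
#'   `background_log_mean`.
#' @param od_max Saturation ceiling for the OD readout (plate-reader
#'   ceiling); all simulated ODs are capped at this value.
#' @param k_half Coating concentration (nM) at half-maximal binding.
#'
#' @return An object of class `"antigen_spec"`.
#' @seealso [sim_params()], [simulate_cohort()]
#' @export
#' @examples
#' antigen_spec("p53", pi = 0.09)
antigen_spec <- function(name, pi,
                         background_log_mean = log(0.10),
                         background_log_sd = 0.25,
                         positive_log_mean = log(1.80),
                         positive_log_sd = 0.35,
                         od_max = 3.5,
                         k_half = 40) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_arg("`name` must be a non-empty string")
  }
  if (!is_fraction(pi)) stop_arg("`pi` must be a probability in [0, 1]")
  if (!is_scalar_number(background_log_mean) || !is_scalar_number(positive_log_mean)) {
    stop_arg("log-means must be finite numbers")
  }
  if (positive_log_mean <= background_log_mean) {
    stop_arg("`positive_log_mean` must exceed `background_log_mean`")
  }
  if (!is_scalar_number(background_log_sd) || background_log_sd < 0 ||
      !is_scalar_number(positive_log_sd) || positive_log_sd < 0) {
    stop_arg("log-sds must be non-negative numbers")
  }
  if (!is_scalar_number(od_max) || od_max <= 0) stop_arg("`od_max` must be > 0")
  if (!is_scalar_number(k_half) || k_half <= 0) stop_arg("`k_half` must be > 0")
  structure(
    list(name = name, pi = pi,
         background_log_mean = background_log_mean,
         background_log_sd = background_log_sd,
         positive_log_mean = positive_log_mean,
         positive_log_sd = positive_log_sd,
         od_max = od_max, k_half = k_half),
    class = "antigen_spec"
  )
}

#' Parameters for a synthetic matched case-control ELISA cohort
#'
#' @param antigens A list of [antigen_spec()] objects (a single spec is
#'   promoted to a list). Names must be unique.
#' @param n_cancer,n_control Cohort sizes; both at least 1. Cancers and
#'   controls are 1:1 matched up to the smaller of the two.
#' @param seed Integer seed; [simulate_cohort()] is a pure function of the
#'   parameters including this seed.
#' @param replicate_cv Coefficient of variation of the multiplicative
#'   replicate (well-to-well) noise; non-negative. Default 0.1.
#' @param concentrations Plate coating concentrations in nM, strictly
#'   positive and non-empty. The highest concentration is the reference at
#'   which the mixture components are parameterized.
#' @param n_replicates Wells per (sample, antigen, concentration); default 2
#'   (assays run in duplicate).
#' @param responder_rho Optional cross-antigen correlation knob in `[0, 1)`:
#'   each cancer draws a latent "responder" flag with probability 1/2 and
#'   its per-antigen seropositivity probability becomes `pi * (1 + rho)`
#'   (responder) or `pi * (1 - rho)` (non-responder), truncated to `[0, 1]`.
#'   The marginal seropositivity stays `pi`; `rho = 0` (default) gives
#'   independence across antigens.
#' @param cohort Label stored in the sample table (e.g. `"cohort1"`).
#'
#' @return An object of class `"sim_params"`.
#' @export
sim_params <- function(antigens,
                       n_cancer = 165L, n_control = 165L,
                       seed = 1L,
                       replicate_cv = 0.1,
                       concentrations = c(160, 100, 50, 25, 12.5),
                       n_replicates = 2L,
                       responder_rho = 0,
                       cohort = "cohort1") {
  if (inherits(antigens, "antigen_spec")) antigens <- list(antigens)
  if (!is.list(antigens) || length(antigens) == 0L ||
      !all(vapply(antigens, inherits, logical(1), "antigen_spec"))) {
    stop_arg("`antigens` must be a non-empty list of antigen_spec objects")
  }
  nm <- vapply(antigens, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop_arg("antigen names must be unique")
  names(antigens) <- nm
  if (!is_scalar_number(n_cancer) || n_cancer < 1 ||
      !is_scalar_number(n_control) || n_control < 1) {
    stop_arg("`n_cancer` and `n_control` must be at least 1")
  }
  if (!is_scalar_number(seed)) stop_arg("`seed` must be a single number")
  if (!is_scalar_number(replicate_cv) || replicate_cv < 0) {
    stop_arg("`replicate_cv` must be non-negative")
  }
  if (!is.numeric(concentrations) || length(concentrations) == 0L ||
      any(!is.finite(concentrations)) || any(concentrations <= 0)) {
    stop_arg("`concentrations` must be non-empty and strictly positive")
  }
  if (anyDuplicated(concentrations)) stop_arg("`concentrations` must be distinct")
  if (!is_scalar_number(n_replicates) || n_replicates < 1) {
    stop_arg("`n_replicates` must be at least 1")
  }
  if (!is_scalar_number(responder_rho) || responder_rho < 0 || responder_rho >= 1) {
    stop_arg("`responder_rho` must lie in [0, 1)")
  }
  structure(
    list(antigens = antigens,
         n_cancer = as.integer(n_cancer), n_control = as.integer(n_control),
         seed = as.integer(seed),
         replicate_cv = replicate_cv,
         concentrations = sort(as.numeric(concentrations), decreasing = TRUE),
         n_replicates = as.integer(n_replicates),
         responder_rho = responder_rho,
         cohort = cohort),
    class = "sim_params"
  )
}

#' Hyperbolic titration scaling of an ELISA signal
#'
#' Scales a baseline OD measured at a reference coating concentration to
#' another concentration using a saturable (hyperbolic) binding curve with
#' half-maximal concentration `k_half`, normalized so that the reference
#' concentration returns `base_od` unchanged. The result is capped at the
#' saturation ceiling `od_max`.
#'
#' The scaling factor is
#' \deqn{\frac{c/(c + K)}{c_{ref}/(c_{ref} + K)}}
#' so a concentration of 0 (no antigen coated) yields OD 0.
#'
#' @param base_od OD at the reference concentration; non-negative.
#' @param conc Target coating concentration in nM; non-negative.
#' @param k_half Half-maximal binding concentration in nM; positive.
#' @param od_max Saturation ceiling; positive.
#' @param reference_conc Reference coating concentration in nM; positive.
#'
#' @return OD at `conc`, in `[0, od_max]`. Vectorized over `base_od` and
#'   `conc`.
#' @export
#' @examples
#' titration_signal(1.0, conc = 50, k_half = 50, od_max = 3.5,
#'                  reference_conc = 100)  # 0.75
titration_signal <- function(base_od, conc, k_half, od_max, reference_conc) {
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop_arg("`conc` must be non-negative")
  }
  if (any(!is.finite(base_od)) || any(base_od < 0)) {
    stop_arg("`base_od` must be non-negative")
  }
  if (!is_scalar_number(k_half) || k_half <= 0) stop_arg("`k_half` must be > 0")
  if (!is_scalar_number(od_max) || od_max <= 0) stop_arg("`od_max` must be > 0")
  if (!is_scalar_number(reference_conc) || reference_conc <= 0) {
    stop_arg("`reference_conc` must be > 0")
  }
  fac <- (conc / (conc + k_half)) / (reference_conc / (reference_conc + k_half))
  pmin(base_od * fac, od_max)
}

#' Simulate a matched case-control ELISA cohort
#'
#' Generates a synthetic cohort under the lognormal seropositive-mixture
#' model described in [antigen_spec()]: controls always draw from the
#' background component; each cancer is seropositive for each antigen with
#' probability `pi` (independently across antigens unless
#' `responder_rho > 0`) and then draws from the elevated component. Baseline
#' signals at the highest (reference) coating concentration are scaled to
#' the other concentrations with [titration_signal()] and measured in
#' `n_replicates` wells with multiplicative Gaussian noise of coefficient of
#' variation `replicate_cv`, truncated at 0 and capped at `od_max`.
#'
#' Matching covariates (age, gender, smoking) are generated per matched
#' pair as plumbing metadata only; they never enter any computation.
#' Generation is a pure function of `params` (including `params$seed`): the
#' same parameters always yield bit-identical tables.
#'
#' @param params A [sim_params()] object.
#'
#' @return An object of class `"sim_cohort"`: a list with elements
#'   `samples` (data frame: `sample_id`, `cohort`, `status`, `match_id`,
#'   `age`, `gender`, `smoking`), `measurements` (long data frame:
#'   `sample_id`, `antigen`, `concentration_nM`, `replicate_index`, `od`),
#'   `od` (numeric array of replicate-mean ODs, samples x antigens x
#'   concentrations), `seropositive` (logical matrix, samples x antigens,
#'   the latent mixture labels; useful for oracle checks), and `params`.
#' @seealso [write_cohort()], [as_assay_matrix()]
#' @export
#' @examples
#' p <- sim_params(list(antigen_spec("A", pi = 0.2)),
#'                 n_cancer = 10, n_control = 10, seed = 42,
#'                 concentrations = c(100, 50))
#' sim <- simulate_cohort(p)
#' head(sim$measurements)
simulate_cohort <- function(params) {
  if (!inherits(params, "sim_params")) stop_arg("`params` must be a sim_params object")
  with_seed(params$seed, simulate_cohort_impl(params))
}

simulate_cohort_impl <- function(params) {
  nc <- params$n_cancer
  nn <- params$n_control
  n <- nc + nn
  ants <- params$antigens
  A <- length(ants)
  concs <- params$concentrations
  C <- length(concs)
  R <- params$n_replicates
  ref <- max(concs)

  sample_id <- c(sprintf("%s_C%04d", params$cohort, seq_len(nc)),
                 sprintf("%s_N%04d", params$cohort, seq_len(nn)))
  status <- rep(c("cancer", "control"), c(nc, nn))
  npair <- min(nc, nn)
  match_of <- function(i, grp_n) ifelse(i <= npair, sprintf("M%04d", i), NA_character_)
  match_id <- c(match_of(seq_len(nc)), match_of(seq_len(nn)))

  # pair-level matching covariates; unmatched samples get their own draw
  n_units <- npair + (nc - npair) + (nn - npair)
  age_u <- round(pmin(87, pmax(34, stats::rnorm(n_units, 63, 9))))
  gender_u <- sample(c("M", "F"), n_units, replace = TRUE, prob = c(0.6, 0.4))
  smoking_u <- sample(c("current", "ex-smoker", "never"), n_units,
                      replace = TRUE, prob = c(0.45, 0.45, 0.10))
  unit_of <- c(seq_len(nc), c(seq_len(npair), npair + (nc - npair) + seq_len(max(0, nn - npair))))
  samples <- data.frame(
    sample_id = sample_id, cohort = params$cohort, status = status,
    match_id = match_id,
    age = age_u[unit_of], gender = gender_u[unit_of], smoking = smoking_u[unit_of],
    stringsAsFactors = FALSE
  )

  # latent seropositivity among cancers (controls always background)
  rho <- params$responder_rho
  responder <- if (rho > 0) stats::rbinom(nc, 1L, 0.5) else integer(nc)
  pis <- vapply(ants, `[[`, numeric(1), "pi")
  seropos <- matrix(FALSE, n, A, dimnames = list(sample_id, names(ants)))
  for (a in seq_len(A)) {
    p_a <- pmin(1, pmax(0, pis[a] * (1 + rho * (2 * responder - 1))))
    seropos[seq_len(nc), a] <- stats::runif(nc) < p_a
  }

  # baseline OD at the reference concentration
  base <- matrix(0, n, A, dimnames = list(sample_id, names(ants)))
  for (a in seq_len(A)) {
    sp <- ants[[a]]
    bg <- stats::rlnorm(n, sp$background_log_mean, sp$background_log_sd)
    pos <- stats::rlnorm(n, sp$positive_log_mean, sp$positive_log_sd)
    base[, a] <- pmin(ifelse(seropos[, a], pos, bg), sp$od_max)
  }

  # mean OD per concentration via the titration curve, then replicate noise
  od_mean <- array(0, dim = c(n, A, C),
                   dimnames = list(sample_id, names(ants), as.character(concs)))
  for (a in seq_len(A)) {
    sp <- ants[[a]]
    for (k in seq_len(C)) {
      od_mean[, a, k] <- titration_signal(base[, a], concs[k], sp$k_half,
                                          sp$od_max, ref)
    }
  }

  od_rep <- array(0, dim = c(n, A, C, R))
  odm_max <- rep(vapply(ants, `[[`, numeric(1), "od_max"), each = n)
  for (k in seq_len(C)) {
    for (r in seq_len(R)) {
      noise <- 1 + stats::rnorm(n * A, 0, params$replicate_cv)
      od_rep[, , k, r] <- pmin(pmax(od_mean[, , k] * noise, 0), odm_max)
    }
  }

  measurements <- data.frame(
    sample_id = rep(sample_id, times = A * C * R),
    antigen = rep(rep(names(ants), each = n), times = C * R),
    concentration_nM = rep(rep(concs, each = n * A), times = R),
    replicate_index = rep(seq_len(R), each = n * A * C),
    od = as.vector(od_rep),
    stringsAsFactors = FALSE
  )

  od_bar <- apply(od_rep, c(1, 2, 3), mean)
  dimnames(od_bar) <- dimnames(od_mean)

  structure(
    list(samples = samples, measurements = measurements, od = od_bar,
         seropositive = seropos, params = params),
    class = "sim_cohort"
  )
}

#' Write a simulated cohort to CSV files
#'
#' Writes `samples.csv` and `measurements.csv` (UTF-8, dot decimal
#' separator, fixed column names) in the schemas consumed by
#' [read_measurements()].
#'
#' @param sim A `"sim_cohort"` object from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths of the two files.
#' @export
write_cohort <- function(sim, dir) {
  if (!inherits(sim, "sim_cohort")) stop_arg("`sim` must be a sim_cohort object")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp <- file.path(dir, "samples.csv")
  mp <- file.path(dir, "measurements.csv")
  utils::write.csv(sim$samples, sp, row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$measurements, mp, row.names = FALSE, quote = FALSE)
  invisible(c(samples = sp, measurements = mp))
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic ELISA cohort:", x$params$cohort, "\n")
  cat(sprintf("  %d cancers, %d controls; %d antigens; concentrations (nM): %s\n",
              x$params$n_cancer, x$params$n_control, length(x$params$antigens),
              paste(x$params$concentrations, collapse = ", ")))
  cat(sprintf("  %d measurement rows (%d replicates)\n",
              nrow(x$measurements), x$params$n_replicates))
  invisible(x)
}
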