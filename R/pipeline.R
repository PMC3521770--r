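#' Configuration for the end-to-end panel extension pipeline
#'
#' Bundles every tunable of the two-cohort workflow: simulate (or load)
#' a discovery cohort and an optimization cohort, screen candidates on the
#' discovery cohort with the K-S distance, confirm leads on the
#' optimization cohort at a stricter threshold, jointly re-optimize
#' cut-offs for the base panel plus confirmed leads, quantify additivity
#' and lead combinations, validate the frozen cut-offs back on the
#' discovery cohort, and convert performance into PPV.
#'
#' The cohort roles are explicit (`screen` on cohort 1, `optimize` on
#' cohort 2, validation back on cohort 1), mirroring the common design in
#' which the discovery cohort doubles as the independent validation set
#' for cut-offs frozen on the second cohort.
#'
#' @param out_dir Directory for the report bundle.
#' @param seed Integer seed driving every stochastic stage (mandatory).
#' @param antigens Named list of [antigen_spec()]; default
#'   [default_antigens()].
#' @param base_panel,candidate_leads Antigen names; defaults
#'   [default_base_panel()] and [default_lead_panel()].
#' @param n_screen,n_optimize Length-2 integer vectors
#'   `(n_cancer, n_control)` for the two cohorts; defaults 165/165 and
#'   100/100.
#' @param concentrations Coating concentrations (nM) simulated for both
#'   cohorts; default the 5-point titration `c(160, 100, 50, 25, 12.5)`.
#' @param stage1_threshold,stage1_concentrations Permissive first-pass
#'   screen; defaults 0.13 at 100/50 nM (the abridged 2-point view).
#' @param stage2_threshold,stage2_concentrations Stricter confirmation
#'   screen; defaults 0.2 at 160/50 nM.
#' @param objective An [objective_spec()] for cut-off optimization. The
#'   pipeline default maximizes sensitivity under a 99% specificity floor,
#'   the operating regime a screening panel with a low-prevalence target
#'   population is tuned to; pass `objective_spec("youden_sum")` for the
#'   unconstrained sens + spec criterion.
#' @param method,n_restarts Joint optimizer settings (see
#'   [optimize_joint()]).
#' @param prevalence Disease prevalence for the PPV conversion; default
#'   0.024 (2.4%, a high-risk screening population).
#' @param max_k Largest lead-subset size in the combination scan.
#' @param replicate_cv,responder_rho Generator noise and cross-antigen
#'   correlation knobs (see [sim_params()]).
#'
#' @return An object of class `"pipeline_config"`.
#' @seealso [run_pipeline()], [read_pipeline_config()]
#' @export
pipeline_config <- function(out_dir, seed,
                            antigens = default_antigens(),
                            base_panel = default_base_panel(),
                            candidate_leads = default_lead_panel(),
                            n_screen = c(165L, 165L),
                            n_optimize = c(100L, 100L),
                            concentrations = c(160, 100, 50, 25, 12.5),
                            stage1_threshold = 0.13,
                            stage1_concentrations = c(100, 50),
                            stage2_threshold = 0.2,
                            stage2_concentrations = c(160, 50),
                            objective = objective_spec("sens_at_spec_floor",
                                                       spec_floor = 0.99),
                            method = "restart", n_restarts = 25L,
                            prevalence = 0.024, max_k = 3L,
                            replicate_cv = 0.1, responder_rho = 0) {
  if (missing(out_dir) || !is.character(out_dir)) stop_arg("`out_dir` is required")
  if (missing(seed) || !is_scalar_number(seed)) {
    stop_arg("an integer `seed` is required")
  }
  if (!is_fraction(stage1_threshold) || !is_fraction(stage2_threshold)) {
    stop_arg("stage thresholds must lie in [0, 1]")
  }
  if (!is_fraction(prevalence)) stop_arg("`prevalence` must lie in [0, 1]")
  nm <- vapply(antigens, `[[`, character(1), "name")
  if (!all(base_panel %in% nm)) stop_arg("`base_panel` names not in `antigens`")
  if (!all(candidate_leads %in% nm)) {
    stop_arg("`candidate_leads` names not in `antigens`")
  }
  if (length(intersect(base_panel, candidate_leads))) {
    stop_arg("`base_panel` and `candidate_leads` must be disjoint")
  }
  if (!all(stage1_concentrations %in% concentrations) ||
      !all(stage2_concentrations %in% concentrations)) {
    stop_arg("stage concentrations must be among the simulated concentrations")
  }
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), antigens = antigens,
         base_panel = base_panel, candidate_leads = candidate_leads,
         n_screen = as.integer(n_screen), n_optimize = as.integer(n_optimize),
         concentrations = concentrations,
         stage1_threshold = stage1_threshold,
         stage1_concentrations = stage1_concentrations,
         stage2_threshold = stage2_threshold,
         stage2_concentrations = stage2_concentrations,
         objective = objective, method = method,
         n_restarts = as.integer(n_restarts),
         prevalence = prevalence, max_k = as.integer(max_k),
         replicate_cv = replicate_cv, responder_rho = responder_rho),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the arguments of [pipeline_config()]; `antigens` is a
#' list of maps with at least `name` and `pi` (remaining [antigen_spec()]
#' fields optional), and `objective` a map with `kind` and optionally
#' `spec_floor`, `w_sens`, `w_spec`.
#'
#' @param path Path to the YAML file.
#' @param out_dir,seed Optional overrides of the configured values.
#' @return A `"pipeline_config"` object.
#' @export
read_pipeline_config <- function(path, out_dir = NULL, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$antigens)) {
    y$antigens <- lapply(y$antigens, function(a) do.call(antigen_spec, a))
    names(y$antigens) <- vapply(y$antigens, `[[`, character(1), "name")
  }
  if (!is.null(y$objective)) y$objective <- do.call(objective_spec, y$objective)
  if (!is.null(out_dir)) y$out_dir <- out_dir
  if (!is.null(seed)) y$seed <- seed
  do.call(pipeline_config, y)
}

#' Run the end-to-end panel extension pipeline
#'
#' Executes simulate, screen, confirm, optimize, evaluate,
#' validate and report (see [pipeline_config()] for the stage layout) and
#' writes a report bundle to `config$out_dir`:
#'
#' * `cohort1/`, `cohort2/` - simulated `samples.csv` / `measurements.csv`;
#' * `ks_screen.csv` - first-pass K-S screen on cohort 1;
#' * `ks_confirm.csv` - confirmation K-S scores on cohort 2 for the
#'   stage-1 leads;
#' * `cutoffs.json` - jointly optimized cut-offs (base + confirmed leads);
#' * `additivity.csv` - per-lead overall/additive positivity and net gain
#'   on the optimization cohort;
#' * `combinations.csv` - OR-rule performance on the validation cohort for
#'   the base panel plus every lead subset up to `max_k`;
#' * `validation.csv` - base and extended panel performance on both
#'   cohorts (training vs frozen-cut-off validation);
#' * `ppv.json` - PPV at the configured prevalence for the base and
#'   extended panels on the validation cohort;
#' * `run_log.txt` - seeds, sizes, thresholds, exclusion counts.
#'
#' Re-running with an identical configuration reproduces every output file
#' byte for byte.
#'
#' @param config A [pipeline_config()] (or a path to a YAML file accepted
#'   by [read_pipeline_config()]).
#' @return Invisibly, a list of class `"pipeline_result"` holding every
#'   intermediate object and the output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    stop_arg("`config` must be a pipeline_config or a YAML path")
  }
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  log_lines <- character(0)
  log_add <- function(...) log_lines <<- c(log_lines, paste0(...))

  # --- simulate the two cohorts ------------------------------------------
  mk_params <- function(cohort, n, seed_off) {
    sim_params(config$antigens, n_cancer = n[1], n_control = n[2],
               seed = config$seed + seed_off,
               replicate_cv = config$replicate_cv,
               concentrations = config$concentrations,
               responder_rho = config$responder_rho,
               cohort = cohort)
  }
  sim1 <- simulate_cohort(mk_params("cohort1", config$n_screen, 1L))
  sim2 <- simulate_cohort(mk_params("cohort2", config$n_optimize, 2L))
  f1 <- write_cohort(sim1, file.path(out, "cohort1"))
  f2 <- write_cohort(sim2, file.path(out, "cohort2"))
  m1 <- suppressMessages(read_measurements(f1[["samples"]], f1[["measurements"]]))
  m2 <- suppressMessages(read_measurements(f2[["samples"]], f2[["measurements"]]))
  log_add("seed: ", config$seed)
  log_add("cohort1 (screen/validate): ", config$n_screen[1], " cancer / ",
          config$n_screen[2], " control, seed ", config$seed + 1L)
  log_add("cohort2 (optimize): ", config$n_optimize[1], " cancer / ",
          config$n_optimize[2], " control, seed ", config$seed + 2L)

  # --- stage 1 screen on cohort 1 ----------------------------------------
  screen <- screen_leads(m1, config$stage1_threshold,
                         config$stage1_concentrations, rule = "any")
  utils::write.csv(screen, file.path(out, "ks_screen.csv"), row.names = FALSE)
  stage1_leads <- intersect(
    config$candidate_leads,
    unique(screen$antigen[screen$selected])
  )
  log_add("stage 1: threshold ", config$stage1_threshold, " at ",
          paste(config$stage1_concentrations, collapse = "/"), " nM; ",
          sum(unique(screen$antigen) %in% screen$antigen[screen$selected]),
          " antigen(s) selected, ", length(stage1_leads), " candidate lead(s)")

  # --- stage 2 confirmation on cohort 2 ----------------------------------
  confirm_all <- screen_leads(m2, config$stage2_threshold,
                              config$stage2_concentrations, rule = "any")
  confirm <- confirm_all[confirm_all$antigen %in% stage1_leads, ]
  utils::write.csv(confirm, file.path(out, "ks_confirm.csv"), row.names = FALSE)
  confirmed <- intersect(config$candidate_leads,
                         unique(confirm$antigen[confirm$selected]))
  log_add("stage 2: threshold ", config$stage2_threshold, " at ",
          paste(config$stage2_concentrations, collapse = "/"), " nM; ",
          length(confirmed), " confirmed lead(s): ",
          paste(confirmed, collapse = ", "))

  # --- joint cut-off optimization on cohort 2 ----------------------------
  panel <- c(config$base_panel, confirmed)
  cutoffs <- optimize_joint(m2, panel, objective = config$objective,
                            method = config$method,
                            n_restarts = config$n_restarts,
                            seed = config$seed + 3L)
  write_cutoffs(cutoffs, file.path(out, "cutoffs.json"))
  log_add("optimizer: ", cutoffs$provenance, ", objective ",
          format(cutoffs$objective_value), ", ", cutoffs$n_excluded,
          " sample(s) excluded")

  # --- additivity of each confirmed lead (optimization cohort) -----------
  add_rows <- lapply(confirmed, function(ld) {
    r <- additive_analysis(m2, cutoffs, config$base_panel, ld)
    data.frame(lead = ld,
               overall_pos_cancer = r$overall_pos_cancer,
               overall_pos_control = r$overall_pos_control,
               additive_pos_cancer = r$additive_pos_cancer,
               additive_pos_control = r$additive_pos_control,
               net_additive_gain = r$net_additive_gain,
               overall_cancer_pct = format_pct(r$overall_pos_cancer, 0),
               overall_control_pct = format_pct(r$overall_pos_control, 0),
               additive_cancer_pct = format_pct(r$additive_pos_cancer, 0),
               additive_control_pct = format_pct(r$additive_pos_control, 0),
               net_gain_pct = format_pct(r$net_additive_gain, 0),
               stringsAsFactors = FALSE)
  })
  additivity <- if (length(add_rows)) {
    do.call(rbind, add_rows)
  } else {
    data.frame(lead = character(0), overall_pos_cancer = numeric(0),
               overall_pos_control = numeric(0), additive_pos_cancer = numeric(0),
               additive_pos_control = numeric(0), net_additive_gain = numeric(0),
               overall_cancer_pct = character(0), overall_control_pct = character(0),
               additive_cancer_pct = character(0), additive_control_pct = character(0),
               net_gain_pct = character(0), stringsAsFactors = FALSE)
  }
  utils::write.csv(additivity, file.path(out, "additivity.csv"), row.names = FALSE)

  # --- combination scan on the validation cohort -------------------------
  combinations <- combination_scan(m1, cutoffs, config$base_panel,
                                   confirmed, config$max_k)
  utils::write.csv(combinations, file.path(out, "combinations.csv"),
                   row.names = FALSE)

  # --- training vs independent-cohort validation -------------------------
  perf_row <- function(label, cohort, perf) {
    data.frame(panel = label, cohort = cohort,
               tp = perf$tp, fp = perf$fp, tn = perf$tn, fn = perf$fn,
               sens = perf$sens, spec = perf$spec,
               sens_pct = format_pct(perf$sens), spec_pct = format_pct(perf$spec),
               n_excluded = perf$n_excluded, stringsAsFactors = FALSE)
  }
  base_train <- panel_performance(m2, cutoffs, config$base_panel)
  base_val <- validate_external(cutoffs, m1, config$base_panel)
  full_train <- panel_performance(m2, cutoffs, panel)
  full_val <- validate_external(cutoffs, m1, panel)
  validation <- rbind(
    perf_row("base", "cohort2 (training)", base_train),
    perf_row("base", "cohort1 (validation)", base_val),
    perf_row("base+confirmed", "cohort2 (training)", full_train),
    perf_row("base+confirmed", "cohort1 (validation)", full_val)
  )
  utils::write.csv(validation, file.path(out, "validation.csv"),
                   row.names = FALSE)

  # --- PPV at the configured prevalence ----------------------------------
  ppv_base <- ppv(base_val$sens, base_val$spec, config$prevalence)
  ppv_full <- ppv(full_val$sens, full_val$spec, config$prevalence)
  jsonlite::write_json(
    list(prevalence = config$prevalence,
         base = list(sens = ppv_base$sens, spec = ppv_base$spec,
                     ppv = ppv_base$ppv, one_in_n = ppv_base$one_in_n),
         extended = list(sens = ppv_full$sens, spec = ppv_full$spec,
                         ppv = ppv_full$ppv, one_in_n = ppv_full$one_in_n)),
    file.path(out, "ppv.json"), auto_unbox = TRUE, digits = NA)
  log_add("validation (cohort1): base sens ", format_pct(base_val$sens),
          " spec ", format_pct(base_val$spec),
          "; extended sens ", format_pct(full_val$sens),
          " spec ", format_pct(full_val$spec))
  log_add("ppv at prevalence ", config$prevalence, ": base 1 in ",
          ppv_base$one_in_n, ", extended 1 in ", ppv_full$one_in_n)
  writeLines(log_lines, file.path(out, "run_log.txt"))

  invisible(structure(
    list(config = config, matrix_screen = m1, matrix_optimize = m2,
         screen = screen, confirm = confirm, confirmed_leads = confirmed,
         cutoffs = cutoffs, additivity = additivity,
         combinations = combinations, validation = validation,
         ppv_base = ppv_base, ppv_extended = ppv_full,
         out_dir = out),
    class = "pipeline_result"
  ))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Panel extension pipeline run\n")
  cat("  confirmed leads:",
      if (length(x$confirmed_leads)) paste(x$confirmed_leads, collapse = ", ")
      else "(none)", "\n")
  cat(sprintf("  validation: base sens %s / spec %s; extended sens %s / spec %s\n",
              format_pct(x$validation$sens[2]), format_pct(x$validation$spec[2]),
              format_pct(x$validation$sens[4]), format_pct(x$validation$spec[4])))
  cat(sprintf("  PPV: base 1 in %d -> extended 1 in %d (prevalence %s)\n",
              x$ppv_base$one_in_n, x$ppv_extended$one_in_n,
              format_pct(x$config$prevalence)))
  cat("  outputs in", x$out_dir, "\n")
  invisible(x)
}
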