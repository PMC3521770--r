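#' Default synthetic study conditions
#'
#' A ready-made antigen set emulating a two-cohort autoantibody panel
#' extension study: a seven-antigen base panel of established
#' tumour-associated antigens, eight candidate lead constructs with
#' cancer seropositivities of 1-15% (the magnitudes reported for lead
#' antigens in published lung-cancer AAb panels), and six
#' non-discriminating candidates (seropositivity 0) standing in for the
#' bulk of a screening library. All antigens share the default lognormal
#' background; seropositive cancers draw from a well-separated elevated
#' component, so control positivity at optimized cut-offs is near 0-2%.
#'
#' `default_sim_params()` wraps these antigens into the matched cohort
#' designs used throughout: a 165 cancer / 165 control discovery cohort
#' (`"cohort1"`) and a 100 / 100 optimization cohort (`"cohort2"`), each
#' measured in duplicate across a 5-point coating titration
#' (160/100/50/25/12.5 nM).
#'
#' @return `default_antigens()`: named list of [antigen_spec()];
#'   `default_base_panel()` / `default_lead_panel()`: character vectors of
#'   antigen names; `default_sim_params()`: a [sim_params()] object.
#' @export
default_antigens <- function() {
  base <- list(
    antigen_spec("p53", pi = 0.09),
    antigen_spec("NY-ESO-1", pi = 0.07),
    antigen_spec("CAGE", pi = 0.05),
    antigen_spec("GBU4-5", pi = 0.04),
    antigen_spec("SOX2", pi = 0.04),
    antigen_spec("HuD", pi = 0.03),
    antigen_spec("MAGE A4", pi = 0.03)
  )
  leads <- list(
    antigen_spec("alpha enolase BirA", pi = 0.15),
    antigen_spec("EGFR2 C-BirA", pi = 0.01),
    antigen_spec("p53 C-BirA", pi = 0.14),
    antigen_spec("p53-EP C-BirA", pi = 0.07),
    antigen_spec("cytokeratin 20 BirA", pi = 0.10),
    antigen_spec("cytokeratin 8 BirA", pi = 0.04),
    antigen_spec("NY-ESO-1 C-BirA", pi = 0.10),
    antigen_spec("Lmyc2", pi = 0.10)
  )
  nulls <- lapply(sprintf("candidate %02d", 1:6), antigen_spec, pi = 0)
  out <- c(base, leads, nulls)
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' @rdname default_antigens
#' @export
default_base_panel <- function() {
  c("p53", "NY-ESO-1", "CAGE", "GBU4-5", "SOX2", "HuD", "MAGE A4")
}

#' @rdname default_antigens
#' @export
default_lead_panel <- function() {
  c("alpha enolase BirA", "EGFR2 C-BirA", "p53 C-BirA", "p53-EP C-BirA",
    "cytokeratin 20 BirA", "cytokeratin 8 BirA", "NY-ESO-1 C-BirA", "Lmyc2")
}

#' @rdname default_antigens
#' @param cohort `"cohort1"` (165/165 discovery) or `"cohort2"`
#'   (100/100 optimization).
#' @param seed Integer seed passed to [sim_params()].
#' @export
default_sim_params <- function(cohort = c("cohort1", "cohort2"), seed = 1L) {
  cohort <- match.arg(cohort)
  n <- if (cohort == "cohort1") c(165L, 165L) else c(100L, 100L)
  sim_params(default_antigens(),
             n_cancer = n[1], n_control = n[2],
             seed = seed,
             concentrations = c(160, 100, 50, 25, 12.5),
             cohort = cohort)
}
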