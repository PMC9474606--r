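## Country/setting configuration: distribution moments plus decision-rule
## parameters for one funding environment.

.config_fields <- c(
  "name", "currency", "benefit_unit",
  "q_mean", "q_sd", "c_mean", "c_sd", "p_mean", "p_sd",
  "n_candidates", "threshold", "budget", "n_funded",
  "capacity_pct", "phase_years", "phase_target_pct",
  "hta_unit_cost")

#' Build a country configuration
#'
#' Bundles the parameters describing one funding setting: the natural-scale
#' moments of the three log-normal intervention components, and the
#' decision-rule parameters (threshold, budget, funded count, analysis
#' capacity, phase-in schedule).
#'
#' Units: `p_mean`/`p_sd` are in thousands of cases; `c_mean`/`c_sd` and
#' `threshold` are in natural currency units per case (resp. per benefit
#' unit); `budget` is in currency millions; `hta_unit_cost` is the optional
#' per-assessment overhead in natural currency (0 disables it).
#'
#' @param name setting label (e.g. `"UK"`).
#' @param currency currency label (e.g. `"GBP"`); display only.
#' @param benefit_unit health benefit unit, `"QALY"` or `"DALY"` (any label
#'   is accepted; display only).
#' @param q_mean,q_sd benefit per case: natural-scale mean and sd.
#' @param c_mean,c_sd cost per case (currency): natural-scale mean and sd.
#' @param p_mean,p_sd impacted population (thousands of cases): mean and sd.
#' @param n_candidates number of candidate interventions per cycle (N).
#' @param threshold cost-effectiveness threshold t (currency per benefit
#'   unit).
#' @param budget annual funding budget (currency millions).
#' @param n_funded number of interventions funded per cycle under the
#'   count-based counterfactual (n).
#' @param capacity_pct annual percentage of highest budget-impact
#'   interventions receiving a threshold assessment (p_a), in `[0, 100]`.
#' @param phase_years number of cycles of phased PSI build-up (Y).
#' @param phase_target_pct percentage of interventions assessed in the final
#'   phase-in year (p_Y), in `[0, 100]`.
#' @param hta_unit_cost cost of one health technology assessment (currency);
#'   default 0.
#' @return An object of class `"country_config"` (a named list), with the
#'   three `"lnorm_spec"` objects attached as `q_spec`, `c_spec`, `p_spec`.
#' @seealso [psi_preset()], [read_country_config()]
#' @export
country_config <- function(name, currency, benefit_unit,
                           q_mean, q_sd, c_mean, c_sd, p_mean, p_sd,
                           n_candidates, threshold, budget, n_funded,
                           capacity_pct = 20, phase_years = 5,
                           phase_target_pct = 100, hta_unit_cost = 0) {
  cfg <- list(name = as.character(name), currency = as.character(currency),
              benefit_unit = as.character(benefit_unit),
              q_mean = q_mean, q_sd = q_sd, c_mean = c_mean, c_sd = c_sd,
              p_mean = p_mean, p_sd = p_sd,
              n_candidates = as.integer(n_candidates),
              threshold = threshold, budget = budget,
              n_funded = as.integer(n_funded),
              capacity_pct = capacity_pct,
              phase_years = as.integer(phase_years),
              phase_target_pct = phase_target_pct,
              hta_unit_cost = hta_unit_cost)
  .check_config(cfg)
  cfg$q_spec <- lognormal_from_moments(q_mean, q_sd)
  cfg$c_spec <- lognormal_from_moments(c_mean, c_sd)
  cfg$p_spec <- lognormal_from_moments(p_mean, p_sd)
  class(cfg) <- "country_config"
  cfg
}

.check_config <- function(cfg) {
  num1 <- function(field, lo = -Inf, hi = Inf, strict_lo = FALSE) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("config field '", field, "' must be a single finite number",
           call. = FALSE)
    if ((strict_lo && v <= lo) || (!strict_lo && v < lo) || v > hi)
      stop("config field '", field, "' = ", v, " is out of range",
           call. = FALSE)
    invisible(v)
  }
  num1("q_mean", 0, strict_lo = TRUE); num1("q_sd", 0)
  num1("c_mean", 0, strict_lo = TRUE); num1("c_sd", 0)
  num1("p_mean", 0, strict_lo = TRUE); num1("p_sd", 0)
  num1("n_candidates", 1)
  num1("threshold", 0, strict_lo = TRUE)
  num1("budget", 0, strict_lo = TRUE)
  num1("n_funded", 0)
  if (cfg$n_funded > cfg$n_candidates)
    stop("config field 'n_funded' exceeds 'n_candidates'", call. = FALSE)
  num1("capacity_pct", 0, 100)
  num1("phase_years", 1)
  num1("phase_target_pct", 0, 100)
  num1("hta_unit_cost", 0)
  invisible(cfg)
}

#' @export
print.country_config <- function(x, ...) {
  cat(sprintf("Funding setting '%s' (%s, benefit in %ss)\n",
              x$name, x$currency, x$benefit_unit))
  cat(sprintf("  benefit/case : mean %g, sd %g\n", x$q_mean, x$q_sd))
  cat(sprintf("  cost/case    : mean %g, sd %g %s\n", x$c_mean, x$c_sd, x$currency))
  cat(sprintf("  cases (k)    : mean %g, sd %g\n", x$p_mean, x$p_sd))
  cat(sprintf("  N = %d candidates, threshold t = %g %s/%s, budget l = %g M, n = %d funded\n",
              x$n_candidates, x$threshold, x$currency, x$benefit_unit,
              x$budget, x$n_funded))
  cat(sprintf("  capacity p_a = %g%%, phase-in Y = %d years to p_Y = %g%%\n",
              x$capacity_pct, x$phase_years, x$phase_target_pct))
  invisible(x)
}

#' Read and validate a country configuration file
#'
#' Parses a YAML (or JSON, which YAML subsumes) configuration with exactly
#' the fields of [country_config()]. Unknown keys and missing required
#' fields are rejected with an error naming the field, as are out-of-range
#' values.
#'
#' @param path path to the configuration file.
#' @return A validated `"country_config"` object.
#' @examples
#' cfg <- read_country_config(system.file("extdata", "uk.yaml", package = "psisim"))
#' cfg$threshold
#' @export
read_country_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config file must contain a mapping of fields")
  unknown <- setdiff(names(raw), .config_fields)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  optional <- c("capacity_pct", "phase_years", "phase_target_pct", "hta_unit_cost")
  missing <- setdiff(setdiff(.config_fields, optional), names(raw))
  if (length(missing))
    stop("missing config field(s): ", paste(missing, collapse = ", "))
  do.call(country_config, raw)
}

#' Shipped parameterisation presets
#'
#' Loads one of the indicative parameter sets shipped with the package:
#' `"uk"` (established universal health coverage; QALYs, GBP, N = 74,
#' t = 20,000 GBP/QALY) or `"malawi"` (fledgling coverage; DALYs, USD,
#' N = 40, t = 2 USD/DALY). `psi_presets()` lists the available preset
#' names.
#'
#' @param name preset name, `"uk"` or `"malawi"`.
#' @return A `"country_config"` object.
#' @examples
#' uk <- psi_preset("uk")
#' @export
psi_preset <- function(name = c("uk", "malawi")) {
  name <- match.arg(tolower(name), psi_presets())
  read_country_config(system.file("extdata", paste0(name, ".yaml"),
                                  package = "psisim", mustWork = TRUE))
}

#' @rdname psi_preset
#' @export
psi_presets <- function() {
  sort(sub("\\.yaml$", "",
           basename(list.files(system.file("extdata", package = "psisim"),
                               pattern = "\\.yaml$"))))
}

## budget expressed in the same units as intervention_cost() (thousands of
## currency, since P is in thousands and C in currency units)
.budget_cost_units <- function(config) config$budget * 1000
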