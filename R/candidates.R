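## Candidate-set sampler: correlated (C, Q) log-normal pairs via a Gaussian
## copula, independent log-normal P. Row order is the sampling order and is
## the first-come-first-served arrival order for every funding rule.

#' Sample a candidate set of interventions
#'
#' Draws `config$n_candidates` interventions. Cost per case `C` and benefit
#' per case `Q` are bivariate log-normal with the requested Pearson
#' correlation `rho` on the untransformed scale (induced by a Gaussian
#' copula with the closed-form latent correlation, see
#' [latent_correlation()]); the impacted population `P` (thousands of cases)
#' is log-normal and independent of `(C, Q)`. A degenerate margin
#' (`sd = 0`) yields a constant column and, if either of `C`/`Q` is
#' degenerate, independence regardless of `rho`.
#'
#' @param config a `"country_config"`.
#' @param rho target Pearson correlation between untransformed `C` and `Q`.
#' @param seed integer seed; identical `(config, rho, seed)` reproduce the
#'   identical candidate set.
#' @return A `data.frame` of class `"candidate_set"` with columns `P`, `C`,
#'   `Q` (one row per candidate, in arrival order) and attributes
#'   `rho_target`, `rho_latent`, `seed`.
#' @examples
#' cs <- sample_candidates(psi_preset("uk"), rho = 0.2, seed = 1)
#' head(cs)
#' @export
sample_candidates <- function(config, rho, seed) {
  stopifnot(inherits(config, "country_config"),
            is.numeric(rho), length(rho) == 1L, rho >= -1, rho <= 1,
            is.numeric(seed), length(seed) == 1L)
  n <- config$n_candidates
  degenerate <- config$c_spec$sigma_log == 0 || config$q_spec$sigma_log == 0
  rho_z <- if (degenerate) 0 else latent_correlation(rho, config$c_spec, config$q_spec)

  set.seed(as.integer(seed))
  z_c <- stats::rnorm(n)
  z_q <- rho_z * z_c + sqrt(1 - rho_z^2) * stats::rnorm(n)
  cs <- data.frame(
    P = stats::rlnorm(n, config$p_spec$mu_log, config$p_spec$sigma_log),
    C = exp(config$c_spec$mu_log + config$c_spec$sigma_log * z_c),
    Q = exp(config$q_spec$mu_log + config$q_spec$sigma_log * z_q))
  structure(cs,
            rho_target = rho, rho_latent = rho_z, seed = as.integer(seed),
            class = c("candidate_set", "data.frame"))
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("Candidate set: %d interventions (rho target %g, seed %d)\n",
              nrow(x), attr(x, "rho_target"), attr(x, "seed")))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat("  ... ", nrow(x) - 6L, " more rows\n", sep = "")
  invisible(x)
}
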