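#' Log-normal parameters from natural-scale moments
#'
#' Converts a natural-scale mean and standard deviation into the location
#' (`mu_log`) and scale (`sigma_log`) of the underlying normal, by exact
#' moment matching: `exp(mu + sigma^2/2) = mean` and
#' `mean^2 * (exp(sigma^2) - 1) = sd^2`. Intervention costs, benefits and
#' population sizes are parameterised this way from their published summary
#' moments.
#'
#' @param mean natural-scale mean; must be strictly positive.
#' @param sd natural-scale standard deviation; `sd = 0` gives a degenerate
#'   point mass at `mean` (`sigma_log = 0`).
#' @return An object of class `"lnorm_spec"`: a list with fields `mean`,
#'   `sd`, `mu_log`, `sigma_log`.
#' @examples
#' sp <- lognormal_from_moments(20, 30)
#' exp(sp$mu_log + sp$sigma_log^2 / 2)  # == 20
#' @export
lognormal_from_moments <- function(mean, sd) {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.numeric(sd), length(sd) == 1L)
  if (!is.finite(mean) || mean <= 0)
    stop("'mean' must be a positive finite number, got ", mean)
  if (!is.finite(sd) || sd < 0)
    stop("'sd' must be a non-negative finite number, got ", sd)
  sigma2 <- log1p((sd / mean)^2)
  structure(
    list(mean = mean, sd = sd,
         mu_log = log(mean) - sigma2 / 2,
         sigma_log = sqrt(sigma2)),
    class = "lnorm_spec")
}

#' @export
print.lnorm_spec <- function(x, ...) {
  cat(sprintf("Log-normal: mean %g, sd %g (mu_log %.6g, sigma_log %.6g)\n",
              x$mean, x$sd, x$mu_log, x$sigma_log))
  invisible(x)
}

#' Latent normal correlation for a bivariate log-normal target
#'
#' Solves, in closed form, for the correlation of the latent bivariate
#' normal in a Gaussian copula such that the Pearson correlation of the two
#' untransformed log-normal margins equals `rho`:
#' `cor(X, Y) = (exp(rho_z * sx * sy) - 1) / sqrt((exp(sx^2)-1)(exp(sy^2)-1))`.
#' If `rho` exceeds the attainable range (the bound at `rho_z = +/-1`), the
#' latent correlation is clipped to the boundary with a warning.
#'
#' @param rho target Pearson correlation of the untransformed pair, in
#'   `[-1, 1]`.
#' @param spec_x,spec_y `"lnorm_spec"` objects (see
#'   [lognormal_from_moments()]); both must be non-degenerate
#'   (`sigma_log > 0`).
#' @return The latent normal-scale correlation (scalar in `[-1, 1]`).
#' @examples
#' sx <- lognormal_from_moments(1, sqrt(exp(1) - 1))  # sigma_log = 1
#' latent_correlation(0.5, sx, sx)                    # log(1 + 0.5*(e-1))
#' @export
latent_correlation <- function(rho, spec_x, spec_y) {
  stopifnot(inherits(spec_x, "lnorm_spec"), inherits(spec_y, "lnorm_spec"),
            is.numeric(rho), length(rho) == 1L, rho >= -1, rho <= 1)
  sx <- spec_x$sigma_log
  sy <- spec_y$sigma_log
  if (sx == 0 || sy == 0)
    stop("latent_correlation() requires non-degenerate margins (sigma_log > 0)")
  arg <- 1 + rho * sqrt(expm1(sx^2) * expm1(sy^2))
  if (arg <= 0) {
    warning("target correlation ", rho, " below the attainable minimum; ",
            "clipping latent correlation to -1")
    return(-1)
  }
  rho_z <- log(arg) / (sx * sy)
  if (rho_z > 1) {
    warning("target correlation ", rho, " above the attainable maximum; ",
            "clipping latent correlation to 1")
    rho_z <- 1
  } else if (rho_z < -1) {
    warning("target correlation ", rho, " below the attainable minimum; ",
            "clipping latent correlation to -1")
    rho_z <- -1
  }
  rho_z
}
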