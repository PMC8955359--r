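# Hydrotime constants and the repeated-probit hydrotime fit at a fixed
# temperature. The population threshold model assumes seed base water
# potentials are Normal(psi_b50, sigma_psi_b); then for seeds incubated at
# potential psi the germinated fraction at time t satisfies
#   probit(g) = (psi - theta_H / t - psi_b50) / sigma_psi_b,
# linear in x = psi - theta_H / t. theta_H is found by scanning a candidate
# grid and keeping the value whose probit regression maximises R^2 (the
# classical "repeated probit" procedure).

.stop_fit <- function(msg, class = "seedhtt_fit_error") {
  stop(errorCondition(msg, class = c(class, "seedhtt_error")))
}

#' Hydrotime constant
#'
#' MPa-hours of water-potential excess over the threshold:
#' \eqn{\theta_H = (\psi - \psi_b) t_g}.
#'
#' @param psi medium water potential, MPa.
#' @param psi_b base (threshold) water potential, MPa.
#' @param tg time to the germination fraction, h.
#' @return MPa h.
#' @export
hydrotime_constant <- function(psi, psi_b, tg) {
  if (any(tg <= 0)) .stop_domain("tg must be > 0")
  if (any(psi < psi_b)) {
    .stop_domain("psi must be >= psi_b (seeds below threshold never germinate)")
  }
  (psi - psi_b) * tg
}

#' Germination rate implied by a hydrotime constant
#'
#' \eqn{GR = (\psi - \psi_b)/\theta_H}, clipped at zero below the
#' threshold.
#'
#' @inheritParams hydrotime_constant
#' @param theta_H hydrotime constant, MPa h (> 0).
#' @return h^-1.
#' @export
gr_from_hydrotime <- function(psi, psi_b, theta_H) {
  if (any(theta_H <= 0)) .stop_domain("theta_H must be > 0")
  pmax(0, psi - psi_b) / theta_H
}

# Probit-scale observations from a grid: one row per (T, psi, time) with
# pooled or per-replicate fractions, keeping only 0 < g < 1 (fractions of 0
# or 1 carry no probit information and would be infinite).
.probit_obs <- function(grid, pool = TRUE) {
  grid <- as_germination_grid(grid)
  if (pool) grid <- pool_replicates(grid)
  g <- grid$cum_germinated / grid$n_sown
  keep <- g > 0 & g < 1
  data.frame(temperature_C = grid$temperature_C[keep],
             psi_MPa = grid$psi_MPa[keep],
             time_h = grid$time_h[keep],
             g = g[keep],
             probit = stats::qnorm(g[keep]))
}

# Simple-regression scan: X is an n x K matrix of candidate regressors, y
# the probit response. Returns slope and R^2 per column without K lm calls.
.scan_linear <- function(X, y) {
  n <- length(y)
  sy <- sum(y)
  syy <- sum(y * y)
  sx <- colSums(X)
  sxx <- colSums(X * X)
  sxy <- as.vector(crossprod(X, y))
  num <- n * sxy - sx * sy
  denx <- n * sxx - sx^2
  deny <- n * syy - sy^2
  slope <- ifelse(denx > 0, num / denx, NA_real_)
  r2 <- ifelse(denx > 0 & deny > 0, num^2 / (denx * deny), NA_real_)
  list(slope = slope, r2 = r2)
}

# Keep the best candidate with positive slope; returns its index or NA.
.best_candidate <- function(scan) {
  score <- ifelse(is.finite(scan$r2) & scan$slope > 0, scan$r2, -Inf)
  if (all(score == -Inf)) return(NA_integer_)
  which.max(score)
}

# Final OLS at the winning candidate, with the diagnostics reported for
# threshold fits (R^2, r, SE of regression, F, p).
.final_probit_fit <- function(x, y) {
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  slope <- coef(fit)[["x"]]
  intercept <- coef(fit)[["(Intercept)"]]
  if (!is.finite(slope) || slope <= 0) {
    .stop_fit("winning probit regression has non-positive slope (sigma_psi_b must be > 0)")
  }
  fstat <- sm$fstatistic
  p <- if (is.null(fstat)) NA_real_ else
    stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  list(slope = slope, intercept = intercept,
       sigma_psi_b = 1 / slope,
       psi_b50 = -intercept / slope,
       r_squared = sm$r.squared,
       r = sign(slope) * sqrt(sm$r.squared),
       se = sm$sigma,
       f_stat = if (is.null(fstat)) NA_real_ else unname(fstat[1]),
       p_value = unname(p))
}

#' Fit the hydrotime model at one temperature
#'
#' Repeated probit regression over a grid of candidate hydrotime constants:
#' for each candidate \eqn{\theta_H}, probit(g) is regressed on
#' \eqn{x = \psi - \theta_H/t} across all informative observations
#' (0 < g < 1); the candidate maximising R^2 wins and its regression line
#' gives \eqn{\sigma_{\psi b}} = 1/slope and \eqn{\psi_b(50)} =
#' -intercept/slope. The candidate grid is log-spaced and refined once by a
#' 10x finer local grid around the winner; the reported `tolerance` is the
#' final grid step at the winner.
#'
#' Replicates are pooled (counts summed per potential and scoring time) by
#' default; `pool = FALSE` keeps per-replicate fractions.
#'
#' @param grid a `germination_grid` (restricted to one temperature, or use
#'   `temperature` to subset).
#' @param temperature temperature to subset, deg C (required when the grid
#'   holds several).
#' @param pool pool replicate counts before the probit transform.
#' @param theta_range candidate range for theta_H, MPa h.
#' @param n_grid number of log-spaced candidates in the first pass.
#' @return object of class `hydrotime_fit`: `theta_H`, `psi_b50`,
#'   `sigma_psi_b`, `r_squared`, `r`, `se`, `f_stat`, `p_value`, `n_obs`,
#'   `temperature_C`, `tolerance`.
#' @export
fit_hydrotime <- function(grid, temperature = NULL, pool = TRUE,
                          theta_range = c(0.01, 100), n_grid = 200) {
  grid <- as_germination_grid(grid)
  if (!is.null(temperature)) {
    grid <- grid[abs(grid$temperature_C - temperature) < 1e-9, ,
                 drop = FALSE]
    if (nrow(grid) == 0) {
      .stop_domain(sprintf("no observations at temperature_C=%g", temperature))
    }
    grid <- as_germination_grid(grid)
  }
  temps <- unique(grid$temperature_C)
  if (length(temps) > 1) {
    .stop_domain("grid spans several temperatures; pass `temperature` to subset")
  }
  obs <- .probit_obs(grid, pool = pool)
  if (nrow(obs) < 3) {
    .stop_fit("need at least 3 observations with 0 < g < 1",
              class = "seedhtt_degenerate_error")
  }
  if (length(unique(obs$psi_MPa)) < 2) {
    .stop_fit("need at least 2 water potentials with informative fractions",
              class = "seedhtt_degenerate_error")
  }

  A <- 1 / obs$time_h
  scan_thetas <- function(thetas) {
    X <- obs$psi_MPa - outer(A, thetas)
    .scan_linear(X, obs$probit)
  }

  thetas <- exp(seq(log(theta_range[1]), log(theta_range[2]),
                    length.out = n_grid))
  s1 <- .scan_thetas_best(scan_thetas, thetas)
  lo <- thetas[max(1L, s1 - 1L)]
  hi <- thetas[min(length(thetas), s1 + 1L)]
  fine <- exp(seq(log(lo), log(hi), length.out = 21))
  s2 <- .scan_thetas_best(scan_thetas, fine)
  theta_H <- fine[s2]
  step <- theta_H * (fine[2] / fine[1] - 1)

  x <- obs$psi_MPa - theta_H / obs$time_h
  res <- .final_probit_fit(x, obs$probit)
  structure(c(list(theta_H = theta_H), res,
              list(n_obs = nrow(obs), temperature_C = temps,
                   tolerance = step, pooled = pool)),
            class = "hydrotime_fit")
}

# Scan helper shared with the HTT fitter: returns the winning index or
# raises a fit failure.
.scan_thetas_best <- function(scan_fn, thetas) {
  s <- scan_fn(thetas)
  i <- .best_candidate(s)
  if (is.na(i)) {
    .stop_fit("no candidate gave a positive probit slope (sigma_psi_b must be > 0)")
  }
  i
}

#' @export
print.hydrotime_fit <- function(x, ...) {
  cat(sprintf("Hydrotime fit at %g degC (%s replicates, %d probit obs)\n",
              x$temperature_C, if (x$pooled) "pooled" else "per",
              x$n_obs))
  cat(sprintf("  theta_H     = %.4g MPa h (grid tolerance %.2g)\n",
              x$theta_H, x$tolerance))
  cat(sprintf("  psi_b(50)   = %.4f MPa\n", x$psi_b50))
  cat(sprintf("  sigma_psi_b = %.4f MPa\n", x$sigma_psi_b))
  cat(sprintf("  R^2 = %.3f  R = %.3f  SE = %.3f  F = %.3f  Sig. = %.3g\n",
              x$r_squared, x$r, x$se, x$f_stat, x$p_value))
  invisible(x)
}
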