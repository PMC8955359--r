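# Hydrothermal-time (HTT) model: joint temperature x water-potential probit
# fit and forward prediction of germination time courses. The model:
#   probit(g) = (psi_adj - theta_HTT / ((T - Tb) t) - psi_b50) / sigma_psi_b
# with psi_adj = psi - kT * max(0, T - To): above the optimum temperature
# the base-water-potential distribution shifts upward by kT per deg C,
# which is what halts germination at the ceiling.

#' Hydrothermal time constant
#'
#' \eqn{\theta_{HTT} = (\psi - \psi_b)(T - T_b) t_g}.
#'
#' @param psi medium water potential, MPa.
#' @param psi_b base water potential, MPa.
#' @param T incubation temperature, deg C.
#' @param Tb base temperature, deg C.
#' @param tg time to the germination fraction, h.
#' @return MPa deg C h.
#' @export
htt_constant <- function(psi, psi_b, T, Tb, tg) {
  if (any(tg <= 0)) .stop_domain("tg must be > 0")
  if (any(psi < psi_b)) .stop_domain("psi must be >= psi_b")
  if (any(T < Tb)) .stop_domain("T must be >= Tb")
  (psi - psi_b) * (T - Tb) * tg
}

#' Supra-optimally adjusted base water potential
#'
#' Above the optimum temperature the germination threshold rises linearly:
#' \eqn{\psi_b + k_T (T - T_o)} for \eqn{T > T_o}, unchanged below.
#'
#' @param psi_b base water potential, MPa.
#' @param kT supra-optimal threshold shift, MPa per deg C.
#' @param T incubation temperature, deg C.
#' @param To optimum temperature, deg C.
#' @return adjusted base water potential, MPa.
#' @export
adjusted_base_potential <- function(psi_b, kT, T, To) {
  psi_b + kT * pmax(0, T - To)
}

#' Fit the hydrothermal-time model
#'
#' Nested grid search wrapped around ordinary least squares: the outer grid
#' runs over the base temperature Tb (0.5 deg C steps from `Tb_range[1]` up
#' to the coolest tested temperature) and log-spaced candidates for
#' theta_HTT; for each candidate pair, probit(g) is regressed on
#' \eqn{x = \psi - k_T \max(0, T - T_o) - \theta_{HTT}/((T - T_b) t)} over
#' all informative observations, and the pair maximising R^2 wins. A second
#' pass refines both grids 10-fold around the winner. psi_b(50) and
#' sigma_psi_b come from the winning regression line.
#'
#' The optimum temperature defaults to the hottest tested temperature, which
#' leaves the supra-optimal branch empty and kT fixed at 0 (reported as not
#' estimable). Supplying `To` below the hottest tested temperature switches
#' on a grid search for kT over `kT_range`.
#'
#' @param grid a `germination_grid` spanning at least two temperatures and
#'   two water potentials with informative fractions.
#' @param pool pool replicate counts before the probit transform.
#' @param To optimum temperature, deg C; `NULL` (default) uses the hottest
#'   tested temperature.
#' @param Tb_range lower/upper bounds for the Tb grid, deg C; the upper
#'   bound is additionally capped at the coolest tested temperature.
#' @param Tb_step Tb grid step, deg C.
#' @param theta_range candidate range for theta_HTT, MPa deg C h.
#' @param n_theta number of log-spaced theta candidates in the first pass.
#' @param kT_range candidate range for kT, MPa per deg C (only used with a
#'   supra-optimal branch).
#' @param n_kT number of kT candidates in the first pass.
#' @return object of class `htt_fit`: `theta_HTT`, `psi_b50`,
#'   `sigma_psi_b`, `Tb`, `To`, `Tc`, `kT`, `kT_estimable`, `r_squared`,
#'   `r`, `se`, `f_stat`, `p_value`, `n_obs`, `tolerance` (theta), and
#'   `Tb_tolerance`.
#' @export
fit_htt <- function(grid, pool = TRUE, To = NULL,
                    Tb_range = c(0, Inf), Tb_step = 0.5,
                    theta_range = c(1, 1000), n_theta = 200,
                    kT_range = c(0, 0.5), n_kT = 26) {
  grid <- as_germination_grid(grid)
  tested_T <- sort(unique(grid$temperature_C))
  obs <- .probit_obs(grid, pool = pool)
  if (length(unique(obs$temperature_C)) < 2) {
    .stop_fit("need at least 2 temperatures with informative fractions",
              class = "seedhtt_degenerate_error")
  }
  if (length(unique(obs$psi_MPa)) < 2) {
    .stop_fit("need at least 2 water potentials with informative fractions",
              class = "seedhtt_degenerate_error")
  }

  if (is.null(To)) To <- max(tested_T)
  supra <- any(obs$temperature_C > To + 1e-9)
  kT_cands <- if (supra) seq(kT_range[1], kT_range[2], length.out = n_kT)
              else 0

  Tb_hi <- min(Tb_range[2], min(tested_T), min(obs$temperature_C) - 1e-6)
  Tb_cands <- seq(Tb_range[1], Tb_hi, by = Tb_step)
  if (Tb_hi - Tb_cands[length(Tb_cands)] > 1e-9) {
    Tb_cands <- c(Tb_cands, Tb_hi)
  }
  thetas <- exp(seq(log(theta_range[1]), log(theta_range[2]),
                    length.out = n_theta))

  y <- obs$probit
  supra_excess <- pmax(0, obs$temperature_C - To)
  scan_all <- function(Tb_cands, kT_cands, thetas) {
    best <- list(r2 = -Inf)
    for (Tb in Tb_cands) {
      A <- 1 / ((obs$temperature_C - Tb) * obs$time_h)
      for (kT in kT_cands) {
        psi_adj <- obs$psi_MPa - kT * supra_excess
        X <- psi_adj - outer(A, thetas)
        s <- .scan_linear(X, y)
        score <- ifelse(is.finite(s$r2) & s$slope > 0, s$r2, -Inf)
        i <- which.max(score)
        if (score[i] > best$r2) {
          best <- list(r2 = score[i], Tb = Tb, kT = kT, i_theta = i,
                       thetas = thetas)
        }
      }
    }
    best
  }

  b1 <- scan_all(Tb_cands, kT_cands, thetas)
  if (!is.finite(b1$r2)) {
    .stop_fit("no candidate gave a positive probit slope (sigma_psi_b must be > 0)")
  }

  # 10x refinement around the first-pass winner. The theta window spans
  # three coarse steps on each side: with several searched dimensions the
  # coarse winners can trade off against each other, so a one-step window
  # can miss the joint optimum.
  Tb_fine <- seq(max(Tb_range[1], b1$Tb - Tb_step),
                 min(Tb_hi, b1$Tb + Tb_step), by = Tb_step / 10)
  i <- b1$i_theta
  th_lo <- thetas[max(1L, i - 3L)]
  th_hi <- thetas[min(length(thetas), i + 3L)]
  th_fine <- exp(seq(log(th_lo), log(th_hi), length.out = 61))
  kT_fine <- if (supra) {
    kstep <- diff(kT_cands[1:2])
    seq(max(kT_range[1], b1$kT - 1.5 * kstep),
        min(kT_range[2], b1$kT + 1.5 * kstep), length.out = 31)
  } else 0
  b2 <- scan_all(Tb_fine, kT_fine, th_fine)

  theta_HTT <- b2$thetas[b2$i_theta]
  Tb <- b2$Tb
  kT <- b2$kT
  x <- obs$psi_MPa - kT * supra_excess -
    theta_HTT / ((obs$temperature_C - Tb) * obs$time_h)
  res <- .final_probit_fit(x, y)
  structure(c(list(theta_HTT = theta_HTT, Tb = Tb, To = To, Tc = To,
                   kT = kT, kT_estimable = supra), res,
              list(n_obs = nrow(obs), pooled = pool,
                   tolerance = theta_HTT * (th_fine[2] / th_fine[1] - 1),
                   Tb_tolerance = Tb_step / 10)),
            class = "htt_fit")
}

#' Predict a germination time course from HTT parameters
#'
#' Forward model: the fraction germinated by time \eqn{t} at temperature
#' \eqn{T} and potential \eqn{\psi} is
#' \deqn{G(t) = \Phi\left(\frac{\psi_{adj} - \theta_{HTT}/((T - T_b) t) -
#'   \psi_b(50)}{\sigma_{\psi b}}\right)}
#' with \eqn{\psi_{adj} = \psi - k_T \max(0, T - T_o)}. At or below the
#' base temperature the prediction is identically zero (flagged via the
#' `"below_base"` attribute).
#'
#' @param fit an `htt_fit`, or any list with elements `theta_HTT`,
#'   `psi_b50`, `sigma_psi_b`, `Tb`, `To`, `kT`.
#' @param T incubation temperature, deg C (scalar).
#' @param psi medium water potential, MPa (scalar).
#' @param times scoring times, h (> 0).
#' @return numeric vector of predicted germinated fractions in \[0, 1\],
#'   non-decreasing in `times`; attribute `below_base` is `TRUE` when
#'   `T <= Tb`.
#' @export
predict_time_course <- function(fit, T, psi, times) {
  if (any(times <= 0)) .stop_domain("times must be > 0")
  kT <- if (is.null(fit$kT)) 0 else fit$kT
  To <- if (is.null(fit$To)) T else fit$To
  if (T <= fit$Tb) {
    return(structure(rep(0, length(times)), below_base = TRUE))
  }
  psi_adj <- psi - kT * max(0, T - To)
  x <- psi_adj - fit$theta_HTT / ((T - fit$Tb) * times)
  structure(stats::pnorm((x - fit$psi_b50) / fit$sigma_psi_b),
            below_base = FALSE)
}

#' @export
print.htt_fit <- function(x, ...) {
  cat(sprintf("Hydrothermal-time fit (%s replicates, %d probit obs)\n",
              if (x$pooled) "pooled" else "per", x$n_obs))
  cat(sprintf("  theta_HTT   = %.4g MPa degC h (grid tolerance %.2g)\n",
              x$theta_HTT, x$tolerance))
  cat(sprintf("  psi_b(50)   = %.4f MPa\n", x$psi_b50))
  cat(sprintf("  sigma_psi_b = %.4f MPa\n", x$sigma_psi_b))
  cat(sprintf("  Tb = %.2f degC   To = %.2f degC   Tc = %.2f degC\n",
              x$Tb, x$To, x$Tc))
  cat(sprintf("  kT = %s\n",
              if (x$kT_estimable) sprintf("%.4f MPa/degC", x$kT)
              else "0 (not estimable: no supra-optimal temperatures)"))
  cat(sprintf("  R^2 = %.3f  R = %.3f  SE = %.3f  F = %.3f  Sig. = %.3g\n",
              x$r_squared, x$r, x$se, x$f_stat, x$p_value))
  invisible(x)
}
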