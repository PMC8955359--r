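# Forward simulator of factorial Petri-dish germination experiments. Seeds
# differ only in their base water potential, drawn Normal(psi_b50,
# sigma_psi_b) -- the single stochastic source the population threshold
# model assumes. A seed germinates iff its (supra-optimally adjusted)
# threshold lies below the medium potential and the temperature exceeds Tb;
# its germination time then follows from the hydrothermal-time requirement.

#' Configuration of a simulated germination experiment
#'
#' Defaults reproduce the reference trial design for rocket seed: five
#' incubation temperatures (5, 10, 15, 20, 30 deg C) crossed with four
#' PEG-imposed osmotic potentials (0, -0.01, -0.02, -0.05 MPa), three
#' replicate dishes of 40 seeds, scored daily over 96 h; and the reported
#' population parameters (theta_HTT 43.2 MPa deg C h, psi_b(50) -0.18 MPa,
#' sigma_psi_b 0.13 MPa, Tb 5 deg C, To 30 deg C, kT 0.104 MPa/deg C).
#'
#' @param theta_HTT hydrothermal time constant, MPa deg C h.
#' @param psi_b50 median base water potential, MPa.
#' @param sigma_psi_b seed-to-seed SD of the base water potential, MPa.
#' @param Tb base temperature, deg C.
#' @param To optimum temperature, deg C.
#' @param kT supra-optimal threshold shift, MPa per deg C.
#' @param temperatures tested temperatures, deg C.
#' @param water_potentials tested osmotic potentials, MPa (all <= 0).
#' @param n_seeds seeds per dish.
#' @param n_replicates dishes per treatment.
#' @param scoring_times scoring times, h.
#' @param horizon trial end, h (seeds slower than this are scored
#'   non-germinated).
#' @param dish_sd SD of an optional dish-level random shift added to every
#'   seed threshold in a dish, MPa (0 = off, the threshold model's
#'   assumption).
#' @param viability probability that a seed is capable of germinating at
#'   all.
#' @param seed RNG seed.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(theta_HTT = 43.2, psi_b50 = -0.18,
                              sigma_psi_b = 0.13, Tb = 5, To = 30,
                              kT = 0.104,
                              temperatures = c(5, 10, 15, 20, 30),
                              water_potentials = c(0, -0.01, -0.02, -0.05),
                              n_seeds = 40, n_replicates = 3,
                              scoring_times = c(24, 48, 72, 96),
                              horizon = 96, dish_sd = 0, viability = 1,
                              seed = 1) {
  cfg <- list(theta_HTT = theta_HTT, psi_b50 = psi_b50,
              sigma_psi_b = sigma_psi_b, Tb = Tb, To = To, kT = kT,
              temperatures = temperatures,
              water_potentials = water_potentials, n_seeds = n_seeds,
              n_replicates = n_replicates,
              scoring_times = sort(scoring_times), horizon = horizon,
              dish_sd = dish_sd, viability = viability, seed = seed)
  if (theta_HTT <= 0) .stop_domain("theta_HTT must be > 0")
  if (sigma_psi_b <= 0) .stop_domain("sigma_psi_b must be > 0")
  if (length(temperatures) == 0 || length(water_potentials) == 0 ||
      length(scoring_times) == 0) {
    .stop_domain("design lists must be non-empty")
  }
  if (any(water_potentials > 0)) {
    .stop_domain("water potentials must be <= 0")
  }
  if (n_seeds <= 0 || n_replicates <= 0) {
    .stop_domain("n_seeds and n_replicates must be > 0")
  }
  if (horizon < max(cfg$scoring_times)) {
    .stop_domain("horizon must cover the last scoring time")
  }
  if (viability < 0 || viability > 1) {
    .stop_domain("viability must lie in [0, 1]")
  }
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate a factorial germination experiment
#'
#' Draws one base water potential per seed from
#' Normal(`psi_b50`, `sigma_psi_b`), shifts it by `kT (T - To)` above the
#' optimum, and lets the seed germinate at
#' \eqn{t_g = \theta_{HTT}/((\psi - \psi_b)(T - T_b))} when the medium
#' potential exceeds its threshold and `T > Tb` -- otherwise never.
#' Cumulative counts are recorded at the scoring times and censored at the
#' horizon. Dish order is deterministic and a fixed `seed` reproduces the
#' grid exactly.
#'
#' @param config a [simulation_config()].
#' @return a `germination_grid`.
#' @examples
#' grid <- simulate_experiment(simulation_config(seed = 42))
#' head(grid)
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  rows <- list()
  k <- 0
  for (T in config$temperatures) {
    shift <- config$kT * max(0, T - config$To)
    for (psi in config$water_potentials) {
      for (rep_i in seq_len(config$n_replicates)) {
        psi_b <- stats::rnorm(config$n_seeds, config$psi_b50,
                              config$sigma_psi_b)
        if (config$dish_sd > 0) {
          psi_b <- psi_b + stats::rnorm(1, 0, config$dish_sd)
        }
        viable <- if (config$viability < 1) {
          stats::runif(config$n_seeds) < config$viability
        } else rep(TRUE, config$n_seeds)
        thr <- psi_b + shift
        can <- viable & (T > config$Tb) & (psi > thr)
        t_g <- rep(Inf, config$n_seeds)
        t_g[can] <- config$theta_HTT / ((psi - thr[can]) * (T - config$Tb))
        t_g[t_g > config$horizon] <- Inf
        cum <- vapply(config$scoring_times,
                      function(s) sum(t_g <= s), numeric(1))
        k <- k + 1
        rows[[k]] <- data.frame(temperature_C = T, psi_MPa = psi,
                                replicate = rep_i,
                                time_h = config$scoring_times,
                                cum_germinated = cum,
                                n_sown = config$n_seeds)
      }
    }
  }
  as_germination_grid(do.call(rbind, rows))
}

#' Simulate seedling traits for a germination grid
#'
#' Generates per-dish seedling length and dry weights whose means scale
#' linearly with the dish's final germinated fraction, with lognormal
#' multiplicative noise (`cv = 0` makes every trait equal its mean).
#' Dishes with zero germination get `NA` traits.
#'
#' @param grid a `germination_grid`.
#' @param length_cm,root_mg,shoot_mg,seed_mg trait means at full
#'   germination.
#' @param cv lognormal coefficient of variation of each trait.
#' @param seed RNG seed.
#' @return data frame with one trait row per dish.
#' @export
simulate_seedling_traits <- function(grid, length_cm = 6, root_mg = 0.5,
                                     shoot_mg = 1.2, seed_mg = 1.8,
                                     cv = 0.1, seed = 1) {
  grid <- as_germination_grid(grid)
  set.seed(seed)
  courses <- time_courses(grid)
  rows <- lapply(courses, function(course) {
    fr <- germination_fractions(course)
    f <- fr$fraction[nrow(fr)]
    base <- data.frame(temperature_C = course$temperature_C[1],
                       psi_MPa = course$psi_MPa[1],
                       replicate = course$replicate[1])
    if (f == 0) {
      return(cbind(base, seedling_length_cm = NA_real_,
                   root_dw_mg = NA_real_, shoot_dw_mg = NA_real_,
                   seed_dw_mg = NA_real_))
    }
    noise <- function() if (cv > 0) exp(stats::rnorm(1, 0, cv)) else 1
    cbind(base,
          seedling_length_cm = length_cm * f * noise(),
          root_dw_mg = root_mg * f * noise(),
          shoot_dw_mg = shoot_mg * f * noise(),
          seed_dw_mg = seed_mg * f * noise())
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
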