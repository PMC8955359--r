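# Fixtures are built in code: small hand-written dishes plus noise-free
# grids generated from the HTT forward model (exact fractions, n_sown = 1).

make_course <- function(times_h, cum, n = 40, temp = 20, psi = 0, rep = 1) {
  data.frame(temperature_C = temp, psi_MPa = psi, replicate = rep,
             time_h = times_h, cum_germinated = cum, n_sown = n)
}

htt_truth <- list(theta_HTT = 43.2, psi_b50 = -0.18, sigma_psi_b = 0.13,
                  Tb = 5, To = 30, kT = 0.104)

# Exact model fractions on a factorial design; counts are fractions of a
# unit dish so the probit observations carry no sampling noise.
noise_free_grid <- function(truth = htt_truth,
                            temperatures = c(5, 10, 15, 20, 30),
                            psis = c(0, -0.01, -0.02, -0.05),
                            times = seq(8, 96, by = 4)) {
  rows <- list()
  k <- 0
  for (T in temperatures) {
    for (psi in psis) {
      G <- predict_time_course(truth, T, psi, times)
      k <- k + 1
      rows[[k]] <- data.frame(temperature_C = T, psi_MPa = psi,
                              replicate = 1, time_h = times,
                              cum_germinated = as.numeric(G), n_sown = 1)
    }
  }
  as_germination_grid(do.call(rbind, rows))
}
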