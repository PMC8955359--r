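# Twelve classical germination and vigor indices. Day-based indices convert
# from the on-disk hour scale with 1 day = 24 h. Undefined indices (e.g. mean
# germination time of a dish where nothing germinated) are reported as NA,
# never as zero.

.HOURS_PER_DAY <- 24

.stop_domain <- function(msg) {
  stop(errorCondition(msg, class = c("seedhtt_domain_error", "seedhtt_error")))
}

#' Final germination percentage
#'
#' Germinated seeds per 100 seeds sown.
#'
#' @param germinated final number of germinated seeds.
#' @param sown number of seeds sown (> 0).
#' @return percentage in \[0, 100\].
#' @export
germination_percentage <- function(germinated, sown) {
  if (any(sown <= 0)) .stop_domain("sown must be > 0")
  if (any(germinated < 0 | germinated > sown)) {
    .stop_domain("germinated must lie in [0, sown]")
  }
  100 * germinated / sown
}

#' Mean germination time
#'
#' Count-weighted mean day of germination, \eqn{\sum f x / \sum f}, with
#' \eqn{f} the seeds first recorded germinated on day \eqn{x}.
#'
#' @param daily_counts seeds newly germinated on each day (increments, not
#'   cumulative).
#' @param days day numbers matching `daily_counts`.
#' @return days; `NA` when no seed germinated.
#' @export
mean_germination_time <- function(daily_counts, days) {
  stopifnot(length(daily_counts) == length(days))
  total <- sum(daily_counts)
  if (total <= 0) return(NA_real_)
  sum(daily_counts * days) / total
}

#' Mean germination rate
#'
#' Reciprocal of the mean germination time.
#'
#' @param mgt mean germination time in days.
#' @return day^-1; `NA` when `mgt` is missing.
#' @export
mean_germination_rate <- function(mgt) {
  ifelse(is.na(mgt) | mgt <= 0, NA_real_, 1 / mgt)
}

#' Germination energy
#'
#' Sum over scoring days of the daily increment in germinated seeds divided
#' by the day number: early germination is weighted most.
#'
#' @param cumulative_counts cumulative germinated counts per day
#'   (non-decreasing).
#' @param days day numbers matching `cumulative_counts`.
#' @return weighted count (day^-1-weighted).
#' @export
germination_energy <- function(cumulative_counts, days) {
  stopifnot(length(cumulative_counts) == length(days))
  if (is.unsorted(cumulative_counts)) {
    .stop_domain("cumulative_counts must be non-decreasing")
  }
  increments <- diff(c(0, cumulative_counts))
  sum(increments / days)
}

#' Coefficient of velocity of germination
#'
#' \eqn{100 \sum N_i / \sum N_i T_i} with \eqn{N_i} seeds germinating on day
#' \eqn{T_i}. Reaches its theoretical maximum of 100 when every germinating
#' seed emerges on day 1.
#'
#' @inheritParams mean_germination_time
#' @return dimensionless (x100 scale); `NA` when no seed germinated.
#' @export
coefficient_velocity_germination <- function(daily_counts, days) {
  stopifnot(length(daily_counts) == length(days))
  total <- sum(daily_counts)
  if (total <= 0) return(NA_real_)
  100 * total / sum(daily_counts * days)
}

#' Coefficient of variation of germination time
#'
#' Sample standard deviation of per-seed germination days over their mean,
#' as a percentage. Per-seed times are the scoring day at which each seed's
#' germination was first recorded (only interval counts exist).
#'
#' @param germination_times germination day of each germinated seed.
#' @return percent; `NA` with fewer than two germinated seeds.
#' @export
coefficient_variation_time <- function(germination_times) {
  if (length(germination_times) < 2) return(NA_real_)
  m <- mean(germination_times)
  if (m <= 0) return(NA_real_)
  100 * stats::sd(germination_times) / m
}

#' Germination index
#'
#' Declining-weight sum over scoring days: seeds germinating on day 1 get
#' weight 10, day 2 weight 9, and so on down the 10-day ladder (weights are
#' clipped at 1 beyond day 10). A 4-day trial uses weights 10, 9, 8, 7.
#'
#' @inheritParams mean_germination_time
#' @return weighted count (0 when nothing germinated).
#' @export
germination_index <- function(daily_counts, days) {
  stopifnot(length(daily_counts) == length(days))
  weights <- pmax(10 - days + 1, 1)
  sum(weights * daily_counts)
}

#' Germination rate index
#'
#' \eqn{\sum_d G_d / d} where \eqn{G_d} is the percentage of sown seeds
#' germinating on day \eqn{d} (daily increments, so each seed contributes
#' once).
#'
#' @param daily_percentages percent of sown seeds newly germinated each day.
#' @param days day numbers matching `daily_percentages`.
#' @return percent day^-1 sum.
#' @export
germination_rate_index <- function(daily_percentages, days) {
  stopifnot(length(daily_percentages) == length(days))
  sum(daily_percentages / days)
}

#' Time to 50\% germination
#'
#' Linearly interpolates, between the adjacent counts bracketing half of the
#' finally germinated seeds, the time at which half had germinated:
#' \eqn{t_i + (N/2 - n_i)(t_j - t_i)/(n_j - n_i)}. If a count equals
#' \eqn{N/2} exactly, its time is returned. When the first count already
#' exceeds \eqn{N/2} the interpolation starts from (0 seeds, time 0); the
#' result is then flagged via the `"from_origin"` attribute.
#'
#' @param total_germinated final number of germinated seeds (> 0).
#' @param cumulative_counts cumulative counts at `times`.
#' @param times scoring times (any unit; the result is in the same unit).
#' @return interpolated time; attribute `from_origin` is `TRUE` when the
#'   origin was used as the lower bracket.
#' @export
time_to_50 <- function(total_germinated, cumulative_counts, times) {
  stopifnot(length(cumulative_counts) == length(times))
  if (total_germinated <= 0) .stop_domain("total_germinated must be > 0")
  half <- total_germinated / 2
  exact <- which(cumulative_counts == half)
  if (length(exact) > 0) {
    return(structure(times[exact[1]], from_origin = FALSE))
  }
  cc <- c(0, cumulative_counts)
  tt <- c(0, times)
  j <- which(cc >= half)[1]
  i <- j - 1
  t50 <- tt[i] + (half - cc[i]) * (tt[j] - tt[i]) / (cc[j] - cc[i])
  structure(t50, from_origin = (i == 1))
}

#' Seedling vigor indices
#'
#' SVI-1 multiplies seedling length (cm) by the final germination percentage;
#' SVI-2 multiplies seedling dry weight (mg) by the same percentage (GP on
#' the 0-100 scale in both).
#'
#' @param seedling_length mean seedling length, cm.
#' @param seed_dry_weight mean seedling dry weight, mg.
#' @param gp final germination percentage (0-100).
#' @return list with elements `svi1` (cm \%) and `svi2` (mg \%).
#' @export
seed_vigor_indices <- function(seedling_length, seed_dry_weight, gp) {
  list(svi1 = seedling_length * gp, svi2 = seed_dry_weight * gp)
}

#' Root to shoot dry-weight ratio
#'
#' @param root_dw root dry weight, mg.
#' @param shoot_dw shoot dry weight, mg (> 0 for a defined ratio).
#' @return dimensionless; `NA` when `shoot_dw` is zero.
#' @export
root_shoot_ratio <- function(root_dw, shoot_dw) {
  ifelse(is.na(shoot_dw) | shoot_dw <= 0, NA_real_, root_dw / shoot_dw)
}

#' Full index report for one dish
#'
#' Computes the twelve indices from a single time course (and, when given,
#' its seedling traits). Scoring times are converted to days (24 h) for the
#' day-based indices. Indices that are undefined for the course (e.g. mean
#' germination time with no germinated seed, vigor indices without traits)
#' are `NA`.
#'
#' @param course single-dish data frame with `time_h`, `cum_germinated`,
#'   `n_sown` (and optionally the treatment/replicate columns).
#' @param traits optional one-row data frame with `seedling_length_cm`,
#'   `root_dw_mg`, `shoot_dw_mg`, `seed_dw_mg` for the same dish.
#' @return one-row data frame with columns `GP`, `GE`, `MGT`, `MGR`, `CVt`,
#'   `CVG`, `GI`, `GRI`, `T50`, `SVI1`, `SVI2`, `RSR` and the logical flag
#'   `t50_from_origin`.
#' @export
compute_index_report <- function(course, traits = NULL) {
  fr <- germination_fractions(course)    # also validates the dish
  ord <- order(course$time_h)
  times_h <- course$time_h[ord]
  cum <- course$cum_germinated[ord]
  n_sown <- course$n_sown[ord][1]
  days <- times_h / .HOURS_PER_DAY
  increments <- diff(c(0, cum))
  total <- cum[length(cum)]

  gp <- germination_percentage(total, n_sown)
  ge <- germination_energy(cum, days)
  mgt <- mean_germination_time(increments, days)
  mgr <- mean_germination_rate(mgt)
  per_seed <- rep(days, increments)
  cvt <- coefficient_variation_time(per_seed)
  cvg <- coefficient_velocity_germination(increments, days)
  gi <- germination_index(increments, days)
  gri <- germination_rate_index(100 * increments / n_sown, days)
  if (total > 0) {
    t50 <- time_to_50(total, cum, days)
    t50_flag <- attr(t50, "from_origin")
    t50 <- as.numeric(t50)
  } else {
    t50 <- NA_real_
    t50_flag <- NA
  }

  svi1 <- svi2 <- rsr <- NA_real_
  if (!is.null(traits) && nrow(traits) > 0) {
    svi <- seed_vigor_indices(traits$seedling_length_cm[1],
                              traits$seed_dw_mg[1], gp)
    svi1 <- svi$svi1
    svi2 <- svi$svi2
    rsr <- root_shoot_ratio(traits$root_dw_mg[1], traits$shoot_dw_mg[1])
  }

  out <- data.frame(GP = gp, GE = ge, MGT = mgt, MGR = mgr, CVt = cvt,
                    CVG = cvg, GI = gi, GRI = gri, T50 = t50,
                    SVI1 = svi1, SVI2 = svi2, RSR = rsr,
                    t50_from_origin = t50_flag)
  if (!is.null(course$temperature_C)) {
    out <- cbind(data.frame(temperature_C = course$temperature_C[1],
                            psi_MPa = course$psi_MPa[1],
                            replicate = course$replicate[1]), out)
  }
  out
}

#' Index table for a whole treatment grid
#'
#' Applies [compute_index_report()] to every dish and optionally averages
#' the per-replicate indices within each treatment (the default reporting
#' mode); `average = FALSE` keeps one row per replicate, and
#' `pool = TRUE` instead sums replicate counts before computing a single
#' pooled report per treatment.
#'
#' @param grid a `germination_grid`.
#' @param traits optional seedling-trait table (one row per dish).
#' @param average average replicate index rows per treatment (ignored when
#'   `pool = TRUE`).
#' @param pool pool replicate counts before computing indices.
#' @return data frame with one row per treatment (or per dish), class
#'   `index_report`.
#' @export
compute_indices <- function(grid, traits = NULL, average = TRUE,
                            pool = FALSE) {
  if (pool) grid <- pool_replicates(grid)
  courses <- time_courses(grid)
  rows <- lapply(courses, function(course) {
    tr <- NULL
    if (!is.null(traits)) {
      sel <- traits$temperature_C == course$temperature_C[1] &
        traits$psi_MPa == course$psi_MPa[1] &
        traits$replicate == course$replicate[1]
      if (any(sel)) tr <- traits[sel, , drop = FALSE]
    }
    compute_index_report(course, tr)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (average && !pool) {
    idx_cols <- c("GP", "GE", "MGT", "MGR", "CVt", "CVG", "GI", "GRI",
                  "T50", "SVI1", "SVI2", "RSR")
    out <- stats::aggregate(out[idx_cols],
                            by = out[c("temperature_C", "psi_MPa")],
                            FUN = function(v) mean(v, na.rm = TRUE))
    out[idx_cols] <- lapply(out[idx_cols], function(v) {
      v[is.nan(v)] <- NA_real_
      v
    })
  }
  class(out) <- c("index_report", "data.frame")
  out
}

#' Write an index report table
#'
#' @param report an `index_report`.
#' @param path output path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_index_report <- function(report, path, sep = ",") {
  utils::write.table(as.data.frame(report), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
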