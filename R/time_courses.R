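# Canonical on-disk form: one row per (dish, scoring time), cumulative counts,
# times in hours, water potentials signed (0, -0.01, ...) in MPa.

.grid_cols <- c("temperature_C", "psi_MPa", "replicate", "time_h",
                "cum_germinated", "n_sown")

.trait_cols <- c("temperature_C", "psi_MPa", "replicate",
                 "seedling_length_cm", "root_dw_mg", "shoot_dw_mg",
                 "seed_dw_mg")

.cell_label <- function(row) {
  sprintf("temperature_C=%g, psi_MPa=%g, replicate=%s",
          row$temperature_C[1], row$psi_MPa[1], row$replicate[1])
}

.stop_schema <- function(msg) {
  stop(errorCondition(msg, class = c("seedhtt_schema_error", "seedhtt_error")))
}

.stop_validation <- function(msg) {
  stop(errorCondition(msg,
                      class = c("seedhtt_validation_error", "seedhtt_error")))
}

#' Assemble and validate a germination treatment grid
#'
#' Takes a data frame of cumulative germination counts (one row per dish and
#' scoring time) and returns a validated, canonically ordered
#' `germination_grid`. All downstream readers, fitters and the simulator
#' exchange this container.
#'
#' Required columns: `temperature_C`, `psi_MPa`, `replicate`, `time_h`,
#' `cum_germinated`, `n_sown`. Water potentials must be non-positive (osmotic
#' potentials), scoring times positive and strictly increasing within a dish,
#' counts non-decreasing and bounded by the number of seeds sown.
#'
#' @param df data frame with the columns listed above.
#' @return `df`, ordered by treatment, replicate and time, with class
#'   `germination_grid`.
#' @examples
#' df <- data.frame(temperature_C = 20, psi_MPa = 0, replicate = 1,
#'                  time_h = c(24, 48), cum_germinated = c(10, 15), n_sown = 40)
#' as_germination_grid(df)
#' @export
as_germination_grid <- function(df) {
  missing <- setdiff(.grid_cols, names(df))
  if (length(missing) > 0) {
    .stop_schema(paste0("missing required column(s): ",
                        paste(missing, collapse = ", ")))
  }
  df <- as.data.frame(df)[, c(.grid_cols, setdiff(names(df), .grid_cols))]
  for (col in c("temperature_C", "psi_MPa", "time_h", "cum_germinated",
                "n_sown")) {
    if (!is.numeric(df[[col]])) {
      .stop_schema(paste0("column ", col, " must be numeric"))
    }
    if (anyNA(df[[col]]) || any(!is.finite(df[[col]]))) {
      .stop_validation(paste0("column ", col, " contains missing or ",
                              "non-finite values"))
    }
  }
  if (any(df$psi_MPa > 0)) {
    .stop_validation("psi_MPa must be <= 0 (osmotic potentials are non-positive)")
  }
  if (any(df$time_h <= 0)) {
    .stop_validation("time_h must be > 0")
  }
  if (any(df$n_sown <= 0)) {
    .stop_validation("n_sown must be > 0")
  }
  df <- df[order(df$temperature_C, df$psi_MPa, df$replicate, df$time_h), ,
           drop = FALSE]
  rownames(df) <- NULL
  key <- interaction(df$temperature_C, df$psi_MPa, df$replicate, drop = TRUE)
  for (dish in split(df, key)) {
    lab <- .cell_label(dish)
    if (anyDuplicated(dish$time_h)) {
      .stop_validation(paste0("duplicate scoring time for dish ", lab))
    }
    if (length(unique(dish$n_sown)) != 1) {
      .stop_validation(paste0("n_sown differs across scoring times for dish ",
                              lab))
    }
    if (any(dish$cum_germinated < 0 | dish$cum_germinated > dish$n_sown)) {
      .stop_validation(paste0("cumulative count outside [0, n_sown] for dish ",
                              lab))
    }
    if (is.unsorted(dish$cum_germinated)) {
      bad <- which(diff(dish$cum_germinated) < 0)[1] + 1
      .stop_validation(sprintf(
        "non-monotone cumulative count at %s, time_h=%g", lab,
        dish$time_h[bad]))
    }
  }
  class(df) <- c("germination_grid", "data.frame")
  df
}

#' Read a germination time-course table
#'
#' Reads a delimiter-separated text file of cumulative germination counts
#' into a validated [as_germination_grid()] container.
#'
#' @param path path to a text table with a header row.
#' @param sep field delimiter (default comma).
#' @param negate_psi if `TRUE`, water potentials given as magnitudes
#'   (0.01, 0.05, ...) are negated on read. Off by default: the canonical
#'   form stores signed values.
#' @return a `germination_grid`.
#' @seealso [write_time_courses()]
#' @export
read_time_courses <- function(path, sep = ",", negate_psi = FALSE) {
  if (!file.exists(path)) {
    .stop_schema(paste0("file not found: ", path))
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (negate_psi) df$psi_MPa <- -abs(df$psi_MPa)
  as_germination_grid(df)
}

#' Write a germination time-course table
#'
#' @param grid a `germination_grid`.
#' @param path output path.
#' @param sep field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_time_courses <- function(grid, path, sep = ",") {
  grid <- as_germination_grid(grid)
  utils::write.table(grid, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a seedling-trait table
#'
#' One row per dish: seedling length (cm) and root, shoot and seed dry
#' weights (mg), used by the vigor indices and the root:shoot ratio.
#'
#' @inheritParams read_time_courses
#' @return data frame with validated trait columns.
#' @export
read_seedling_traits <- function(path, sep = ",", negate_psi = FALSE) {
  if (!file.exists(path)) {
    .stop_schema(paste0("file not found: ", path))
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  missing <- setdiff(.trait_cols, names(df))
  if (length(missing) > 0) {
    .stop_schema(paste0("missing required column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (negate_psi) df$psi_MPa <- -abs(df$psi_MPa)
  vals <- df[, c("seedling_length_cm", "root_dw_mg", "shoot_dw_mg",
                 "seed_dw_mg")]
  if (any(vals < 0, na.rm = TRUE)) {
    .stop_validation("seedling traits must be >= 0")
  }
  df
}

#' Germination fractions of a single dish
#'
#' Converts the cumulative counts of one time course into germinated
#' fractions of the seeds sown.
#'
#' @param course data frame holding one dish (single
#'   temperature/potential/replicate) with columns `time_h`,
#'   `cum_germinated`, `n_sown`.
#' @return data frame with columns `time_h` and `fraction` (in \[0, 1\],
#'   non-decreasing).
#' @examples
#' course <- data.frame(time_h = c(24, 48), cum_germinated = c(10, 15),
#'                      n_sown = 40)
#' germination_fractions(course)  # 0.25, 0.375
#' @export
germination_fractions <- function(course) {
  needed <- c("time_h", "cum_germinated", "n_sown")
  missing <- setdiff(needed, names(course))
  if (length(missing) > 0) {
    .stop_schema(paste0("missing required column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (length(unique(course$n_sown)) != 1) {
    .stop_validation("germination_fractions expects a single dish")
  }
  ord <- order(course$time_h)
  data.frame(time_h = course$time_h[ord],
             fraction = course$cum_germinated[ord] / course$n_sown[ord])
}

#' Split a grid into single-dish time courses
#'
#' @param grid a `germination_grid`.
#' @return named list of data frames, one per (temperature, potential,
#'   replicate) dish, in canonical order.
#' @export
time_courses <- function(grid) {
  grid <- as_germination_grid(grid)
  key <- interaction(grid$temperature_C, grid$psi_MPa, grid$replicate,
                     drop = TRUE, lex.order = TRUE)
  split(as.data.frame(grid), key)
}

#' Pool replicate dishes within each treatment
#'
#' Sums cumulative counts and seeds sown across replicates sharing a
#' (temperature, water potential) treatment. Replicates of a treatment must
#' have been scored on the same time grid; cumulative counts are step
#' functions, so resampling between scorings would fabricate observations.
#'
#' @param grid a `germination_grid`.
#' @return a `germination_grid` with one pseudo-replicate `"pooled"` per
#'   treatment.
#' @export
pool_replicates <- function(grid) {
  grid <- as_germination_grid(grid)
  key <- interaction(grid$temperature_C, grid$psi_MPa, drop = TRUE)
  for (cell in split(as.data.frame(grid), key)) {
    grids <- split(cell$time_h, cell$replicate)
    if (length(unique(lapply(grids, sort))) != 1) {
      .stop_validation(sprintf(
        "replicates at temperature_C=%g, psi_MPa=%g were scored on different time grids; cannot pool",
        cell$temperature_C[1], cell$psi_MPa[1]))
    }
  }
  agg <- stats::aggregate(
    cbind(cum_germinated, n_sown) ~ temperature_C + psi_MPa + time_h,
    data = as.data.frame(grid), FUN = sum)
  agg$replicate <- "pooled"
  as_germination_grid(agg)
}

#' @export
print.germination_grid <- function(x, ...) {
  n_dish <- length(unique(interaction(x$temperature_C, x$psi_MPa,
                                      x$replicate, drop = TRUE)))
  cat(sprintf(
    "germination_grid: %d dishes (%d temperatures x %d potentials), %d rows\n",
    n_dish, length(unique(x$temperature_C)), length(unique(x$psi_MPa)),
    nrow(x)))
  print(utils::head(as.data.frame(x), 8), ...)
  if (nrow(x) > 8) cat("...\n")
  invisible(x)
}
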