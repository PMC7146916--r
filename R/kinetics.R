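#' Exponential growth rate of a trait time-series
#'
#' Fits `value = a * exp(k * t)` by ordinary least squares on
#' `log(value) ~ t`, restricted to the imaging-session window (sessions 2
#' to 5 by default, matching the interval over which root expansion is
#' close to exponential). Zero or negative values inside the window are
#' excluded with a warning; at least three positive in-window points are
#' required.
#'
#' @param time Numeric vector of imaging-session indices.
#' @param value Numeric vector of trait values (same length).
#' @param window Inclusive session window, default `c(2, 5)`.
#' @return List with `k` (per-session exponential rate), `r2` of the
#'   log-linear fit, and `n` points used.
#' @export
growth_rate <- function(time, value, window = c(2, 5)) {
  stopifnot(length(time) == length(value))
  inwin <- time >= window[1L] & time <= window[2L] & !is.na(value)
  nonpos <- inwin & value <= 0
  if (any(nonpos)) {
    warn(sprintf("%d non-positive value(s) in window excluded from exponential fit.",
                 sum(nonpos)))
    inwin <- inwin & value > 0
  }
  if (sum(inwin) < 3L)
    abort("Fewer than 3 positive observations inside the fitting window.",
          class = "rhizoquant_insufficient_data")
  t <- time[inwin]; y <- log(value[inwin])
  fit <- lm(y ~ t)
  # noiseless series fit exactly; the summary() warning for that case is moot
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (is.nan(r2)) r2 <- 1  # constant series: perfect fit with k = 0
  list(k = unname(coef(fit)[2L]), r2 = r2, n = sum(inwin))
}

#' Growth rates for every plant and trait in a stacked trait table
#'
#' Takes the long trait table produced by [all_traits()] rows stacked over
#' time points and returns one exponential growth rate per plant and trait.
#'
#' @param traits Data frame with `plant_id`, `time_point` and trait columns.
#' @param trait_cols Character vector of trait columns to fit; defaults to
#'   the size traits whose expansion is close to exponential.
#' @param window Inclusive session window passed to [growth_rate()].
#' @return Tibble with `plant_id`, `trait`, `k`, `r2`, `n`; plants with
#'   insufficient in-window data get `NA` rates.
#' @export
growth_rates <- function(traits,
                         trait_cols = c("total_length", "total_area",
                                        "convex_area", "perimeter", "volume"),
                         window = c(2, 5)) {
  trait_cols <- intersect(trait_cols, names(traits))
  long <- tidyr::pivot_longer(
    traits[, c("plant_id", "time_point", trait_cols)],
    dplyr::all_of(trait_cols), names_to = "trait", values_to = "value")
  long %>%
    group_by(.data$plant_id, .data$trait) %>%
    summarise(fit = list(tryCatch(
      growth_rate(.data$time_point, .data$value, window = window),
      rhizoquant_insufficient_data = function(e) list(k = NA_real_,
                                                      r2 = NA_real_, n = 0L))),
      .groups = "drop") %>%
    mutate(k = map_dbl(.data$fit, "k"),
           r2 = map_dbl(.data$fit, "r2"),
           n = map_dbl(.data$fit, "n")) %>%
    select(-"fit")
}
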