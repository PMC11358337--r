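#' Seasonal preset for the synthetic diel forcing generator
#'
#' A preset bundles the shape parameters of an idealized 24 h day: a sinusoidal
#' air temperature between a pre-dawn minimum and a mid-afternoon maximum, a
#' half-sine light curve between sunrise and sunset, a stone temperature offset
#' that follows insolation (stone warmer than air under sun, cooler at night),
#' and a fixed dewpoint from which relative humidity is derived. The four named
#' presets are ordered so that mean daily water activity increases from summer
#' (hot, large diel swing) to winter (cold, persistently humid).
#'
#' @param name one of `"summer"`, `"spring"`, `"autumn"`, `"winter"`, or
#'   `"custom"` (in which case every shape parameter must be supplied).
#' @param T_a_min,T_a_max daily air temperature range \[degC\].
#' @param dewpoint dewpoint temperature \[degC\]; relative humidity is
#'   `e_sat(dewpoint)/e_sat(T_a)` clipped to \[0, 1\].
#' @param I_max peak light intensity \[uE m-2 s-1\].
#' @param sunrise,sunset daylight window \[h\], `0 <= sunrise < sunset <= 24`.
#' @param stone_day_offset stone-minus-air temperature at full sun \[degC\].
#' @param stone_night_offset air-minus-stone temperature at night \[degC\].
#' @return an object of class `sab_preset`.
#' @export
#' @examples
#' season_preset("summer")
#' season_preset("custom", T_a_min = 5, T_a_max = 12, dewpoint = 4,
#'               I_max = 800, sunrise = 7, sunset = 18,
#'               stone_day_offset = 3, stone_night_offset = 2)
season_preset <- function(name = c("summer", "spring", "autumn", "winter", "custom"),
                          T_a_min = NULL, T_a_max = NULL, dewpoint = NULL,
                          I_max = NULL, sunrise = NULL, sunset = NULL,
                          stone_day_offset = NULL, stone_night_offset = NULL) {
  name <- match.arg(name)
  defaults <- list(
    summer = list(T_a_min = 20, T_a_max = 33, dewpoint = 17, I_max = 2000,
                  sunrise = 5.5, sunset = 19.5,
                  stone_day_offset = 8, stone_night_offset = 2),
    spring = list(T_a_min = 10, T_a_max = 24, dewpoint = 10, I_max = 1600,
                  sunrise = 6, sunset = 19,
                  stone_day_offset = 6, stone_night_offset = 2),
    autumn = list(T_a_min = 8, T_a_max = 18, dewpoint = 6, I_max = 1000,
                  sunrise = 6.5, sunset = 18,
                  stone_day_offset = 4, stone_night_offset = 2),
    winter = list(T_a_min = 0, T_a_max = 8, dewpoint = 4, I_max = 700,
                  sunrise = 7.5, sunset = 17,
                  stone_day_offset = 2, stone_night_offset = 2)
  )
  base <- if (name == "custom") list() else defaults[[name]]
  supplied <- list(T_a_min = T_a_min, T_a_max = T_a_max, dewpoint = dewpoint,
                   I_max = I_max, sunrise = sunrise, sunset = sunset,
                   stone_day_offset = stone_day_offset,
                   stone_night_offset = stone_night_offset)
  supplied <- supplied[!vapply(supplied, is.null, logical(1))]
  p <- utils::modifyList(base, supplied)
  required <- c("T_a_min", "T_a_max", "dewpoint", "I_max", "sunrise", "sunset",
                "stone_day_offset", "stone_night_offset")
  missing <- setdiff(required, names(p))
  if (length(missing) > 0)
    stop("preset is missing fields: ", paste(missing, collapse = ", "))
  p <- p[required]
  p$name <- name
  if (p$T_a_min > p$T_a_max) stop("T_a_min must not exceed T_a_max")
  if (p$I_max < 0) stop("I_max must be non-negative")
  if (!(p$sunrise >= 0 && p$sunrise < p$sunset && p$sunset <= 24))
    stop("need 0 <= sunrise < sunset <= 24")
  if (p$stone_day_offset < 0 || p$stone_night_offset < 0)
    stop("stone temperature offsets must be non-negative")
  structure(p, class = "sab_preset")
}

#' @export
print.sab_preset <- function(x, ...) {
  cat(sprintf("<sab_preset '%s'> T_a %g..%g degC, dewpoint %g degC, I_max %g uE, day %g-%g h\n",
              x$name, x$T_a_min, x$T_a_max, x$dewpoint, x$I_max, x$sunrise, x$sunset))
  invisible(x)
}

# raw preset curves, vectorized over t in [0, 24)
preset_curves <- function(preset, t) {
  mid <- (preset$T_a_min + preset$T_a_max) / 2
  amp <- (preset$T_a_max - preset$T_a_min) / 2
  t_min <- preset$sunrise - 1 # coldest just before dawn
  T_a <- mid - amp * cos(2 * pi * (t - t_min) / 24)
  I <- ifelse(t >= preset$sunrise & t <= preset$sunset,
              preset$I_max * sin(pi * (t - preset$sunrise) /
                                   (preset$sunset - preset$sunrise)),
              0)
  I <- pmax(I, 0)
  frac <- if (preset$I_max > 0) I / preset$I_max else 0 * I
  T_s <- T_a + preset$stone_day_offset * frac -
    preset$stone_night_offset * (1 - frac)
  RH_a <- pmin(1, magnus_e_sat(preset$dewpoint) / magnus_e_sat(T_a))
  list(T_a = T_a, T_s = T_s, RH_a = RH_a, I = I)
}

#' Generate a 24 h-periodic synthetic diel forcing table
#'
#' Builds an [sab_forcing] object from a seasonal preset on a regular time
#' grid. Air temperature is sinusoidal (minimum one hour before sunrise,
#' maximum twelve hours later), light a half-sine over the daylight window,
#' stone temperature smoothly blends a day offset (scaled by instantaneous
#' insolation) with a night offset, and relative humidity follows from the
#' preset dewpoint via the Magnus saturation vapor pressure.
#'
#' @param preset an [season_preset()] object.
#' @param resolution sample spacing \[h\] (default 0.25 h).
#' @return an `sab_forcing` object (see [sab_forcing()]).
#' @export
#' @examples
#' f <- make_diel_forcing(season_preset("summer"))
#' sample_forcing(f, c(0, 6, 12, 18))
make_diel_forcing <- function(preset, resolution = 0.25) {
  stopifnot(inherits(preset, "sab_preset"))
  if (!(resolution > 0 && resolution <= 6))
    stop("resolution must be in (0, 6] hours")
  t <- seq(0, 24 - resolution / 2, by = resolution)
  cv <- preset_curves(preset, t)
  sab_forcing(data.frame(time_h = t, T_air_C = cv$T_a, T_stone_C = cv$T_s,
                         RH_air = cv$RH_a, light_uE = cv$I))
}

#' Construct a periodic environmental forcing object
#'
#' Validates a one-day forcing table and wraps it for periodic piecewise-linear
#' sampling. Times must lie in \[0, 24) and be strictly increasing; relative
#' humidity is a fraction in \[0, 1\]; light intensity is non-negative.
#'
#' @param samples data frame with columns `time_h`, `T_air_C`, `T_stone_C`,
#'   `RH_air` (fraction), `light_uE`.
#' @return an object of class `sab_forcing` with fields `samples` and
#'   `period` (always 24 h).
#' @export
sab_forcing <- function(samples) {
  required <- c("time_h", "T_air_C", "T_stone_C", "RH_air", "light_uE")
  missing <- setdiff(required, names(samples))
  if (length(missing) > 0)
    stop("forcing table is missing columns: ", paste(missing, collapse = ", "))
  samples <- as.data.frame(samples)[required]
  if (nrow(samples) < 4) stop("forcing needs at least 4 samples over the day")
  t <- samples$time_h
  if (any(!is.finite(as.matrix(samples)))) stop("forcing table contains non-finite values")
  if (any(t < 0 | t >= 24)) stop("sample times must lie in [0, 24)")
  if (any(diff(t) <= 0)) stop("sample times must be strictly increasing (no duplicates)")
  if (any(samples$RH_air < 0 | samples$RH_air > 1)) stop("RH_air must lie in [0, 1]")
  if (any(samples$light_uE < 0)) stop("light_uE must be non-negative")
  structure(list(samples = samples, period = 24), class = "sab_forcing")
}

#' @export
print.sab_forcing <- function(x, ...) {
  s <- x$samples
  cat(sprintf("<sab_forcing> %d samples over 24 h; T_air %.1f..%.1f degC, RH %.2f..%.2f, I max %.0f uE\n",
              nrow(s), min(s$T_air_C), max(s$T_air_C), min(s$RH_air),
              max(s$RH_air), max(s$light_uE)))
  invisible(x)
}

#' Read a forcing table from CSV
#'
#' Expects columns `time_h`, `T_air_C`, `T_stone_C`, `RH_air`, `light_uE` with
#' a header row. Relative humidity may be given as a fraction or in percent;
#' any value above 1.5 switches interpretation to percent for the whole
#' column. Times are normalized into \[0, 24) (a trailing `24` duplicate of
#' hour 0 is dropped).
#'
#' @param path path to a CSV file.
#' @return an [sab_forcing()] object.
#' @export
read_forcing_table <- function(path) {
  tab <- utils::read.csv(path, check.names = TRUE)
  required <- c("time_h", "T_air_C", "T_stone_C", "RH_air", "light_uE")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0)
    stop("forcing CSV is missing columns: ", paste(missing, collapse = ", "))
  rh <- tab$RH_air
  if (any(rh < 0 | rh > 100)) stop("RH_air outside [0, 100]")
  if (any(rh > 1.5)) rh <- rh / 100 # percent scale auto-detected
  tab$RH_air <- rh
  if (any(tab$time_h == 24) && any(tab$time_h %% 24 == 0))
    tab <- tab[tab$time_h != 24, , drop = FALSE] # trailing midnight duplicate
  tab$time_h <- tab$time_h %% 24
  tab <- tab[order(tab$time_h), , drop = FALSE]
  sab_forcing(tab)
}

#' Write a forcing table to CSV
#'
#' @param forcing an [sab_forcing()] object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_forcing_table <- function(forcing, path) {
  stopifnot(inherits(forcing, "sab_forcing"))
  utils::write.csv(forcing$samples, path, row.names = FALSE)
  invisible(path)
}

#' Sample a periodic forcing at arbitrary times
#'
#' Piecewise-linear interpolation of the one-day table, periodically extended:
#' `sample_forcing(f, t)` equals `sample_forcing(f, t + 24)` exactly, and the
#' interval between the last sample and the (wrapped) first sample is
#' interpolated across midnight.
#'
#' @param forcing an [sab_forcing()] object.
#' @param t numeric vector of times \[h\], `t >= 0`.
#' @return data frame with columns `t`, `T_a`, `T_s`, `RH_a`, `I`.
#' @export
sample_forcing <- function(forcing, t) {
  stopifnot(inherits(forcing, "sab_forcing"))
  if (any(t < 0)) stop("t must be non-negative")
  fns <- forcing_functions(forcing)
  data.frame(t = t, T_a = fns$T_a(t), T_s = fns$T_s(t),
             RH_a = fns$RH_a(t), I = fns$I(t))
}

# Fast periodic interpolators (one closure per channel) used inside the ODE
# right-hand side; wraps the last->first segment across midnight.
forcing_functions <- function(forcing) {
  s <- forcing$samples
  tt <- c(s$time_h, s$time_h[1] + 24)
  mk <- function(v) {
    vv <- c(v, v[1])
    function(t) stats::approx(tt, vv, xout = (t - tt[1]) %% 24 + tt[1],
                              method = "linear", rule = 2)$y
  }
  list(T_a = mk(s$T_air_C), T_s = mk(s$T_stone_C),
       RH_a = mk(s$RH_air), I = mk(s$light_uE))
}
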