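#' Acoustic medium properties
#'
#' @param density Density, kg/m^3.
#' @param sound_speed Speed of sound, m/s.
#' @param attenuation Attenuation coefficient, dB/(MHz^2 cm).
#' @return A list of class `medium_properties`. Defaults are free-field
#'   water.
#' @export
medium_properties <- function(density = 1000, sound_speed = 1500,
                              attenuation = 0.002) {
  if (density <= 0 || sound_speed <= 0 || attenuation < 0)
    stop("medium properties must be positive")
  structure(list(density = density, sound_speed = sound_speed,
                 attenuation = attenuation),
            class = "medium_properties")
}

#' Annular transducer geometry
#'
#' @param inner_diameter,outer_diameter Annulus diameters, mm
#'   (0 <= inner < outer; inner 0 gives a plain circular piston).
#' @param frequency Drive frequency, MHz.
#' @return A list of class `annular_geometry`. Defaults are the 11/19 mm
#'   annulus at 1 MHz used throughout the package.
#' @export
annular_geometry <- function(inner_diameter = 11, outer_diameter = 19,
                             frequency = 1) {
  if (inner_diameter < 0 || outer_diameter <= inner_diameter)
    stop("need 0 <= inner_diameter < outer_diameter")
  if (frequency <= 0) stop("frequency must be positive")
  structure(list(inner_diameter = inner_diameter,
                 outer_diameter = outer_diameter,
                 frequency = frequency),
            class = "annular_geometry")
}

#' Pulse duty cycle
#'
#' Fraction of each pulse repetition interval during which the transducer is
#' driven: `PD / PRI`.
#'
#' @param pd Pulse duration, ms.
#' @param pri Pulse repetition interval, ms (`1000 / PRF`).
#' @return Duty cycle in (0, 1].
#' @examples
#' duty_cycle(50, 100)  # 0.5
#' @export
duty_cycle <- function(pd, pri) {
  if (pd <= 0 || pri <= 0) stop("pd and pri must be positive")
  if (pd > pri) stop("pulse duration exceeds repetition interval")
  pd / pri
}

#' Actual ultrasound on-time of one stimulation train
#'
#' @param sd_s Stimulation duration (train length), s.
#' @param duty Duty cycle in `[0, 1]`.
#' @return On-time, s (`sd_s * duty`); 0.25 s for a 0.5 s train at 50% duty.
#' @export
on_time <- function(sd_s, duty) {
  if (sd_s < 0) stop("sd_s must be >= 0")
  if (duty < 0 || duty > 1) stop("duty must be in [0, 1]")
  sd_s * duty
}

#' Mechanical index
#'
#' `MI = P / sqrt(f)` with the peak negative pressure `P` in MPa and the
#' frequency `f` in MHz; a cavitation-risk proxy bounded by 1.9 in
#' diagnostic regulation.
#'
#' @param p_mpa Peak negative pressure, MPa.
#' @param f_mhz Frequency, MHz.
#' @return MI, unitless.
#' @examples
#' mechanical_index(0.45, 1)  # 0.45
#' @export
mechanical_index <- function(p_mpa, f_mhz) {
  if (f_mhz <= 0) stop("frequency must be positive")
  if (any(p_mpa < 0)) stop("pressure must be >= 0")
  p_mpa / sqrt(f_mhz)
}

#' Spatial-peak pulse-average intensity
#'
#' Plane-wave relation `I = P^2 / (2 rho c)` evaluated with the peak
#' negative pressure, converted to W/cm^2. 450 kPa in water gives
#' 6.75 W/cm^2.
#'
#' @param p_pa Peak negative pressure, Pa.
#' @param medium A [medium_properties()].
#' @return I_sppa, W/cm^2.
#' @export
isppa <- function(p_pa, medium = medium_properties()) {
  if (any(p_pa < 0)) stop("pressure must be >= 0")
  p_pa^2 / (2 * medium$density * medium$sound_speed) / 1e4
}

#' Spatial-peak temporal-average intensity
#'
#' Scales I_sppa by the within-train duty cycle and the train's share of the
#' repetition period: `I_spta = I_sppa * duty * SD / period * 1000` (mW/cm^2).
#' The default period convention is `SD + SI` (one train every 30.5 s for the
#' standard protocol), giving 55.33 mW/cm^2 at 6.75 W/cm^2 and 50% duty.
#'
#' @param i_sppa I_sppa, W/cm^2.
#' @param duty Duty cycle in `[0, 1]`.
#' @param sd_s Stimulation duration, s.
#' @param period_s Train repetition period, s (>= `sd_s`).
#' @return I_spta, mW/cm^2.
#' @export
ispta <- function(i_sppa, duty, sd_s, period_s) {
  if (period_s <= 0) stop("period must be positive")
  if (sd_s <= 0 || sd_s > period_s) stop("need 0 < sd_s <= period_s")
  if (duty < 0 || duty > 1) stop("duty must be in [0, 1]")
  i_sppa * duty * (sd_s / period_s) * 1000
}

#' Full exposure report for a protocol
#'
#' Bundles the timing and safety metrics of a stimulation protocol: duty
#' cycle, on-time per train, pulse count, MI, I_sppa and I_spta (period
#' `SD + SI`).
#'
#' @param protocol A [stimulus_protocol()].
#' @param medium A [medium_properties()].
#' @return A list of class `exposure_report`.
#' @export
exposure_report <- function(protocol, medium = medium_properties()) {
  validate_protocol(protocol)
  duty <- duty_cycle(protocol$pd, protocol$pri)
  i_pa <- isppa(protocol$peak_negative_pressure * 1e3, medium)
  rep <- list(
    duty_cycle = duty,
    on_time_per_train = on_time(protocol$sd_s, duty),
    pulses_per_train = pulses_per_train(protocol),
    mi = mechanical_index(protocol$peak_negative_pressure / 1e3,
                          protocol$center_frequency),
    isppa_w_cm2 = i_pa,
    ispta_mw_cm2 = ispta(i_pa, duty, protocol$sd_s,
                         protocol$sd_s + protocol$si_s))
  class(rep) <- "exposure_report"
  rep
}

#' @export
print.exposure_report <- function(x, ...) {
  cat(sprintf(
    paste0("<exposure_report> duty %.1f%% | on-time %.4g s | %d pulses/train | ",
           "MI %.3g | Isppa %.4g W/cm2 | Ispta %.4g mW/cm2\n"),
    100 * x$duty_cycle, x$on_time_per_train, x$pulses_per_train,
    x$mi, x$isppa_w_cm2, x$ispta_mw_cm2))
  invisible(x)
}

#' Ordinary least-squares pressure-voltage calibration
#'
#' Fits `pressure = slope * voltage + intercept` by OLS, as used to calibrate
#' focal pressure against drive amplitude.
#'
#' @param voltage Drive voltage amplitudes (>= 2 distinct values).
#' @param pressure Measured focal pressures (same length).
#' @return A list with `slope`, `intercept`, `r_squared` and the `lm` fit.
#' @export
fit_pressure_voltage <- function(voltage, pressure) {
  if (length(voltage) != length(pressure)) stop("lengths differ")
  if (length(unique(voltage)) < 2) stop("need >= 2 distinct voltages")
  fit <- stats::lm(pressure ~ voltage)
  tss <- sum((pressure - mean(pressure))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       fit = fit)
}
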