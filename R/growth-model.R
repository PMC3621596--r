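# Dose-dependent logistic growth model used by every synthetic plate assay.
#
# A single Hill-type inhibition factor f(c) = max(0, 1 - (c/c_max)^h) scales
# both the specific growth rate and the carrying capacity, so one calibration
# fixes the whole dose-response family and the stationary-phase OD ratio has
# a closed form.

#' Dose-response parameters for the synthetic growth model
#'
#' Bundles the parameters of the logistic butanol dose-response model:
#' at concentration `c` (% v/v) the effective rate is
#' `mu(c) = mu0 * f(c)` and the plateau `K(c) = K0 * f(c)` with
#' `f(c) = max(0, 1 - (c/c_max)^h)`. Above `c_max` growth ceases.
#'
#' Defaults describe a laboratory *S. cerevisiae* strain in a sealed 96-well
#' plate: maximal specific growth rate 0.40 h^-1, unstressed stationary OD660
#' of 1.2, inoculum OD 0.05, no measurement noise.
#'
#' @param mu0 maximal specific growth rate (per hour), > 0.
#' @param K0 unstressed carrying capacity (OD660 units), > `od0`.
#' @param c_max concentration at which growth ceases (% v/v), > 0.
#' @param h Hill steepness (dimensionless), > 0.
#' @param od0 inoculum OD660, > 0.
#' @param noise_sd multiplicative lognormal OD noise standard deviation
#'   (log scale), >= 0.
#' @return an object of class `dose_response_params` (a named list).
#' @seealso [calibrate_reference()], [generate_growth_curve()]
#' @export
dose_response_params <- function(mu0 = 0.40, K0 = 1.2, c_max = 1.45,
                                 h = 1.865, od0 = 0.05, noise_sd = 0) {
  check_that(is_number(mu0) && mu0 > 0, "mu0 must be a positive number")
  check_that(is_number(od0) && od0 > 0, "od0 must be a positive number")
  check_that(is_number(K0) && K0 > od0, "K0 must exceed od0")
  check_that(is_number(c_max) && c_max > 0, "c_max must be positive")
  check_that(is_number(h) && h > 0, "h must be positive")
  check_that(is_number(noise_sd) && noise_sd >= 0,
             "noise_sd must be non-negative")
  structure(list(mu0 = mu0, K0 = K0, c_max = c_max, h = h,
                 od0 = od0, noise_sd = noise_sd),
            class = "dose_response_params")
}

#' @export
print.dose_response_params <- function(x, ...) {
  cat("Dose-response parameters (shared Hill inhibition)\n")
  cat(sprintf("  mu0 = %.3f h^-1, K0 = %.3f OD, od0 = %.3f OD\n",
              x$mu0, x$K0, x$od0))
  cat(sprintf("  c_max = %.3f %% v/v, h = %.4f, noise_sd = %.3f\n",
              x$c_max, x$h, x$noise_sd))
  invisible(x)
}

# shared inhibition factor f(c) in [0, 1]
inhibition_factor <- function(params, concentration) {
  pmax(0, 1 - (concentration / params$c_max)^params$h)
}

#' Calibrate the dose-response model to a stationary-phase OD ratio
#'
#' Solves the Hill steepness `h` so that the plateau at 1% butanol is
#' `1/target_od_ratio_at_1pct` of the unstressed plateau, while `c_max` is
#' pinned at the concentration where growth ceases. Because one inhibition
#' factor scales rate and plateau alike, the solution is closed form:
#' `h = log(1 - 1/ratio) / log(1 / c_noGrowth)`.
#'
#' With the reference calibration (ratio 2 at 1%, no growth above 1.45%)
#' the generated 48-h OD ratio control/butanol — the butanol sensitivity
#' index — equals the target ratio once the culture has saturated.
#'
#' @param target_od_ratio_at_1pct stationary OD ratio (0% over 1% butanol),
#'   must be > 1.
#' @param c_noGrowth concentration (% v/v) above which no growth occurs,
#'   must be > 1.
#' @param ... further parameters passed to [dose_response_params()]
#'   (e.g. `mu0`, `K0`, `od0`, `noise_sd`).
#' @return a `dose_response_params` object with the solved `h`.
#' @examples
#' p <- calibrate_reference(2.0, 1.45)
#' p$h # closed-form Hill steepness
#' @export
calibrate_reference <- function(target_od_ratio_at_1pct, c_noGrowth, ...) {
  check_that(is_number(target_od_ratio_at_1pct),
             "target ratio must be a number")
  check_that(is_number(c_noGrowth) && c_noGrowth > 1,
             "c_noGrowth must be > 1 (%% v/v)")
  if (target_od_ratio_at_1pct <= 1) {
    stop("target OD ratio must exceed 1: a ratio of 1 means no inhibition, ",
         "which is incompatible with a finite no-growth concentration",
         call. = FALSE)
  }
  h <- log(1 - 1 / target_od_ratio_at_1pct) / log(1 / c_noGrowth)
  check_that(is.finite(h) && h > 0, "infeasible ratio/c_noGrowth combination")
  dose_response_params(c_max = c_noGrowth, h = h, ...)
}

#' Generate one synthetic growth curve
#'
#' Simulates a blank-corrected OD660 trajectory under the logistic model with
#' dose-dependent rate and plateau. In noise-free mode the curve is the exact
#' logistic solution and is monotone non-decreasing; when the dose-scaled
#' plateau falls at or below the inoculum OD the culture cannot grow and the
#' curve stays flat at `od0`. With `noise_sd > 0` readings are multiplied by
#' iid lognormal factors `exp(N(0, noise_sd^2))`.
#'
#' @param params a [dose_response_params()] object.
#' @param concentration butanol concentration (% v/v), >= 0.
#' @param duration total incubation time in hours (default 48).
#' @param interval sampling interval in minutes (default 30, mirroring
#'   half-hourly plate-reader acquisition).
#' @param seed optional integer seed for the noise draws.
#' @param strain,well optional labels carried in the result's attributes.
#' @return a `growth_curve`: a data frame with columns `time_h` and `od660`
#'   and attributes `strain`, `well` and `concentration`.
#' @export
generate_growth_curve <- function(params, concentration, duration = 48,
                                  interval = 30, seed = NULL,
                                  strain = NA_character_,
                                  well = NA_character_) {
  stopifnot(inherits(params, "dose_response_params"))
  check_that(is_number(concentration) && concentration >= 0,
             "concentration must be a non-negative number (%% v/v)")
  check_that(is_number(interval) && interval > 0, "interval must be > 0")
  check_that(is_number(duration) && duration > 0, "duration must be > 0")

  times <- seq(0, duration, by = interval / 60)
  od <- logistic_od(params, concentration, times)
  if (params$noise_sd > 0) {
    od <- with_seed(seed, od * exp(stats::rnorm(length(od), 0,
                                                params$noise_sd)))
  }
  growth_curve(times, od, strain = strain, well = well,
               concentration = concentration)
}

# exact logistic solution at the dose-scaled (mu, K); flat when growth is
# impossible (f = 0 or plateau at/below inoculum)
logistic_od <- function(params, concentration, times) {
  f <- inhibition_factor(params, concentration)
  mu <- params$mu0 * f
  K <- params$K0 * f
  od0 <- params$od0
  if (mu <= 0 || K <= od0) {
    return(rep(od0, length(times)))
  }
  # decaying-exponential form: safe from overflow at large mu * t
  K / (1 + ((K - od0) / od0) * exp(-mu * times))
}

#' Construct a growth-curve object
#'
#' @param times time points in hours, strictly increasing.
#' @param od blank-corrected OD660 readings, non-negative, same length.
#' @param strain,well,concentration metadata stored as attributes.
#' @return a data frame of class `growth_curve`.
#' @export
growth_curve <- function(times, od, strain = NA_character_,
                         well = NA_character_, concentration = NA_real_) {
  check_that(length(times) == length(od),
             "times and od must have equal length")
  check_that(all(diff(times) > 0), "times must be strictly increasing")
  check_that(all(od >= 0), "od readings must be non-negative")
  structure(data.frame(time_h = times, od660 = od),
            strain = strain, well = well, concentration = concentration,
            class = c("growth_curve", "data.frame"))
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf(
    "Growth curve: strain %s, %.2f%% butanol, %d readings over %.1f h\n",
    attr(x, "strain"), attr(x, "concentration"), nrow(x),
    max(x$time_h)))
  cat(sprintf("  final OD660 = %.4f\n", x$od660[nrow(x)]))
  invisible(x)
}
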