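#' CGM sensor configuration
#'
#' Continuous glucose monitor model: the plasma glucose is sampled every
#' `period` minutes and perturbed by first-order autocorrelated Gaussian
#' noise, `n(t) = rho * n(t-1) + e(t)`, `e ~ N(0, sd^2)`, then clipped to the
#' reportable range 39--400 mg/dL. With `noise = "off"` the reading is the
#' clipped plasma glucose itself.
#'
#' @param period sampling period in minutes (default 5).
#' @param noise `"off"` or `"autocorrelated"`.
#' @param sd innovation standard deviation, mg/dL (default 2; the stationary
#'   marginal s.d. is `sd / sqrt(1 - rho^2)`).
#' @param rho per-step autocorrelation in `[0, 1)` (default 0.7).
#' @return an object of class `cgm_config`.
#' @export
cgm_config <- function(period = 5, noise = c("autocorrelated", "off"),
                       sd = 2, rho = 0.7) {
  noise <- match.arg(noise)
  if (period <= 0) stop("sampling period must be positive")
  if (sd < 0) stop("noise sd must be non-negative")
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  structure(list(period = period, noise = noise, sd = sd, rho = rho),
            class = "cgm_config")
}

#' Draw one CGM reading
#'
#' Advances the autocorrelated noise state by one step and returns the
#' clipped reading. Randomness is taken from the current R RNG stream, so
#' seeding the stream makes the noise sequence reproducible.
#'
#' @param plasma_glucose true plasma glucose, mg/dL, `> 0`.
#' @param previous_noise the noise state carried from the previous sample
#'   (0 at start-up).
#' @param config a [cgm_config()].
#' @return list with `reading` (mg/dL, in 39--400) and `noise` (new state).
#' @export
#' @examples
#' cgm_sample(100, 0, cgm_config(noise = "off"))$reading  # 100
cgm_sample <- function(plasma_glucose, previous_noise, config) {
  if (!is.finite(plasma_glucose) || plasma_glucose <= 0)
    stop("plasma glucose must be positive")
  noise <- if (config$noise == "off") 0
           else config$rho * previous_noise + rnorm(1, 0, config$sd)
  reading <- min(400, max(39, plasma_glucose + noise))
  list(reading = reading, noise = noise)
}
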