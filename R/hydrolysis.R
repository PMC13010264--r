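#' Bulk hydrolysis time course
#'
#' Container for a glucose-release time course with optional free-enzyme
#' measurements. Conversion is computed from released glucose on an
#' anhydroglucose basis (162/180 mass correction for the water added on
#' hydrolysis) unless supplied directly.
#'
#' @param times sampling times (min).
#' @param glucose released glucose (g/L).
#' @param substrate_0 initial substrate loading (g/L).
#' @param enzyme_free,enzyme_total optional enzyme concentrations (mg/mL);
#'   when both are given the adsorbed enzyme follows by mass balance.
#' @param conversion optional conversion values in \code{[0, 1]}; computed
#'   from glucose when \code{NULL}.
#' @return A \code{data.frame} of class \code{"hydrolysis_series"}.
#' @export
hydrolysis_series <- function(times, glucose, substrate_0,
                              enzyme_free = NULL, enzyme_total = NULL,
                              conversion = NULL) {
  stopifnot(length(times) == length(glucose), substrate_0 > 0)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (is.null(conversion)) conversion <- (162 / 180) * glucose / substrate_0
  if (any(conversion < -1e-9 | conversion > 1 + 1e-9))
    stop("conversion outside [0, 1]")
  out <- data.frame(time = times, glucose = glucose,
                    conversion = pmin(pmax(conversion, 0), 1))
  if (!is.null(enzyme_free)) {
    out$enzyme_free <- enzyme_free
    if (!is.null(enzyme_total))
      out$enzyme_adsorbed <- adsorbed_enzyme(enzyme_total, enzyme_free)
  }
  attr(out, "substrate_0") <- substrate_0
  class(out) <- c("hydrolysis_series", "data.frame")
  out
}

#' Adsorbed enzyme by mass balance
#'
#' @param enzyme_total,enzyme_free total and free (solution) enzyme
#'   concentrations (mg/mL), vectorized.
#' @return Adsorbed enzyme concentration (mg/mL), never negative.
#' @export
adsorbed_enzyme <- function(enzyme_total, enzyme_free) {
  if (any(enzyme_free < 0) || any(enzyme_total < 0))
    stop("enzyme concentrations must be non-negative")
  if (any(enzyme_free > enzyme_total + 1e-12))
    stop("enzyme_free exceeds enzyme_total")
  pmax(enzyme_total - enzyme_free, 0)
}

#' Specific activity of the adsorbed enzyme
#'
#' The glucose release rate per unit mass of adsorbed enzyme, the quantity
#' used to follow how the activity of surface-bound enzyme evolves with
#' substrate conversion.
#'
#' @param glucose_rate glucose release rate (umol min^-1).
#' @param enzyme_adsorbed adsorbed enzyme mass (mg), must be positive.
#' @param se_rate,se_enzyme optional standard errors; when either is given
#'   the result carries an \code{"se"} attribute from first-order error
#'   propagation.
#' @return Specific rate (umol min^-1 mg^-1).
#' @export
r_ads <- function(glucose_rate, enzyme_adsorbed,
                  se_rate = NULL, se_enzyme = NULL) {
  if (any(enzyme_adsorbed <= 0)) stop("enzyme_adsorbed must be > 0")
  val <- glucose_rate / enzyme_adsorbed
  if (!is.null(se_rate) || !is.null(se_enzyme)) {
    if (is.null(se_rate)) se_rate <- 0
    if (is.null(se_enzyme)) se_enzyme <- 0
    rel2 <- (se_rate / glucose_rate)^2 + (se_enzyme / enzyme_adsorbed)^2
    rel2[glucose_rate == 0] <- (se_rate / enzyme_adsorbed)[glucose_rate == 0]^2
    attr(val, "se") <- abs(val) * sqrt(rel2)
    attr(val, "se")[glucose_rate == 0] <- se_rate / enzyme_adsorbed
  }
  val
}

#' Initial hydrolysis rate
#'
#' Least-squares slope of glucose versus time over an initial window,
#' the standard "rate within the first hour" descriptor.
#'
#' @param series a [hydrolysis_series()] (or data.frame with \code{time} and
#'   \code{glucose}).
#' @param window_min length of the initial window (min), default 60.
#' @return Slope in glucose units per minute.
#' @export
initial_rate <- function(series, window_min = 60) {
  sel <- series$time <= window_min
  if (sum(sel) < 2L) stop("need at least 2 samples inside the window")
  unname(stats::coef(stats::lm(glucose ~ time, data = series[sel, ]))[2])
}

#' Rate-versus-conversion analysis
#'
#' Computes the instantaneous conversion rate by finite differences (central
#' in the interior, one-sided at the ends), regresses it on conversion, and
#' extrapolates the conversion at which the reaction stalls
#' (\code{-intercept/slope}, clipped to \code{[0, 1]}). A near-linear decline
#' of rate with conversion that stalls well short of complete conversion is
#' the signature of substrate recalcitrance.
#'
#' @param series a [hydrolysis_series()] with non-decreasing conversion.
#' @return A list with \code{slope}, \code{intercept},
#'   \code{stall_conversion} (\code{NA} with \code{stall_defined = FALSE}
#'   when the rate does not decline), and the fitted \code{lm} object.
#' @export
rate_vs_conversion <- function(series) {
  x <- series$conversion
  t <- series$time
  n <- length(x)
  if (n < 3L) stop("need at least 3 points")
  if (any(diff(x) < -1e-9)) stop("conversion must be non-decreasing")
  rate <- numeric(n)
  rate[1] <- (x[2] - x[1]) / (t[2] - t[1])
  rate[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
  if (n > 2L)
    rate[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  fit <- stats::lm(rate ~ x)
  b <- unname(stats::coef(fit))
  # the stall extrapolation is meaningful only when the rate declines
  # appreciably over the observed conversion range
  decline <- -b[2] * diff(range(x))
  stall_defined <- b[2] < 0 && decline > 0.01 * mean(abs(rate))
  stall <- if (stall_defined) min(max(-b[1] / b[2], 0), 1) else NA_real_
  list(slope = b[2], intercept = b[1], stall_conversion = stall,
       stall_defined = stall_defined, fit = fit)
}

#' Read a competition series from CSV
#'
#' Accepts either fraction columns (\code{time_min, f12, f13}) or percentage
#' columns (\code{time_min, pct12, pct13}).
#'
#' @param path CSV file path.
#' @return A \code{competition_series} data.frame.
#' @export
read_competition_csv <- function(path) {
  d <- utils::read.csv(path)
  if (all(c("pct12", "pct13") %in% names(d))) {
    d$f12 <- d$pct12 / 100
    d$f13 <- d$pct13 / 100
  }
  if (!all(c("time_min", "f12", "f13") %in% names(d)))
    stop("CSV needs columns time_min plus f12/f13 or pct12/pct13")
  if (any(abs(d$f12 + d$f13 - 1) > 1e-6))
    stop("f12 + f13 must equal 1 for every sample")
  out <- data.frame(time = d$time_min, f12 = d$f12, f13 = d$f13)
  if ("g_total" %in% names(d)) out$g_total <- d$g_total
  class(out) <- c("competition_series", "data.frame")
  out
}

#' Write a competition series to CSV
#'
#' @param series a \code{competition_series}.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_competition_csv <- function(series, path) {
  d <- data.frame(time_min = series$time, f12 = series$f12,
                  f13 = series$f13)
  if ("g_total" %in% names(series)) d$g_total <- series$g_total
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read a hydrolysis time course from CSV
#'
#' Expects columns \code{time_min}, \code{glucose} and optionally
#' \code{enzyme_free}.
#'
#' @param path CSV file path.
#' @param substrate_0 initial substrate loading (g/L).
#' @param enzyme_total total enzyme (mg/mL), optional.
#' @return A [hydrolysis_series()].
#' @export
read_hydrolysis_csv <- function(path, substrate_0, enzyme_total = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("time_min", "glucose") %in% names(d)))
    stop("CSV needs columns time_min and glucose")
  hydrolysis_series(d$time_min, d$glucose, substrate_0,
                    enzyme_free = d[["enzyme_free"]],
                    enzyme_total = enzyme_total)
}
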