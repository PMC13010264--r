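#' Kinetic constants of the isotope-competition adsorption model
#'
#' Bundles the rate constants describing how a cellulolytic enzyme system
#' partitions between two cellulose substrates. A fraction \code{E_i} of the
#' initially adsorbed enzyme is irreversibly bound and never exchanges; the
#' remainder desorbs with rate constant \code{k_off} and re-adsorbs with rate
#' constant \code{k_on}. Both the irreversible and the reversibly bound pools
#' are catalytically active with apparent specific rate \code{kcat_app}.
#'
#' @param k_off desorption rate constant (min^-1).
#' @param E_i irreversibly adsorbed fraction of the initially bound enzyme,
#'   dimensionless in \code{[0, 1]}.
#' @param k_on adsorption rate constant (mL mg^-1 min^-1). The competition
#'   experiment operates in the adsorption-limited regime (free enzyme
#'   effectively zero), so \code{k_on} is fixed at a large default and is not
#'   a fitted parameter.
#' @param kcat_app apparent specific glucose release rate
#'   (umol min^-1 mg^-1). Cancels from isotope fractions; only sets the
#'   scale of total release.
#' @return An object of class \code{"adsorption_params"}.
#' @seealso [simulate_competition()], [fit_competition()],
#'   [steady_state_ratio()]
#' @export
adsorption_params <- function(k_off, E_i, k_on = 1e4, kcat_app = 1) {
  stopifnot(is.numeric(k_off), length(k_off) == 1L,
            is.numeric(E_i), length(E_i) == 1L,
            is.numeric(k_on), length(k_on) == 1L,
            is.numeric(kcat_app), length(kcat_app) == 1L)
  if (k_off < 0 || k_on < 0 || kcat_app < 0)
    stop("rate constants must be non-negative")
  if (E_i < 0 || E_i > 1)
    stop("E_i must lie in [0, 1]")
  structure(list(k_on = unname(k_on), k_off = unname(k_off),
                 E_i = unname(E_i), kcat_app = unname(kcat_app)),
            class = "adsorption_params")
}

#' @export
print.adsorption_params <- function(x, ...) {
  cat("Adsorption model parameters\n")
  cat(sprintf("  k_off   : %g min^-1\n", x$k_off))
  cat(sprintf("  E_i     : %g (irreversible fraction)\n", x$E_i))
  cat(sprintf("  k_on    : %g mL mg^-1 min^-1 (fixed)\n", x$k_on))
  cat(sprintf("  kcat_app: %g umol min^-1 mg^-1\n", x$kcat_app))
  invisible(x)
}

#' Design of a 13C-competition experiment
#'
#' Describes the experimental layout of a two-substrate competition assay:
#' enzyme preloaded on unlabeled (12C) cellulose, an equal concentration of
#' uniformly 13C-labeled cellulose added at t = 0, and the isotope
#' composition of released glucose sampled over time.
#'
#' @param S12_0,S13_0 substrate concentrations (mg/mL) of the unlabeled and
#'   labeled cellulose. Defaults are the equal 1.0 mg/mL loadings of the
#'   standard assay.
#' @param ES_ratio enzyme-to-substrate mass ratio (mg enzyme per g of the
#'   preloaded 12C cellulose). Default 0.83 mg/g keeps the free-enzyme
#'   concentration effectively zero.
#' @param E_total total enzyme concentration (mg/mL); computed from
#'   \code{ES_ratio} and \code{S12_0} when \code{NULL}.
#' @param sample_times sampling times (min), strictly increasing, all > 0.
#'   The default samples every 30 min over 12 h, several relaxation times
#'   of even the slowest-exchanging system, so that the irreversible
#'   fraction is identified from the near-equilibrium plateau rather than
#'   extrapolated from a partially relaxed curve.
#' @param fit_window two-element numeric, the \code{[t_start, t_end]}
#'   interval (min) used when fitting; must lie within the sampled range.
#' @param noise_sd standard deviation of fraction-scale measurement noise
#'   applied by [simulate_competition()] when positive.
#' @param cumulative logical; report cumulative isotope fractions instead of
#'   the default per-sampling-interval (incremental) fractions.
#' @param deplete_substrate logical; include substrate consumption in the
#'   forward simulation (never used during fitting, where the early fit
#'   window justifies neglecting depletion).
#' @return An object of class \code{"competition_design"}.
#' @export
competition_design <- function(S12_0 = 1.0, S13_0 = 1.0, ES_ratio = 0.83,
                               E_total = NULL,
                               sample_times = seq(30, 720, by = 30),
                               fit_window = range(sample_times),
                               noise_sd = 0,
                               cumulative = FALSE,
                               deplete_substrate = FALSE) {
  if (S12_0 <= 0 || S13_0 <= 0) stop("substrate concentrations must be > 0")
  if (is.null(E_total)) E_total <- ES_ratio * S12_0 / 1000  # mg/g * mg/mL / 1000
  if (E_total <= 0) stop("E_total must be > 0")
  if (any(diff(sample_times) <= 0) || any(sample_times <= 0))
    stop("sample_times must be strictly increasing and positive")
  if (length(fit_window) != 2L || fit_window[1] >= fit_window[2])
    stop("fit_window must be an increasing pair of times")
  if (fit_window[1] > max(sample_times) || fit_window[2] < min(sample_times))
    stop("fit_window must overlap the sampled range")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(S12_0 = S12_0, S13_0 = S13_0, ES_ratio = ES_ratio,
                 E_total = E_total, sample_times = as.numeric(sample_times),
                 fit_window = as.numeric(fit_window), noise_sd = noise_sd,
                 cumulative = cumulative,
                 deplete_substrate = deplete_substrate),
            class = "competition_design")
}

# Right-hand side of the competition ODE system.
# State: R12, R13 (reversibly bound enzyme, mg/mL), G12, G13 (released
# glucose, umol/mL). The irreversible pool I = E_i * E_total stays on the
# 12C substrate; free enzyme F follows by conservation.
competition_rhs <- function(t, state, p) {
  with(as.list(c(state, p)), {
    Fe <- E_total - I - R12 - R13
    s12 <- S12_0
    s13 <- S13_0
    if (p[["deplete"]] > 0.5) {
      # 0.180 mg glucose per umol; 162/180 accounts for the water of hydrolysis
      s12 <- max(S12_0 - 0.180 * (162 / 180) * G12, 0)
      s13 <- max(S13_0 - 0.180 * (162 / 180) * G13, 0)
    }
    dR12 <- k_on * s12 * Fe - k_off * R12
    dR13 <- k_on * s13 * Fe - k_off * R13
    dG12 <- kcat * (I + R12)
    dG13 <- kcat * R13
    list(c(dR12, dR13, dG12, dG13))
  })
}

# Integrate the competition model and return cumulative glucose pools at
# the requested times (t = 0 prepended).
competition_solve <- function(params, design, times) {
  I <- params$E_i * design$E_total
  y0 <- c(R12 = (1 - params$E_i) * design$E_total, R13 = 0, G12 = 0, G13 = 0)
  p <- c(k_on = params$k_on, k_off = params$k_off, kcat = params$kcat_app,
         E_total = design$E_total, I = I,
         S12_0 = design$S12_0, S13_0 = design$S13_0,
         deplete = as.numeric(isTRUE(design$deplete_substrate)))
  tt <- sort(unique(c(0, times)))
  sol <- deSolve::lsoda(y0, tt, competition_rhs, p,
                        rtol = 1e-9, atol = 1e-12, maxsteps = 100000)
  if (anyNA(sol) || any(!is.finite(sol)))
    stop("integration failure: non-finite ODE solution")
  sol <- as.data.frame(sol)
  # enzyme conservation guard
  cons <- sol$R12 + sol$R13 + I
  if (any(cons > design$E_total * (1 + 1e-6)))
    stop("integration failure: enzyme conservation violated")
  sol[match(c(0, times), sol$time), , drop = FALSE]
}

#' Simulate a 13C-competition time series
#'
#' Forward-simulates the three-pool competition model (irreversible pool on
#' the unlabeled substrate, reversible pools exchanging between substrates,
#' free enzyme by conservation) and reports the isotope composition of the
#' glucose released in each sampling interval (or cumulatively, per the
#' design).
#'
#' @param params an [adsorption_params()] object.
#' @param design a [competition_design()] object.
#' @param seed integer seed used only when \code{design$noise_sd > 0}.
#' @return A \code{data.frame} of class \code{"competition_series"} with
#'   columns \code{time} (min), \code{f12}, \code{f13} (isotope fractions of
#'   released glucose, summing to 1) and \code{g_total} (glucose released in
#'   the interval, umol/mL).
#' @details With equal substrate concentrations the long-time 12C/13C
#'   release-rate ratio equals \code{(1 + E_i) / (1 - E_i)}; for fully
#'   reversible adsorption (\code{E_i = 0}) the ratio approaches unity.
#' @export
simulate_competition <- function(params, design, seed = NULL) {
  stopifnot(inherits(params, "adsorption_params"),
            inherits(design, "competition_design"))
  times <- design$sample_times
  if (params$E_i >= 1) {
    # no reversible pool: all release is 12C at all times
    f12 <- rep(1, length(times))
    g12 <- params$kcat_app * design$E_total * times
    ser <- data.frame(time = times, f12 = f12, f13 = 1 - f12,
                      g_total = c(g12[1], diff(g12)))
  } else {
    sol <- competition_solve(params, design, times)
    G12 <- sol$G12; G13 <- sol$G13
    if (design$cumulative) {
      g12 <- G12[-1]; g13 <- G13[-1]
    } else {
      g12 <- diff(G12); g13 <- diff(G13)
    }
    gt <- g12 + g13
    if (any(gt <= 0)) stop("no glucose released in a sampling interval")
    ser <- data.frame(time = times, f12 = g12 / gt, f13 = g13 / gt,
                      g_total = if (design$cumulative) gt else gt)
  }
  if (design$noise_sd > 0) {
    ser <- add_fraction_noise(ser, design$noise_sd, seed)
  }
  class(ser) <- c("competition_series", "data.frame")
  ser
}

# Truncated-Gaussian noise on the 12C fraction, renormalized so f12+f13 = 1.
add_fraction_noise <- function(series, noise_sd, seed = NULL) {
  if (noise_sd >= 0.5) stop("noise_sd >= 0.5 makes fractions meaningless")
  if (!is.null(seed)) set.seed(seed)
  f12 <- series$f12 + stats::rnorm(nrow(series), 0, noise_sd)
  f12 <- pmin(pmax(f12, 0), 1)
  series$f12 <- f12
  series$f13 <- 1 - f12
  series
}

#' Steady-state 12C/13C release-rate ratio
#'
#' Closed-form long-time limit of the competition model at equal substrate
#' concentrations: the reversible pool equilibrates 50/50 between the two
#' substrates while the irreversible fraction \code{E_i} stays on the
#' unlabeled one, giving a release ratio \code{(1 + E_i) / (1 - E_i)}.
#'
#' @param params an [adsorption_params()] object (or a bare \code{E_i}
#'   value).
#' @return The dimensionless ratio; 1 when adsorption is fully reversible.
#' @export
steady_state_ratio <- function(params) {
  E_i <- if (inherits(params, "adsorption_params")) params$E_i else params
  if (E_i < 0 || E_i > 1) stop("E_i must lie in [0, 1]")
  if (E_i == 1) stop("ratio diverges at E_i = 1 (no exchangeable enzyme)")
  (1 + E_i) / (1 - E_i)
}

#' Fit the competition model to an isotope-fraction time series
#'
#' Estimates the desorption rate constant \code{k_off} and the irreversible
#' fraction \code{E_i} by bounded nonlinear least squares
#' (Levenberg-Marquardt) on the observed 12C fractions inside the design's
#' fit window. \code{k_on} stays fixed at the design value (the free-enzyme
#' concentration is effectively zero, so \code{k_on} is not identifiable).
#'
#' @param series a \code{competition_series} (columns \code{time},
#'   \code{f12}).
#' @param design a [competition_design()]; its \code{fit_window} selects the
#'   samples used.
#' @param init an [adsorption_params()] with starting values; defaults to
#'   \code{k_off = 0.01}, \code{E_i = 0.3}.
#' @return An object of class \code{"competition_fit"}: a list with
#'   \code{estimates} (named \code{k_off}, \code{E_i}), \code{se},
#'   \code{conf_int} (95 percent), \code{rss}, \code{converged},
#'   \code{n_points} and \code{k_off_identifiable}. When the series carries
#'   no kinetic information (already at exchange equilibrium) the
#'   \code{k_off_identifiable} flag is \code{FALSE} and only \code{E_i}
#'   should be interpreted.
#' @export
fit_competition <- function(series, design,
                            init = adsorption_params(k_off = 0.01, E_i = 0.3)) {
  stopifnot(inherits(design, "competition_design"))
  if (!all(c("time", "f12") %in% names(series)))
    stop("series must have columns time and f12")
  inw <- series$time >= design$fit_window[1] &
         series$time <= design$fit_window[2]
  obs <- series[inw, , drop = FALSE]
  if (nrow(obs) < 4L) stop("need at least 4 samples inside the fit window")
  if (any(obs$f12 < -1e-9 | obs$f12 > 1 + 1e-9)) stop("invalid fractions")

  fitdesign <- design
  fitdesign$sample_times <- obs$time
  fitdesign$noise_sd <- 0
  fitdesign$deplete_substrate <- FALSE

  predict_f12 <- function(k_off, E_i) {
    p <- adsorption_params(k_off = k_off, E_i = min(E_i, 1 - 1e-9),
                           k_on = init$k_on, kcat_app = init$kcat_app)
    simulate_competition(p, fitdesign)$f12
  }
  resid_fn <- function(par) predict_f12(par[1], par[2]) - obs$f12

  lower <- c(k_off = 1e-6, E_i = 0)
  upper <- c(k_off = 10, E_i = 1 - 1e-6)
  start <- c(k_off = min(max(init$k_off, lower[1]), upper[1]),
             E_i = min(max(init$E_i, lower[2]), upper[2]))
  fit <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  est <- fit$par
  n <- nrow(obs); p <- 2L
  rss <- sum(fit$fvec^2)
  converged <- fit$info %in% 1:4

  # delta-method standard errors from the Gauss-Newton hessian (J'J)
  se <- c(k_off = NA_real_, E_i = NA_real_)
  if (!is.null(fit$hessian) && n > p) {
    s2 <- rss / (n - p)
    cv <- tryCatch(solve(fit$hessian) * s2, error = function(e) NULL)
    if (!is.null(cv)) se[] <- sqrt(pmax(diag(cv), 0))
  }
  tq <- stats::qt(0.975, max(n - p, 1))
  ci <- cbind(lower = est - tq * se, upper = est + tq * se)
  rownames(ci) <- c("k_off", "E_i")

  # k_off identifiability: a four-fold perturbation of k_off must move the
  # predicted fractions by more than a percent of the fraction scale, and
  # the estimate must not sit on a box bound (already-equilibrated series
  # push k_off to the upper bound with vanishing sensitivity)
  sens <- max(abs(predict_f12(est[1] * 2, est[2]) -
                  predict_f12(est[1] / 2, est[2])))
  at_bound <- est[1] >= upper[1] * (1 - 1e-6) || est[1] <= lower[1] * (1 + 1e-6)
  identifiable <- is.finite(sens) && sens > 0.01 && !at_bound

  structure(list(estimates = c(k_off = unname(est[1]), E_i = unname(est[2])),
                 se = se, conf_int = ci, rss = rss,
                 converged = converged, n_points = n,
                 k_off_identifiable = identifiable,
                 fit_window = design$fit_window),
            class = "competition_fit")
}

#' @export
print.competition_fit <- function(x, ...) {
  cat("Competition-model fit\n")
  cat(sprintf("  k_off = %.4g min^-1 (SE %.2g)%s\n",
              x$estimates["k_off"], x$se["k_off"],
              if (x$k_off_identifiable) "" else "  [NOT identifiable]"))
  cat(sprintf("  E_i   = %.4g (SE %.2g)\n", x$estimates["E_i"], x$se["E_i"]))
  cat(sprintf("  RSS %.3g over %d points; converged: %s\n",
              x$rss, x$n_points, x$converged))
  invisible(x)
}
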