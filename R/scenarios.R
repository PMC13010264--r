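#' Degradation program for a synthetic time-lapse experiment
#'
#' Describes how a fibril phantom is degraded over a time-lapse acquisition
#' and which imaging imperfections corrupt the emitted frames. Two modes
#' mirror the two enzyme systems: \code{"ablation"} removes material
#' layer-by-layer from the surface (dispersed cellulases), exposing
#' progressively stiffer core material; \code{"fragmentation"} nucleates
#' full-depth cavities that widen and cut the fiber into fragments
#' (cellulosome), leaving the exposed surface mechanically unchanged until
#' short fragments (below \code{fragment_threshold_nm}) undergo
#' near-complete degradation.
#'
#' @param mode \code{"ablation"} or \code{"fragmentation"}.
#' @param n_frames number of frames (>= 2); with \code{frame_interval_min}
#'   the default run spans about 120 min.
#' @param frame_interval_min time between frames (min), typically 5-10.
#' @param ablation_rate_nm height removed per frame in ablation mode (nm)
#'   on fully compliant (shell) material.
#' @param stiffness_coupling logical (ablation mode): scale the per-frame
#'   erosion by the softness of the currently exposed surface,
#'   \code{(E_core - E(D)) / (E_core - E_shell)}, so the layer-by-layer
#'   attack slows down as stiffer core material is exposed — the cellulase
#'   slowdown the time-lapse experiments show. \code{FALSE} gives constant
#'   erosion.
#' @param nucleation_intensity expected new cavities per frame
#'   (fragmentation mode, Poisson).
#' @param cavity_growth_nm total cavity-edge growth budget per frame (nm),
#'   shared equally among active cavity ends (enzyme-limited attack).
#' @param late_ablation_rate_nm extra erosion per frame (nm) applied to
#'   fragments shorter than \code{fragment_threshold_nm}.
#' @param fragment_threshold_nm fragment length below which near-complete
#'   degradation (and the associated stiffness rise) sets in; default
#'   150 nm.
#' @param drift_nm_per_frame lateral drift per frame, \code{c(x, y)} nm.
#' @param tilt_nm_per_px residual plane tilt added to every frame,
#'   \code{c(gx, gy)} nm per pixel.
#' @param height_noise_sd additive height noise (nm).
#' @param modulus_noise_frac multiplicative modulus noise (fraction of the
#'   local value).
#' @param gain_jitter per-frame uniform modulus gain jitter half-width
#'   (0.2 = +/-20 percent), emulating tip wear and laser drift.
#' @return An object of class \code{"degradation_scenario"}.
#' @export
degradation_scenario <- function(mode = c("ablation", "fragmentation"),
                                 n_frames = 13, frame_interval_min = 10,
                                 ablation_rate_nm = 2.0,
                                 stiffness_coupling = TRUE,
                                 nucleation_intensity = 0.5,
                                 cavity_growth_nm = 36,
                                 late_ablation_rate_nm = 1.8,
                                 fragment_threshold_nm = 150,
                                 drift_nm_per_frame = c(4, 2),
                                 tilt_nm_per_px = c(0.004, 0.006),
                                 height_noise_sd = 0.3,
                                 modulus_noise_frac = 0.05,
                                 gain_jitter = 0.2) {
  mode <- match.arg(mode)
  # fragmentation runs use more, shorter intervals: the late rise needs
  # several frames after the breakpoint within the ~120 min acquisition
  if (mode == "fragmentation") {
    if (missing(n_frames)) n_frames <- 15
    if (missing(frame_interval_min)) frame_interval_min <- 8
  }
  if (n_frames < 2) stop("need at least 2 frames")
  if (ablation_rate_nm < 0 || nucleation_intensity < 0 ||
      cavity_growth_nm < 0 || late_ablation_rate_nm < 0)
    stop("rates must be non-negative")
  dur <- (n_frames - 1) * frame_interval_min
  if (dur > 150)
    warning("total duration ", dur, " min exceeds the ~120 min a stable ",
            "time-lapse acquisition sustains")
  structure(list(mode = mode, n_frames = as.integer(n_frames),
                 frame_interval_min = frame_interval_min,
                 ablation_rate_nm = ablation_rate_nm,
                 stiffness_coupling = stiffness_coupling,
                 nucleation_intensity = nucleation_intensity,
                 cavity_growth_nm = cavity_growth_nm,
                 late_ablation_rate_nm = late_ablation_rate_nm,
                 fragment_threshold_nm = fragment_threshold_nm,
                 drift_nm_per_frame = drift_nm_per_frame,
                 tilt_nm_per_px = tilt_nm_per_px,
                 height_noise_sd = height_noise_sd,
                 modulus_noise_frac = modulus_noise_frac,
                 gain_jitter = gain_jitter),
            class = "degradation_scenario")
}

# Build a map_frame from true height/modulus, then apply drift, tilt, gain
# and noise. Returns the corrupted frame plus the applied corruption record.
corrupt_frame <- function(phantom, h_true, E_true, time, scenario, frame_i,
                          corrupt = TRUE) {
  px <- phantom$pixel_size
  h <- h_true; E <- E_true
  drift_px <- c(0L, 0L); gain <- 1
  if (corrupt) {
    drift_px <- round((frame_i - 1) * rev(scenario$drift_nm_per_frame) / px)
    if (any(drift_px != 0)) {
      h <- translate_int(h, drift_px[1], drift_px[2], 0)
      E <- translate_int(E, drift_px[1], drift_px[2], phantom$E_substrate)
    }
    g <- scenario$tilt_nm_per_px
    h <- h + g[1] * col(h) + g[2] * row(h)
    gain <- 1 + stats::runif(1, -scenario$gain_jitter, scenario$gain_jitter)
    E <- E * gain
    if (scenario$height_noise_sd > 0)
      h <- h + stats::rnorm(length(h), 0, scenario$height_noise_sd)
    if (scenario$modulus_noise_frac > 0)
      E <- E * (1 + stats::rnorm(length(E), 0, scenario$modulus_noise_frac))
  }
  list(frame = map_frame(h, E, pixel_size = px, time = time),
       drift_px = drift_px, gain = gain)
}

#' Generate a layer-by-layer ablation stack
#'
#' Emulates degradation by dispersed cellulases: a uniform layer of
#' material is removed from the fiber surface each frame, so the exposed
#' surface follows the core-shell depth profile and the true surface-mean
#' modulus rises monotonically with volume loss. Drift, tilt, per-frame
#' gain jitter and noise are applied after the degradation program; ground
#' truth is recorded pre-corruption.
#'
#' @param phantom a [gen_fibril_phantom()].
#' @param scenario a [degradation_scenario()] with \code{mode="ablation"}.
#' @param seed integer seed.
#' @param corrupt apply imaging corruptions (default TRUE); FALSE gives
#'   clean frames for truth-level studies.
#' @return A list with \code{stack} (a [frame_stack()]) and \code{truth}
#'   (per-frame true volume nm^3, surface-mean modulus MPa, fiber masks,
#'   applied drift and gains).
#' @export
gen_ablation_stack <- function(phantom, scenario = degradation_scenario("ablation"),
                               seed = 1, corrupt = TRUE) {
  stopifnot(inherits(phantom, "fibril_phantom"),
            scenario$mode == "ablation")
  set.seed(seed)
  h0 <- phantom$height0
  frames <- vector("list", scenario$n_frames)
  truth <- list(volume = numeric(scenario$n_frames),
                surface_modulus = numeric(scenario$n_frames),
                masks = vector("list", scenario$n_frames),
                drift_px = matrix(0L, scenario$n_frames, 2),
                gain = numeric(scenario$n_frames),
                times = numeric(scenario$n_frames))
  D <- 0
  for (f in seq_len(scenario$n_frames)) {
    if (f > 1) {
      soft <- if (isTRUE(scenario$stiffness_coupling)) {
        (phantom$E_core - depth_modulus(phantom, D)) /
          (phantom$E_core - phantom$E_shell)
      } else 1
      D <- D + scenario$ablation_rate_nm * soft
    }
    h <- pmax(h0 - D, 0)
    remaining <- h > 0
    E <- surface_modulus_map(phantom, D, remaining)
    t_f <- (f - 1) * scenario$frame_interval_min
    truth$volume[f] <- sum(h) * phantom$pixel_size^2
    truth$surface_modulus[f] <-
      if (any(remaining)) mean(E[remaining]) else NA_real_
    truth$masks[[f]] <- remaining
    truth$times[f] <- t_f
    cf <- corrupt_frame(phantom, h, E, t_f, scenario, f, corrupt)
    frames[[f]] <- cf$frame
    truth$drift_px[f, ] <- cf$drift_px
    truth$gain[f] <- cf$gain
  }
  list(stack = frame_stack(frames), truth = truth)
}

#' Generate a cavity-driven fragmentation stack
#'
#' Emulates degradation by the cellulosome: full-depth cavities nucleate
#' along the fiber (a Poisson process biased 3:1 toward the soft segments,
#' the preferred sites of initial attack) and widen under a fixed total
#' growth budget shared among active cavity ends. While cavities remove
#' material the exposed surface of the remaining fiber keeps its original
#' shell modulus, so the true surface-mean modulus stays almost flat
#' despite substantial volume loss. Once fragments shorten below the
#' fragment threshold they undergo accelerated near-complete degradation,
#' exposing core material and driving the late stiffness rise — the
#' biphasic truth program.
#'
#' @inheritParams gen_ablation_stack
#' @param scenario a [degradation_scenario()] with
#'   \code{mode="fragmentation"}.
#' @return As [gen_ablation_stack()]; \code{truth} additionally carries
#'   \code{breakpoint_loss_pct}, the percent volume loss at the time the
#'   first fragment dropped below the fragment threshold.
#' @export
gen_fragmentation_stack <- function(phantom,
                                    scenario = degradation_scenario("fragmentation"),
                                    seed = 1, corrupt = TRUE) {
  stopifnot(inherits(phantom, "fibril_phantom"),
            scenario$mode == "fragmentation")
  if (scenario$nucleation_intensity == 0 && scenario$cavity_growth_nm > 0)
    warning("no cavities will ever nucleate; fragmentation stack is a no-op")
  set.seed(seed)
  px <- phantom$pixel_size
  h0 <- phantom$height0
  nx <- ncol(h0)
  fiber_cols <- phantom$fiber_cols
  x_nm <- (seq_len(nx) - 0.5) * px            # column center coordinates
  soft <- phantom$soft_col_factor < 1
  cavities <- matrix(numeric(0), ncol = 2)    # rows of [left, right] nm
  ero <- numeric(nx)                          # per-column extra erosion, nm

  frames <- vector("list", scenario$n_frames)
  nfr <- scenario$n_frames
  truth <- list(volume = numeric(nfr), surface_modulus = numeric(nfr),
                masks = vector("list", nfr),
                drift_px = matrix(0L, nfr, 2), gain = numeric(nfr),
                times = numeric(nfr), breakpoint_loss_pct = NA_real_)
  x_min <- min(x_nm[fiber_cols]) - px / 2
  x_max <- max(x_nm[fiber_cols]) + px / 2
  first_short_frame <- NA_integer_

  for (f in seq_len(nfr)) {
    if (f > 1) {
      # The enzyme pool sets a fixed total degradation budget per frame
      # (expressed as nm of full-depth cavity length). Enzyme working at
      # the interface of a fragment already below the fragment threshold
      # consumes that fragment (late ablation); whatever budget remains
      # widens cavities whose ends border long fragments. The overall
      # material-loss rate therefore stays roughly steady across the flat
      # and rising phases, as observed for the cellulosome.
      # The enzyme pool sets a fixed total degradation budget per frame,
      # expressed as nm of full-depth cavity length. It is spent in order
      # on: (1) consuming fragments already below the fragment threshold
      # (late ablation, the budget-equivalent of their eroded volume),
      # (2) opening new attack sites, (3) widening cavities whose ends
      # border long fragments. The overall material-loss rate therefore
      # stays roughly steady across the flat and rising phases, as
      # observed for the cellulosome.
      frag_now <- fragment_runs(cavities, x_min, x_max)
      vol_per_nm <- sum(h0[, round(ncol(h0) / 2)]) * px^2 / px
      budget <- scenario$cavity_growth_nm
      if (nrow(frag_now) > 0 && scenario$late_ablation_rate_nm > 0) {
        short <- which((frag_now[, 2] - frag_now[, 1]) <=
                         scenario$fragment_threshold_nm)
        if (length(short) && is.na(first_short_frame))
          first_short_frame <- f - 1L
        for (k in short[sample.int(length(short))]) {  # fair order
          if (budget <= 0) break
          cols <- which(x_nm >= frag_now[k, 1] & x_nm <= frag_now[k, 2])
          # erosion stops at the shell depth: the isolated crystalline
          # cores persist through the late stage of the reaction
          ero_cap <- phantom$shell_thickness_nm
          if (all(ero[cols] >= ero_cap)) next
          h_before <- pmax(sweep(h0[, cols, drop = FALSE], 2, ero[cols],
                                 `-`), 0)
          ero_full <- pmin(ero[cols] + scenario$late_ablation_rate_nm,
                           ero_cap)
          full_after <- pmax(sweep(h0[, cols, drop = FALSE], 2, ero_full,
                                   `-`), 0)
          full_cost <- sum(h_before - full_after) * px^2 / max(vol_per_nm, 1e-9)
          # partial-depth erosion when the budget cannot cover the full step
          frac <- if (full_cost > budget) budget / full_cost else 1
          ero[cols] <- ero[cols] + frac * (ero_full - ero[cols])
          budget <- budget - frac * full_cost
        }
      }
      budget <- max(0, budget)
      # The first two degradation frames open one attack site each, at
      # well-separated interior positions (jittered thirds of the fiber),
      # reproducing the distinct, spread-out initial attack loci the
      # time-lapse images show; the enzyme binds and nicks the fiber at
      # once. Later sites follow a Poisson process, biased 3:1 toward soft
      # segments, in the fiber interior (the edges of the imaged region
      # are not free fiber ends) and at a minimum spacing from existing
      # cavities, so short fragments arise by cavity growth rather than by
      # nucleation right next to an existing cavity.
      if (f <= 3L && budget >= 10) {
        frac0 <- if (f == 2L) 0.35 else 0.65
        pos <- x_min + frac0 * (x_max - x_min) + stats::runif(1, -15, 15)
        clear <- nrow(cavities) == 0 ||
          all(pos < cavities[, 1] - (scenario$fragment_threshold_nm + 100) |
              pos > cavities[, 2] + (scenario$fragment_threshold_nm + 100))
        if (clear) {
          cavities <- rbind(cavities, c(pos - 5, pos + 5))
          budget <- budget - 10
        }
      }
      n_new <- stats::rpois(1, scenario$nucleation_intensity)
      if (n_new > 0) {
        margin <- scenario$fragment_threshold_nm + 90
        min_sep <- scenario$fragment_threshold_nm + 100
        for (dummy in seq_len(n_new)) {
          if (budget < 10) break
          okx <- x_nm[fiber_cols] >= x_min + margin &
                 x_nm[fiber_cols] <= x_max - margin
          if (nrow(cavities) > 0)
            for (k in seq_len(nrow(cavities)))
              okx <- okx & (x_nm[fiber_cols] < cavities[k, 1] - min_sep |
                            x_nm[fiber_cols] > cavities[k, 2] + min_sep)
          sites <- fiber_cols[okx]
          if (!length(sites)) break   # attack sites saturated
          w <- ifelse(soft[sites], 3, 1)
          pos <- x_nm[sites[sample.int(length(sites), 1, prob = w)]]
          cavities <- rbind(cavities, c(pos - 5, pos + 5))
          budget <- budget - 10
        }
      }
      cavities <- merge_intervals(cavities, x_min, x_max)
      if (nrow(cavities) > 0 && budget > 0) {
        frag_now <- fragment_runs(cavities, x_min, x_max)
        long_at <- function(edge) {
          k <- which(abs(frag_now[, 1] - edge) < 1e-6 |
                     abs(frag_now[, 2] - edge) < 1e-6)
          length(k) > 0 &&
            any(frag_now[k, 2] - frag_now[k, 1] > scenario$fragment_threshold_nm)
        }
        ends <- cbind(cavities[, 1] > x_min & vapply(cavities[, 1], long_at, TRUE),
                      cavities[, 2] < x_max & vapply(cavities[, 2], long_at, TRUE))
        n_active <- sum(ends)
        if (n_active > 0) {
          g <- budget / n_active
          cavities[, 1] <- ifelse(ends[, 1], cavities[, 1] - g, cavities[, 1])
          cavities[, 2] <- ifelse(ends[, 2], cavities[, 2] + g, cavities[, 2])
        }
      }
      cavities <- merge_intervals(cavities, x_min, x_max)
    }
    in_cavity <- logical(nx)
    if (nrow(cavities) > 0)
      for (k in seq_len(nrow(cavities)))
        in_cavity <- in_cavity |
          (x_nm >= cavities[k, 1] & x_nm <= cavities[k, 2])
    h <- sweep(h0, 2, ero, function(hh, e) pmax(hh - e, 0))
    h[, in_cavity] <- 0
    remaining <- h > 0
    depth <- matrix(rep(ero, each = nrow(h0)), nrow(h0), nx)
    E <- surface_modulus_map(phantom, depth, remaining)
    t_f <- (f - 1) * scenario$frame_interval_min
    truth$volume[f] <- sum(h) * px^2
    truth$surface_modulus[f] <-
      if (any(remaining)) mean(E[remaining]) else NA_real_
    truth$masks[[f]] <- remaining
    truth$times[f] <- t_f
    cf <- corrupt_frame(phantom, h, E, t_f, scenario, f, corrupt)
    frames[[f]] <- cf$frame
    truth$drift_px[f, ] <- cf$drift_px
    truth$gain[f] <- cf$gain
  }
  if (!is.na(first_short_frame))
    truth$breakpoint_loss_pct <-
      100 * (1 - truth$volume[first_short_frame] / truth$volume[1])
  list(stack = frame_stack(frames), truth = truth)
}

# Merge overlapping [left, right] intervals and clip to the fiber extent.
merge_intervals <- function(iv, x_min, x_max) {
  if (nrow(iv) == 0) return(iv)
  iv[, 1] <- pmax(iv[, 1], x_min)
  iv[, 2] <- pmin(iv[, 2], x_max)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) for (k in 2:nrow(iv)) {
    if (iv[k, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], iv[k, 2])
    } else out <- rbind(out, iv[k, , drop = FALSE])
  }
  out
}

# Complement of the cavity set within the fiber extent: remaining fragments.
fragment_runs <- function(cavities, x_min, x_max) {
  if (nrow(cavities) == 0) return(matrix(c(x_min, x_max), ncol = 2))
  edges <- c(x_min, t(cavities), x_max)
  runs <- matrix(edges, ncol = 2, byrow = TRUE)
  runs[runs[, 2] - runs[, 1] > 1e-9, , drop = FALSE]
}

#' Simulate a degradation trajectory without imaging
#'
#' Runs the same degradation programs as the image-stack generators on a
#' clean phantom and returns the ground-truth volume and surface-modulus
#' series with measurement-level noise added — a fast way to produce many
#' trajectories for classifier studies without rendering and re-processing
#' image stacks.
#'
#' @param mode \code{"ablation"} or \code{"fragmentation"}.
#' @param seed integer seed.
#' @param phantom a [gen_fibril_phantom()].
#' @param scenario a [degradation_scenario()] for the chosen mode.
#' @param estar_noise_frac relative noise on the E*_av readout (default
#   0.01, conservative relative to the sub-percent scatter the map
#   pipeline delivers after HOPG normalization).
#' @param volume_noise_frac relative noise on the volume readout.
#' @return A [degradation_trajectory()] with attribute \code{"truth"}.
#' @export
gen_degradation_trajectory <- function(mode = c("ablation", "fragmentation"),
                                       seed = 1,
                                       phantom = gen_fibril_phantom(),
                                       scenario = NULL,
                                       estar_noise_frac = 0.01,
                                       volume_noise_frac = 0.01) {
  mode <- match.arg(mode)
  if (is.null(scenario)) scenario <- degradation_scenario(mode)
  gen <- if (mode == "ablation") gen_ablation_stack else gen_fragmentation_stack
  res <- gen(phantom, scenario, seed = seed, corrupt = FALSE)
  tr <- res$truth
  set.seed(seed + 10000L)
  vol <- tr$volume * (1 + stats::rnorm(length(tr$volume), 0, volume_noise_frac))
  est <- tr$surface_modulus *
    (1 + stats::rnorm(length(tr$volume), 0, estar_noise_frac))
  out <- degradation_trajectory(times = tr$times, volumes = vol,
                                estar_av = est)
  attr(out, "truth") <- tr
  out
}

#' Simulate a noisy isotope-competition dataset with known truth
#'
#' Wraps [simulate_competition()] with truncated-Gaussian measurement noise
#' on the isotope fractions (renormalized so f12 + f13 = 1) and records the
#' generating parameters.
#'
#' @param truth an [adsorption_params()] object (the generating values).
#' @param design a [competition_design()]; its \code{noise_sd} sets the
#'   fraction-scale noise (default assays use 0.03).
#' @param seed integer seed; fixed seeds give bitwise-identical series.
#' @return A list with \code{series} (a \code{competition_series}) and
#'   \code{truth}.
#' @export
gen_competition_data <- function(truth, design, seed = 1) {
  clean_design <- design
  clean_design$noise_sd <- 0
  ser <- simulate_competition(truth, clean_design)
  if (design$noise_sd > 0)
    ser <- add_fraction_noise(ser, design$noise_sd, seed)
  list(series = ser, truth = truth)
}
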