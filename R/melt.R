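# FRET thermal-shift melt curves: simulation, Tm estimation, QC, delta-Tm,
# and the active call.
#
# The assay monitors donor fluorescence of a dual-labeled folded RNA while
# temperature is ramped; unfolding separates donor and quencher, so the
# signal rises through a sigmoidal transition whose inflection is the
# melting temperature Tm. A compound that stabilizes the fold shifts Tm up.

#' Construct a melt curve
#'
#' A melt curve is a fluorescence-versus-temperature trace for one compound
#' (or for a compound-free reference well). Temperatures must be strictly
#' increasing, with at least 5 points.
#'
#' @param temperature numeric vector of temperatures (degrees C), strictly
#'   increasing.
#' @param fluorescence numeric vector of intensities (arbitrary units), same
#'   length as `temperature`.
#' @param compound_id identifier of the measured compound (or reference well).
#' @param is_reference logical; `TRUE` for a compound-free control curve.
#' @return an object of class `melt_curve`.
#' @seealso [estimate_tm()], [simulate_melt_curve()]
#' @export
melt_curve <- function(temperature, fluorescence, compound_id = "",
                       is_reference = FALSE) {
  temperature <- as.numeric(temperature)
  fluorescence <- as.numeric(fluorescence)
  assert_that(length(temperature) == length(fluorescence),
              "temperature and fluorescence must have equal length")
  assert_that(length(temperature) >= 5,
              "a melt curve needs at least 5 grid points",
              subclass = "iterscreen_degenerate_grid")
  assert_that(all(is.finite(temperature)) && all(is.finite(fluorescence)),
              "melt curve values must be finite")
  assert_that(all(diff(temperature) > 0),
              "temperatures must be strictly increasing")
  structure(
    list(compound_id = as.character(compound_id),
         temperature = temperature,
         fluorescence = fluorescence,
         is_reference = isTRUE(is_reference)),
    class = "melt_curve"
  )
}

#' @export
print.melt_curve <- function(x, ...) {
  cat(sprintf("<melt_curve> %s%s: %d points, %.1f-%.1f degC\n",
              x$compound_id, if (x$is_reference) " (reference)" else "",
              length(x$temperature), min(x$temperature), max(x$temperature)))
  invisible(x)
}

#' Default temperature grid of the thermal-shift assay
#'
#' 25 to 95 degrees C in 2 degree increments, the ramp used throughout the
#' package's simulated assays.
#'
#' @return numeric vector of temperatures.
#' @export
default_melt_grid <- function() seq(25, 95, by = 2)

#' Simulate a melt curve from a two-state unfolding model
#'
#' Generates fluorescence `baseline + amplitude / (1 + exp(-(T - tm) / width))`
#' plus optional Gaussian noise: a logistic rise with inflection at `tm_true`,
#' mimicking the increase in donor fluorescence as the RNA unfolds.
#'
#' @param tm_true true melting temperature (degrees C).
#' @param amplitude signal change across the transition (arbitrary units).
#' @param baseline low-temperature signal level.
#' @param width transition width parameter (degrees C), must be positive.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param grid temperature grid (strictly increasing, at least 5 points).
#' @param seed integer seed making the noise reproducible; `NULL` uses the
#'   current RNG stream.
#' @param compound_id,is_reference passed to [melt_curve()].
#' @return a [melt_curve()] object.
#' @examples
#' crv <- simulate_melt_curve(61, seed = 1)
#' estimate_tm(crv)
#' @export
simulate_melt_curve <- function(tm_true, amplitude = 1, baseline = 0,
                                width = 2, noise_sd = 0,
                                grid = default_melt_grid(), seed = NULL,
                                compound_id = "", is_reference = FALSE) {
  assert_that(is.numeric(width) && width > 0, "width must be positive")
  assert_that(length(grid) >= 5, "grid needs at least 5 points",
              subclass = "iterscreen_degenerate_grid")
  assert_that(all(diff(grid) > 0), "grid must be strictly increasing")
  f <- baseline + amplitude / (1 + exp(-(grid - tm_true) / width))
  if (noise_sd > 0) {
    f <- f + with_seed(seed, stats::rnorm(length(grid), 0, noise_sd))
  }
  melt_curve(grid, f, compound_id = compound_id, is_reference = is_reference)
}

#' Control parameters for Tm estimation and melt-curve QC
#'
#' @param smooth_window width (grid points, odd) of the symmetric
#'   moving-average smoother applied before differentiation. The default 3 is
#'   deliberately light: the assay grid is coarse (2 degree steps) and heavier
#'   smoothing biases the inflection estimate.
#' @param snr_min minimum ratio of post-smoothing amplitude to residual noise;
#'   below it a trace is called `nonsigmoidal`.
#' @param boundary_exclude number of grid points at each end of the ramp
#'   within which an inflection is not trusted (`no_inflection`).
#' @param secondary_ratio a second transition whose first-derivative peak
#'   reaches this fraction of the main peak (with a real valley between)
#'   makes the curve `irregular`.
#' @param monotone_min minimum ratio of net signal rise to total variation of
#'   the smoothed trace; below it the trace is not predominantly monotone and
#'   is called `nonsigmoidal`.
#' @param refine refine the derivative-based inflection by a local two-state
#'   (Boltzmann sigmoid) least-squares fit of the raw trace, initialized at
#'   the crossing (default `TRUE`). The refined Tm is still the inflection
#'   of the curve - now of the fitted sigmoid rather than of the discrete
#'   derivatives - and on a coarse noisy grid it recovers most of the
#'   precision the two-point interpolation loses.
#' @param refine_window maximum distance (degrees C) the refined Tm may move
#'   from the derivative-based estimate before the refinement is discarded
#'   as having chased a different feature.
#' @return a list of class `tm_control`.
#' @export
tm_control <- function(smooth_window = 3, snr_min = 5, boundary_exclude = 2,
                       secondary_ratio = 0.5, monotone_min = 0.5,
                       refine = TRUE, refine_window = 6) {
  assert_that(smooth_window >= 1 && smooth_window %% 2 == 1,
              "smooth_window must be odd and >= 1")
  assert_that(boundary_exclude >= 0, "boundary_exclude must be >= 0")
  structure(list(smooth_window = smooth_window, snr_min = snr_min,
                 boundary_exclude = boundary_exclude,
                 secondary_ratio = secondary_ratio,
                 monotone_min = monotone_min,
                 refine = isTRUE(refine), refine_window = refine_window),
            class = "tm_control")
}

# Symmetric moving average with window shrinking near the edges; symmetric
# shrink keeps the smoother phase-free so Tm is not dragged toward the ends.
smooth_symmetric <- function(y, window) {
  if (window <= 1) return(y)
  half <- (window - 1) %/% 2
  n <- length(y)
  vapply(seq_len(n), function(i) {
    k <- min(half, i - 1, n - i)
    mean(y[(i - k):(i + k)])
  }, numeric(1))
}

# First derivative on a (possibly non-uniform) grid: central differences in
# the interior, one-sided at the ends.
grid_deriv <- function(t, y) {
  n <- length(y)
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (t[2] - t[1])
  d[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    d[i] <- (y[i + 1] - y[i - 1]) / (t[i + 1] - t[i - 1])
  }
  d
}

local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[v[i] > v[i - 1] & v[i] >= v[i + 1] & v[i] > 0]
}

# Shared analysis backing estimate_tm() and qc_curve(): smoothing,
# derivatives, QC decision and (when ok) the interpolated inflection.
melt_analysis <- function(curve, control) {
  t <- curve$temperature
  f <- curve$fluorescence
  n <- length(t)
  s <- smooth_symmetric(f, control$smooth_window)
  noise_sd <- stats::sd(f - s)
  amplitude <- max(s) - min(s)
  d1 <- grid_deriv(t, s)
  d2 <- grid_deriv(t, d1)

  status <- "ok"
  tm <- NA_real_

  # nonsigmoidal: signal indistinguishable from noise, or not predominantly
  # rising through the transition
  if (noise_sd > 0 && amplitude < control$snr_min * noise_sd) {
    status <- "nonsigmoidal"
  }
  tv <- sum(abs(diff(s)))
  if (status == "ok" && tv > 0 && (s[n] - s[1]) / tv < control$monotone_min) {
    status <- "nonsigmoidal"
  }

  # irregular: a secondary transition of comparable size, separated from the
  # main one by a genuine valley in the first derivative
  if (status == "ok") {
    peaks <- local_maxima(d1)
    if (length(peaks) >= 2) {
      ord <- order(d1[peaks], decreasing = TRUE)
      main <- peaks[ord[1]]
      for (p in peaks[ord[-1]]) {
        if (d1[p] >= control$secondary_ratio * d1[main]) {
          between <- seq(min(main, p), max(main, p))
          if (min(d1[between]) < 0.5 * d1[p]) {
            status <- "irregular"
            break
          }
        }
      }
    }
  }

  # A transition whose steepest rise sits at the very edge of the ramp is
  # not fully captured: its inflection cannot be located.
  be <- control$boundary_exclude
  if (status == "ok") {
    i_peak <- which.max(d1)
    if (i_peak <= be || i_peak > n - be) status <- "no_inflection"
  }

  # Tm: falling zero crossing of the second derivative (positive curvature
  # before the inflection, negative after) nearest the first-derivative
  # maximum, linearly interpolated between grid points.
  if (status == "ok") {
    i <- seq_len(n - 1)
    crossing <- i[d2[i] > 0 & d2[i + 1] <= 0]
    if (length(crossing)) {
      denom <- d2[crossing] - d2[crossing + 1]
      frac <- ifelse(denom > 0, d2[crossing] / denom, 0)
      tc <- t[crossing] + frac * (t[crossing + 1] - t[crossing])
      lo <- t[1 + be]
      hi <- t[n - be]
      tc <- tc[tc >= lo & tc <= hi]
      if (length(tc)) {
        t_peak <- t[which.max(d1)]
        tm <- tc[which.min(abs(tc - t_peak))]
        if (control$refine) {
          tm <- refine_tm(t, f, s, tm, control)
        }
      } else {
        status <- "no_inflection"
      }
    } else {
      status <- "no_inflection"
    }
  }

  list(tm = tm, qc_status = status, amplitude = amplitude,
       noise_sd = noise_sd, smoothed = s, d1 = d1, d2 = d2)
}

# Model-based refinement of the inflection: least-squares fit of a
# two-state sigmoid F(T) = b + A / (1 + exp(-(T - tm) / w)) to the raw
# trace, initialized at the derivative-based estimate. The fitted tm is the
# inflection of the fitted curve; the refinement is discarded if the fit
# fails, leaves the grid, or wanders more than refine_window away from its
# initialization (a sign it latched onto a different feature).
refine_tm <- function(t, f, s, tm0, control) {
  step <- stats::median(diff(t))
  dat <- data.frame(t = t, f = f)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      f ~ b + A / (1 + exp(-(t - tm) / w)),
      data = dat,
      start = list(b = min(s), A = max(s) - min(s), tm = tm0, w = step),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) return(tm0)
  co <- try(stats::coef(fit), silent = TRUE)
  if (inherits(co, "try-error")) return(tm0)
  tmf <- co[["tm"]]
  if (!is.finite(tmf) || co[["w"]] <= 0 ||
      abs(tmf - tm0) > control$refine_window ||
      tmf < min(t) || tmf > max(t)) {
    return(tm0)
  }
  tmf
}

#' Estimate the melting temperature of a melt curve
#'
#' The trace is lightly smoothed, discrete first and second derivatives are
#' taken on the temperature grid, and the inflection is located as the
#' linearly interpolated zero crossing of the second derivative nearest the
#' maximum of the first derivative (the rising inflection). By default this
#' estimate then seeds a local two-state Boltzmann least-squares fit of the
#' raw trace whose midpoint is reported as Tm (see [tm_control()]'s
#' `refine`); on the coarse assay grid the refinement roughly halves the
#' noise-induced error. Failures are never errors: they are
#' encoded in `qc_status` (see [qc_curve()] for the taxonomy), and `tm` is
#' present if and only if `qc_status == "ok"`. The estimate never
#' extrapolates beyond the measured grid.
#'
#' @param curve a [melt_curve()].
#' @param control a [tm_control()] configuration.
#' @return an object of class `tm_fit` with elements `tm` (degrees C or `NA`),
#'   `qc_status`, `amplitude`, and `diagnostics`.
#' @examples
#' fit <- estimate_tm(simulate_melt_curve(61))
#' fit$tm
#' @export
estimate_tm <- function(curve, control = tm_control()) {
  stopifnot(inherits(curve, "melt_curve"))
  res <- melt_analysis(curve, control)
  structure(
    list(compound_id = curve$compound_id,
         tm = res$tm,
         qc_status = res$qc_status,
         amplitude = res$amplitude,
         diagnostics = list(noise_sd = res$noise_sd,
                            d1_max = max(res$d1),
                            smooth_window = control$smooth_window)),
    class = "tm_fit"
  )
}

#' @export
print.tm_fit <- function(x, ...) {
  if (x$qc_status == "ok") {
    cat(sprintf("<tm_fit> %s: Tm = %.2f degC (qc ok, amplitude %.3g)\n",
                x$compound_id, x$tm, x$amplitude))
  } else {
    cat(sprintf("<tm_fit> %s: qc %s (no Tm)\n", x$compound_id, x$qc_status))
  }
  invisible(x)
}

#' Quality-control a melt curve
#'
#' Classifies a trace into one of four states: `"ok"`; `"nonsigmoidal"`
#' (amplitude below the noise floor, or the trace is not predominantly
#' monotone through the transition); `"irregular"` (more than one transition
#' of comparable amplitude); or `"no_inflection"` (no second-derivative zero
#' crossing, or the crossing sits within the excluded boundary points of the
#' ramp). Curves not rated `"ok"` yield no Tm and are excluded from the
#' valid-data universe downstream.
#'
#' @inheritParams estimate_tm
#' @return a character scalar QC status.
#' @export
qc_curve <- function(curve, control = tm_control()) {
  stopifnot(inherits(curve, "melt_curve"))
  melt_analysis(curve, control)$qc_status
}

#' Ligand-induced melting-temperature shift
#'
#' `delta_tm = sample Tm - reference Tm`, defined only when both fits passed
#' QC; otherwise the measurement is flagged invalid and the shift is absent.
#' A positive shift indicates stabilization of the folded RNA by the
#' compound.
#'
#' @param sample a `tm_fit` for the compound-containing well.
#' @param reference a `tm_fit` for the matched compound-free control.
#' @param motif_id identifier of the RNA motif probed.
#' @return a list of class `delta_tm` with `compound_id`, `motif_id`,
#'   `delta_tm` (degrees C or `NA`) and `valid`.
#' @export
delta_tm <- function(sample, reference, motif_id = NA) {
  stopifnot(inherits(sample, "tm_fit"), inherits(reference, "tm_fit"))
  ok <- sample$qc_status == "ok" && reference$qc_status == "ok"
  structure(
    list(compound_id = sample$compound_id,
         motif_id = motif_id,
         delta_tm = if (ok) sample$tm - reference$tm else NA_real_,
         valid = ok),
    class = "delta_tm"
  )
}

#' Call a compound active from its Tm shift
#'
#' A compound is active against a motif when its delta-Tm strictly exceeds
#' the threshold (default 1 degree C); a shift of exactly the threshold is
#' inactive. Missing shifts are invalid measurements and signal an error
#' rather than silently returning a label.
#'
#' @param delta_tm numeric vector of Tm shifts (degrees C).
#' @param threshold activity cutoff (degrees C), strict inequality.
#' @return logical vector of active flags.
#' @examples
#' classify_active(c(0.8, 2.6, 1.0))  # FALSE TRUE FALSE
#' @export
classify_active <- function(delta_tm, threshold = 1) {
  if (inherits(delta_tm, "delta_tm")) delta_tm <- delta_tm$delta_tm
  if (any(!is.finite(delta_tm))) {
    stop_iterscreen("iterscreen_invalid_measurement",
                    "delta_tm contains missing values: invalid measurement")
  }
  delta_tm > threshold
}
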