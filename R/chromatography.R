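#' Specify synthetic chromatographic peaks
#'
#' A peak is modelled as an exponentially modified Gaussian (EMG): a
#' Gaussian of width `sigma` convolved with an exponential decay of
#' time constant `tau`.  `tau = 0` gives the symmetric Gaussian limit;
#' growing `tau` produces the peak tailing that method development
#' works to suppress.
#'
#' @param analyte character vector of peak names.
#' @param rt_min retention times in minutes (positive).
#' @param area peak areas in detector-units x minutes.
#' @param sigma_min Gaussian sigma in minutes (positive).
#' @param tau_min exponential tailing constant in minutes (>= 0).
#' @return A data frame of class `peak_spec`.
#' @examples
#' peak_spec("x", 5, area = 10, sigma_min = 0.05, tau_min = 0.02)
#' @export
peak_spec <- function(analyte, rt_min, area = 1, sigma_min = 0.03,
                      tau_min = 0) {
  n <- length(rt_min)
  out <- data.frame(analyte = rep_len(as.character(analyte), n),
                    rt_min = rt_min,
                    area = rep_len(area, n),
                    sigma_min = rep_len(sigma_min, n),
                    tau_min = rep_len(tau_min, n),
                    stringsAsFactors = FALSE)
  if (any(out$rt_min <= 0)) stop_aqbd("retention times must be positive")
  if (any(out$sigma_min <= 0)) stop_aqbd("sigma must be positive")
  if (any(out$tau_min < 0)) stop_aqbd("tau must be non-negative")
  class(out) <- c("peak_spec", "data.frame")
  out
}

# scaled complementary error function erfcx(z) = exp(z^2) erfc(z) for
# z >= 0; direct form up to z = 15, then the asymptotic expansion
# 1/(z sqrt(pi)) (1 - 1/(2 z^2) + 3/(4 z^4)) (relative error < 1e-7)
erfcx_pos <- function(z) {
  out <- numeric(length(z))
  small <- z <= 15
  out[small] <- exp(z[small]^2) * 2 * pnorm(-z[small] * sqrt(2))
  zb <- z[!small]
  out[!small] <- (1 - 0.5 / zb^2 + 0.75 / zb^4) / (zb * sqrt(pi))
  out
}

# EMG profile evaluated stably via the scaled complementary error
# function: f(t) = A/(2 tau) * erfcx(z) * exp(-u^2 / (2 sigma^2)),
# z = (sigma/tau - u/sigma)/sqrt(2), u = t - rt.  tau = 0 -> Gaussian.
emg_profile <- function(t, rt, area, sigma, tau) {
  u <- t - rt
  if (tau <= 0)
    return(area / (sigma * sqrt(2 * pi)) * exp(-u^2 / (2 * sigma^2)))
  z <- (sigma / tau - u / sigma) / sqrt(2)
  out <- numeric(length(u))
  pos <- z >= 0
  # leading edge: scaled erfcx form avoids overflow of exp(z^2)
  out[pos] <- area / (2 * tau) * erfcx_pos(z[pos]) *
    exp(-u[pos]^2 / (2 * sigma^2))
  # tailing edge (z < 0 implies the direct exponent is negative)
  out[!pos] <- area / (2 * tau) *
    exp(sigma^2 / (2 * tau^2) - u[!pos] / tau) *
    2 * pnorm(-z[!pos] * sqrt(2))
  out
}

#' Simulate a detector trace from a peak table
#'
#' Sums EMG profiles for every peak over a uniform time grid and adds
#' an optional linear baseline drift and white Gaussian detector
#' noise.
#'
#' @param peaks a [peak_spec()] table.
#' @param duration_min trace length in minutes.
#' @param sampling_s sampling interval in seconds (default 0.3 s).
#' @param noise_sd standard deviation of the additive Gaussian noise
#'   in detector units (0 for a noiseless trace).
#' @param drift total linear baseline rise over the trace in detector
#'   units (default 0).
#' @param seed integer seed for the noise realisation.
#' @return A data frame of class `chromatogram` with columns
#'   `time_min` and `intensity`; the generation parameters are stored
#'   as attributes (`sampling_s`, `noise_sd`, `drift`, `seed`).
#' @examples
#' pk <- peak_spec(c("a", "b"), c(2, 3), area = c(5, 5))
#' ch <- simulate_chromatogram(pk, duration_min = 5, noise_sd = 0)
#' @export
simulate_chromatogram <- function(peaks, duration_min, sampling_s = 0.3,
                                  noise_sd = 0, drift = 0, seed = NULL) {
  if (any(peaks$rt_min > duration_min))
    stop_aqbd("all peaks must elute within the trace duration")
  dt <- sampling_s / 60
  t <- seq(0, duration_min, by = dt)
  y <- numeric(length(t))
  for (i in seq_len(nrow(peaks)))
    y <- y + emg_profile(t, peaks$rt_min[i], peaks$area[i],
                         peaks$sigma_min[i], peaks$tau_min[i])
  y <- y + drift * t / duration_min
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + rnorm(length(t), 0, noise_sd)
  }
  out <- data.frame(time_min = t, intensity = y)
  attr(out, "sampling_s") <- sampling_s
  attr(out, "noise_sd") <- noise_sd
  attr(out, "drift") <- drift
  attr(out, "seed") <- seed
  class(out) <- c("chromatogram", "data.frame")
  out
}

# interpolated time at which the trace crosses `level`, walking from
# the apex index in direction dir (+1 right, -1 left); NA if the trace
# never drops below the level before the record ends
cross_time <- function(t, y, apex_i, level, dir) {
  i <- apex_i
  n <- length(y)
  while (i + dir >= 1 && i + dir <= n) {
    j <- i + dir
    if (y[j] <= level) {
      frac <- (y[i] - level) / (y[i] - y[j])
      return(t[i] + frac * (t[j] - t[i]))
    }
    i <- j
  }
  NA_real_
}

#' Measure peaks on a chromatogram
#'
#' Detects peaks as local maxima above a detection threshold, refines
#' each apex with a parabolic fit through the three samples around the
#' maximum, and measures widths by linear interpolation of the level
#' crossings at 50% and 5% of the baseline-corrected height.  The
#' tailing factor is the pharmacopoeial `T = W0.05 / (2 f)`, with `f`
#' the front half-width at 5% height.
#'
#' Baseline correction (`baseline = "linear"`) fits a straight line
#' through the low-intensity portion of the trace (lowest quartile),
#' which removes the linear drift the simulator can add; `"none"`
#' assumes a zero baseline.
#'
#' @param chrom a [simulate_chromatogram()] result (or any data frame
#'   with `time_min` and `intensity`).
#' @param min_height detection threshold in detector units; default is
#'   2% of the largest baseline-corrected intensity.
#' @param baseline `"linear"` (default) or `"none"`.
#' @return A data frame with one row per detected peak: `apex_time`,
#'   `height`, `width_half`, `width_5`, `front_half_width_5`,
#'   `tailing`; empty when nothing exceeds the threshold.
#' @examples
#' ch <- simulate_chromatogram(peak_spec("a", 2, area = 5),
#'                             duration_min = 4)
#' measure_peaks(ch)
#' @export
measure_peaks <- function(chrom, min_height = NULL,
                          baseline = c("linear", "none")) {
  baseline <- match.arg(baseline)
  t <- chrom$time_min; y <- chrom$intensity
  if (baseline == "linear") {
    low <- y <= stats::quantile(y, 0.25)
    bl <- lm(y[low] ~ t[low])
    y <- y - (coef(bl)[1] + coef(bl)[2] * t)
  }
  if (is.null(min_height)) min_height <- 0.02 * max(y)
  n <- length(y)
  apex <- which(y > min_height &
                  y >= c(-Inf, y[-n]) & y >= c(y[-1], -Inf))
  # collapse plateaus / adjacent ties to a single apex
  if (length(apex) > 1)
    apex <- apex[c(TRUE, diff(apex) > 2)]
  if (!length(apex))
    return(data.frame(apex_time = numeric(0), height = numeric(0),
                      width_half = numeric(0), width_5 = numeric(0),
                      front_half_width_5 = numeric(0),
                      tailing = numeric(0)))
  rows <- lapply(apex, function(i) {
    # parabolic apex refinement
    if (i > 1 && i < n) {
      y1 <- y[i - 1]; y2 <- y[i]; y3 <- y[i + 1]
      den <- y1 - 2 * y2 + y3
      delta <- if (den < 0) 0.5 * (y1 - y3) / den else 0
      delta <- max(min(delta, 0.5), -0.5)
      apex_time <- t[i] + delta * (t[2] - t[1])
      height <- y2 - 0.25 * (y1 - y3) * delta
    } else {
      apex_time <- t[i]; height <- y[i]
    }
    w_at <- function(frac) {
      lev <- frac * height
      left <- cross_time(t, y, i, lev, -1L)
      right <- cross_time(t, y, i, lev, +1L)
      c(left = left, right = right)
    }
    w50 <- w_at(0.5); w05 <- w_at(0.05)
    width_half <- unname(w50["right"] - w50["left"])
    width_5 <- unname(w05["right"] - w05["left"])
    front <- unname(apex_time - w05["left"])
    data.frame(apex_time = apex_time, height = height,
               width_half = width_half, width_5 = width_5,
               front_half_width_5 = front,
               tailing = width_5 / (2 * front))
  })
  do.call(rbind, rows)
}

#' Resolution between two chromatographic peaks
#'
#' Half-height form: `Rs = 1.18 (t2 - t1) / (w0.5,1 + w0.5,2)`.
#' Baseline form: `Rs = 2 (t2 - t1) / (wb,1 + wb,2)` with the tangent
#' base width taken as `1.699 * w0.5` (exact for Gaussian peaks) when
#' only half-height widths were measured.
#'
#' @param peak1,peak2 single rows of a [measure_peaks()] table (or any
#'   list with `apex_time` and `width_half`), with
#'   `peak1$apex_time <= peak2$apex_time`.
#' @param formula `"half_height"` (default) or `"baseline"`.
#' @return The resolution (0 for coincident apexes).
#' @examples
#' p1 <- list(apex_time = 10, width_half = 0.2)
#' p2 <- list(apex_time = 11, width_half = 0.2)
#' resolution(p1, p2)  # 2.95
#' @export
resolution <- function(peak1, peak2, formula = c("half_height", "baseline")) {
  formula <- match.arg(formula)
  dt <- peak2$apex_time - peak1$apex_time
  if (dt < 0) stop_aqbd("peak1 must elute before peak2")
  if (dt == 0) return(0)
  if (formula == "half_height") {
    1.18 * dt / (peak1$width_half + peak2$width_half)
  } else {
    2 * dt / (1.699 * (peak1$width_half + peak2$width_half))
  }
}

#' @rdname resolution
#' @param peaks a [measure_peaks()] table ordered by apex time.
#' @return `peak_resolutions()`: a vector of adjacent-pair resolutions
#'   (length `nrow(peaks) - 1`).
#' @export
peak_resolutions <- function(peaks, formula = c("half_height", "baseline")) {
  formula <- match.arg(formula)
  if (nrow(peaks) < 2) return(numeric(0))
  vapply(seq_len(nrow(peaks) - 1), function(i) {
    resolution(peaks[i, ], peaks[i + 1, ], formula)
  }, numeric(1))
}

#' Simulate DoE response tables from ground-truth models
#'
#' Evaluates ground-truth response models at every design run (on the
#' natural, back-transformed scale) and adds independent Gaussian
#' measurement noise — the stand-in for running the instrument at each
#' DoE condition.
#'
#' @param models named list of [response_model()]s (the ground truth).
#' @param design coded design data frame (one column per factor; other
#'   columns are carried through).
#' @param noise_sd measurement noise standard deviation: a single
#'   number or a named vector per response.
#' @param seed integer seed.
#' @return A data frame with `run_id` and one response column per
#'   model.
#' @examples
#' fs <- cabotegravir_factor_space()
#' g <- candidate_grid(fs)
#' simulate_doe_responses(cabotegravir_models(), g, noise_sd = 0.05,
#'                        seed = 1)[1:3, ]
#' @export
simulate_doe_responses <- function(models, design, noise_sd = 0,
                                   seed = NULL) {
  design <- as.data.frame(design)
  if (!is.null(seed)) set.seed(seed)
  sds <- if (length(noise_sd) == 1 && is.null(names(noise_sd)))
    setNames(rep(noise_sd, length(models)), names(models))
  else noise_sd
  out <- data.frame(run_id = design$run_id %||% seq_len(nrow(design)))
  for (mname in names(models)) {
    mu <- evaluate_model(models[[mname]], design)
    s <- sds[[mname]] %||% 0
    out[[mname]] <- mu + if (s > 0) rnorm(length(mu), 0, s) else 0
  }
  out
}

#' Illustrative ten-peak cabotegravir separation scenario
#'
#' A synthetic peak table emulating the working-point separation of
#' the cabotegravir impurity method: the four degradation products,
#' the four related substances, the parent drug and one unknown
#' impurity, in the elution order DP1, DP2, DP3, dFCBG, 2CBG, 4CBG,
#' cabotegravir, DP4, unknown, HICBG.  Retention times, areas and peak
#' widths are free inventions chosen to look like a 16-minute
#' gradient separation (they are not measured values); the
#' unknown-impurity peak is placed close enough to DP4 that their
#' resolution falls below 2.0, so a resolution census over the
#' scenario exercises both outcomes.
#'
#' @return A [peak_spec()] table with 10 rows.
#' @examples
#' cabotegravir_demo_peaks()
#' @export
cabotegravir_demo_peaks <- function() {
  peak_spec(
    analyte = c("DP1", "DP2", "DP3", "dFCBG", "2CBG", "4CBG",
                "cabotegravir", "DP4", "unknown", "HICBG"),
    rt_min = c(3.2, 4.1, 5.0, 6.3, 7.2, 8.0, 8.9, 10.2, 10.42, 12.1),
    area = c(1.2, 1.0, 1.1, 0.9, 1.0, 1.0, 50, 0.8, 0.5, 0.9),
    sigma_min = c(0.028, 0.030, 0.030, 0.032, 0.030, 0.030, 0.034,
                  0.032, 0.030, 0.036),
    tau_min = c(0, 0, 0, 0, 0, 0, 0.012, 0, 0, 0))
}
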