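#' Acceptance criteria for method validation
#'
#' Bundles the pass/fail thresholds of an ICH-style impurity-method
#' validation: spike recovery window, repeatability limit,
#' signal-to-noise minima for detection and quantification limits, and
#' the minimum Pearson correlation for linearity.
#'
#' @param recovery_low,recovery_high accepted recovery window in
#'   percent (default 70-130%).
#' @param rsd_max maximum relative standard deviation in percent.
#' @param snr_lod_min minimum S/N at the detection limit (3:1).
#' @param snr_loq_min minimum S/N at the quantification limit (10:1).
#' @param pearson_min minimum Pearson r for linearity.
#' @return A list of class `validation_criteria`.
#' @export
validation_criteria <- function(recovery_low = 70, recovery_high = 130,
                                rsd_max = 10, snr_lod_min = 3,
                                snr_loq_min = 10, pearson_min = 0.998) {
  if (recovery_low >= recovery_high)
    stop_aqbd("recovery window must have low < high")
  structure(list(recovery_low = recovery_low,
                 recovery_high = recovery_high,
                 rsd_max = rsd_max, snr_lod_min = snr_lod_min,
                 snr_loq_min = snr_loq_min, pearson_min = pearson_min),
            class = "validation_criteria")
}

#' Spike recovery in percent
#'
#' `100 * found / added`, reported to two decimals (ties away from
#' zero), the standard expression of accuracy for spiked impurity
#' samples.
#'
#' @param added,found spiked and measured amounts (same units, e.g.
#'   ug/mL); `added` must be positive.
#' @param digits decimals reported (default 2; `NULL` for full
#'   precision).
#' @return Recovery percentage(s).
#' @examples
#' recovery_percent(0.3785, 0.2966)  # 78.37
#' @export
recovery_percent <- function(added, found, digits = 2) {
  if (any(added <= 0)) stop_aqbd("added amount must be positive")
  r <- 100 * found / added
  if (is.null(digits)) r else round_half_away(r, digits)
}

#' Relative standard deviation in percent
#'
#' `100 * sd(x) / mean(x)` with the usual n-1 sample standard
#' deviation; the repeatability measure of replicate determinations.
#'
#' @param values numeric vector of at least two replicate values with
#'   non-zero mean.
#' @return RSD percentage.
#' @examples
#' rsd_percent(c(1, 2, 3))  # 50
#' @export
rsd_percent <- function(values) {
  if (length(values) < 2) stop_aqbd("need at least two replicate values")
  m <- mean(values)
  if (m == 0) stop_aqbd("mean of replicate values is zero")
  100 * sd(values) / m
}

#' Detector response factor of an impurity
#'
#' The ratio of an impurity's calibration slope to the parent
#' compound's slope, used to correct area-based impurity
#' quantification; reported at two decimals.
#'
#' @param slope_analyte,slope_reference calibration slopes (detector
#'   response per concentration unit).
#' @param digits decimals reported (default 2; `NULL` for full
#'   precision).
#' @return The response factor.
#' @examples
#' response_factor(8303, 24927)  # 0.33
#' @export
response_factor <- function(slope_analyte, slope_reference, digits = 2) {
  if (any(slope_reference == 0)) stop_aqbd("reference slope must be non-zero")
  f <- slope_analyte / slope_reference
  if (is.null(digits)) f else round_half_away(f, digits)
}

#' Calibration line and Pearson correlation
#'
#' Ordinary least-squares line of detector area on concentration, with
#' the Pearson correlation coefficient of the pairs (the linearity
#' criterion of the validation, r >= 0.998).
#'
#' @param concentration,area paired numeric vectors; at least three
#'   distinct concentrations.
#' @return A list with `slope`, `intercept`, `r` (full precision) and
#'   `r3` (r rounded to three decimals, as reported).
#' @examples
#' fit_linearity(1:5, 2 * (1:5) + 1)
#' @export
fit_linearity <- function(concentration, area) {
  if (length(concentration) != length(area))
    stop_aqbd("concentration and area must pair up")
  if (length(unique(concentration)) < 3)
    stop_aqbd("need at least three distinct concentrations")
  fit <- lm(area ~ concentration)
  r <- cor(concentration, area)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = r, r3 = round_half_away(r, 3))
}

#' Signal-to-noise ratio of a chromatographic peak
#'
#' European-Pharmacopoeia style S/N = 2H / h, where H is the
#' baseline-corrected peak height inside the peak window (baseline
#' taken as the mean of the noise window) and h is the peak-to-peak
#' noise amplitude in a peak-free baseline window.  With
#' `method = "sd"` the plain H / sd(noise) form is used instead.
#'
#' @param chrom a chromatogram data frame with columns `time_min` and
#'   `intensity` (see [simulate_chromatogram()]).
#' @param peak_window,noise_window numeric `c(start, end)` windows in
#'   minutes; they must not overlap and the noise window must contain
#'   baseline only.
#' @param method `"ep"` (2H/h, default) or `"sd"` (H / sd of noise).
#' @param cap value returned when the noise amplitude is zero but a
#'   peak is present (a noiseless synthetic trace).
#' @return The signal-to-noise ratio (0 when no signal rises above the
#'   baseline).
#' @export
snr <- function(chrom, peak_window, noise_window, method = c("ep", "sd"),
                cap = 999) {
  method <- match.arg(method)
  if (max(peak_window[1], noise_window[1]) <
      min(peak_window[2], noise_window[2]))
    stop_aqbd("peak and noise windows must not overlap")
  t <- chrom$time_min; y <- chrom$intensity
  in_peak <- t >= peak_window[1] & t <= peak_window[2]
  in_noise <- t >= noise_window[1] & t <= noise_window[2]
  if (!any(in_peak) || sum(in_noise) < 2)
    stop_aqbd("windows select too few samples")
  baseline <- mean(y[in_noise])
  H <- max(y[in_peak]) - baseline
  if (H <= 0) return(0)
  if (method == "ep") {
    h <- diff(range(y[in_noise]))
    if (h == 0) return(cap)
    2 * H / h
  } else {
    s <- sd(y[in_noise])
    if (s == 0) return(cap)
    H / s
  }
}

#' Packaged validation tables of the cabotegravir method
#'
#' Returns the method-validation result tables shipped with the
#' package as plain CSV: spike accuracy/repeatability (`accuracy`),
#' detection-limit S/N (`lod`), quantification-limit S/N and area RSD
#' (`loq`), response factors (`response_factors`), and calibration
#' lines (`linearity`).
#'
#' @return A named list of data frames.
#' @examples
#' names(validation_tables())
#' @export
validation_tables <- function() {
  dir <- system.file("extdata", "validation", package = "aqbd")
  read1 <- function(f) read.csv(file.path(dir, f), stringsAsFactors = FALSE,
                                check.names = FALSE)
  list(accuracy = read1("accuracy_spikes.csv"),
       lod = read1("detection_limit.csv"),
       loq = read1("quantification_limit.csv"),
       response_factors = read1("response_factors.csv"),
       linearity = read1("linearity.csv"))
}

#' Pass/fail screening of validation results
#'
#' Applies the [validation_criteria()] to validation tables in the
#' packaged layout (see [validation_tables()]): accuracy rows pass when
#' recovery lies in the window and RSD is below the limit; LOD rows
#' when S/N meets the 3:1 minimum; LOQ rows when S/N meets the 10:1
#' minimum and the area RSD stays within the limit; linearity rows
#' when Pearson r meets the minimum.
#'
#' @param tables a list with any of `accuracy`, `lod`, `loq`,
#'   `linearity` in the [validation_tables()] column layout.
#' @param criteria a [validation_criteria()].
#' @return A list of data frames, each with the identifying columns
#'   and a logical `pass`, plus `all_pass`, a single logical.
#' @examples
#' rep <- check_limits(validation_tables())
#' rep$all_pass
#' @export
check_limits <- function(tables, criteria = validation_criteria()) {
  out <- list()
  if (!is.null(tables$accuracy)) {
    a <- tables$accuracy
    out$accuracy <- data.frame(
      impurity = a$impurity, level_pct = a$level_pct,
      recovery_pct = a$recovery_pct, rsd_pct = a$rsd_pct,
      pass = a$recovery_pct >= criteria$recovery_low &
        a$recovery_pct <= criteria$recovery_high &
        a$rsd_pct <= criteria$rsd_max)
  }
  if (!is.null(tables$lod)) {
    out$lod <- data.frame(analyte = tables$lod$analyte,
                          snr = tables$lod$snr,
                          pass = tables$lod$snr >= criteria$snr_lod_min)
  }
  if (!is.null(tables$loq)) {
    q <- tables$loq
    out$loq <- data.frame(analyte = q$analyte, snr = q$snr,
                          rsd_area_pct = q$rsd_area_pct,
                          pass = q$snr >= criteria$snr_loq_min &
                            q$rsd_area_pct <= criteria$rsd_max)
  }
  if (!is.null(tables$linearity)) {
    l <- tables$linearity
    out$linearity <- data.frame(analyte = l$analyte, pearson_r = l$pearson_r,
                                pass = l$pearson_r >= criteria$pearson_min)
  }
  out$all_pass <- all(vapply(out, function(d) all(d$pass), logical(1)))
  out
}
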