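#' @importFrom stats median mad setNames
NULL

#' Chromatogram container
#'
#' A total ion chromatogram (TIC): summed ion intensity on a strictly
#' increasing retention-time grid.
#'
#' @param rt Retention times (minutes), strictly increasing.
#' @param intensity Detector intensities, same length, finite.
#' @param sample_id Sample label.
#' @return Object of class `chromatogram` (a data.frame with attributes).
#' @export
chromatogram <- function(rt, intensity, sample_id = NA_character_) {
  rt <- as.numeric(rt); intensity <- as.numeric(intensity)
  if (length(rt) != length(intensity))
    stop("rt and intensity must have equal length")
  if (length(rt) > 1 && any(diff(rt) <= 0))
    stop("rt must be strictly increasing")
  if (any(!is.finite(intensity)))
    stop("intensities must be finite")
  structure(data.frame(rt = rt, intensity = intensity),
            sample_id = sample_id,
            class = c("chromatogram", "data.frame"))
}

# running minimum / maximum over a centred window of k points
run_extreme <- function(x, k, fun) {
  n <- length(x)
  k <- min(k, n)
  half <- k %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    fun(x[lo:min(n, lo + k - 1L)])
  }, numeric(1))
}

# morphological opening (erosion then dilation): a baseline that follows
# broad humps but drops under narrow resolved peaks
opening_baseline <- function(intensity, k) {
  run_extreme(run_extreme(intensity, k, min), k, max)
}

# The opening of a noisy trace is negatively biased: the erosion tracks the
# lower envelope of the noise. Estimate that bias by applying the identical
# smooth+opening pipeline to matched synthetic white noise, and subtract it.
# Uses its own RNG stream; the caller's RNG state is untouched.
opening_noise_bias <- function(n, sigma_raw, k_smooth, k_open,
                               replicates = 2L) {
  if (sigma_raw <= 0 || n < k_open) return(0)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(285713L)
  mean(vapply(seq_len(replicates), function(r) {
    z <- smooth_trace(stats::rnorm(n, 0, sigma_raw), k_smooth)
    mean(opening_baseline(z, k_open))
  }, numeric(1)))
}

# centred moving average with edge padding; width forced odd
smooth_trace <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k == 1L || length(x) < k) return(x)
  half <- k %/% 2L
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2))[
    (half + 1L):(half + length(x))]
}

window_points <- function(rt, window_minutes) {
  step <- median(diff(rt))
  max(3L, as.integer(round(window_minutes / step)))
}

#' Unresolved complex mixture (UCM) index of a chromatogram
#'
#' Degraded oils show a broad "hump" of co-eluting compounds under the
#' resolved peaks. The index is the fraction of total trace area carried by
#' the unresolved component, where the unresolved component is a
#' morphological-opening envelope (running minimum then running maximum,
#' window `baseline_window`) of the lightly smoothed trace. A window much
#' wider than a resolved peak but much narrower than the hump separates the
#' two. Result is clipped to [0, 1]; an all-zero trace returns 0.
#'
#' @param chrom A [chromatogram()].
#' @param baseline_window Envelope window (minutes). Must exceed the width of
#'   resolved peaks.
#' @param smooth_window Pre-smoothing window (minutes) applied before the
#'   envelope; damps detector noise.
#' @return UCM index in [0, 1].
#' @export
compute_ucm_index <- function(chrom, baseline_window = 1.5,
                              smooth_window = 0.14) {
  stopifnot(baseline_window > 0)
  ksm <- window_points(chrom$rt, smooth_window)
  x <- smooth_trace(chrom$intensity, ksm)
  k <- window_points(chrom$rt, baseline_window)
  bias <- opening_noise_bias(length(x),
                             mad(diff(chrom$intensity)) / sqrt(2),
                             ksm, k)
  base <- pmax(opening_baseline(x, k) - bias, 0)
  total <- pracma::trapz(chrom$rt, pmax(x, 0))
  if (total <= 0) return(0)
  min(max(pracma::trapz(chrom$rt, base) / total, 0), 1)
}

#' Detect resolved peaks in a chromatogram
#'
#' The trace is smoothed, a morphological-opening baseline is subtracted, and
#' local maxima of the corrected trace are kept if they exceed both
#' `min_snr` times the estimated noise level and `min_prominence_fraction`
#' of the tallest corrected excursion. Peak areas are integrated between the
#' flanking minima. Heights are baseline-corrected, so diagnostic ratios are
#' insensitive to the UCM hump underneath.
#'
#' @param chrom A [chromatogram()].
#' @param min_snr Minimum peak height in units of the (smoothed-trace) noise
#'   standard deviation, estimated from first differences of the raw trace.
#' @param min_prominence_fraction Minimum height as a fraction of the tallest
#'   corrected peak.
#' @param baseline_window,smooth_window Passed to the baseline step; see
#'   [compute_ucm_index()].
#' @return data.frame with columns `apex_rt`, `height`, `area`,
#'   `assignment` (initialised `"unassigned"`). Empty for a flat trace.
#' @export
detect_peaks <- function(chrom, min_snr = 5, min_prominence_fraction = 0.02,
                         baseline_window = 1.5, smooth_window = 0.14) {
  stopifnot(min_snr > 0, min_prominence_fraction > 0)
  empty <- data.frame(apex_rt = numeric(0), height = numeric(0),
                      area = numeric(0), assignment = character(0))
  if (nrow(chrom) < 5L) return(empty)
  ksm <- window_points(chrom$rt, smooth_window)
  x <- smooth_trace(chrom$intensity, ksm)
  kb <- window_points(chrom$rt, baseline_window)
  # raw-trace noise, propagated through the boxcar smoother
  noise_raw <- mad(diff(chrom$intensity)) / sqrt(2)
  noise <- noise_raw / sqrt(ksm)
  bias <- opening_noise_bias(length(x), noise_raw, ksm, kb)
  corrected <- x - (opening_baseline(x, kb) - bias)
  if (max(corrected) <= 0) return(empty)
  floor_h <- max(min_snr * noise, min_prominence_fraction * max(corrected))

  pk <- pracma::findpeaks(corrected, minpeakheight = floor_h,
                          minpeakdistance = max(2L, ksm))
  if (is.null(pk)) return(empty)
  pk <- matrix(pk, ncol = 4)
  data.frame(
    apex_rt = chrom$rt[pk[, 2]],
    height = pk[, 1],
    area = vapply(seq_len(nrow(pk)), function(i) {
      sel <- pk[i, 3]:pk[i, 4]
      pracma::trapz(chrom$rt[sel], pmax(corrected[sel], 0))
    }, numeric(1)),
    assignment = "unassigned",
    stringsAsFactors = FALSE)
}

#' Default retention-time calibration for the n-alkane / isoprenoid series
#'
#' Linear carbon-number-to-retention-time mapping for nC10-nC35, with
#' pristane (Pr) eluting just after nC17 and phytane (Ph) just after nC18,
#' mirroring their standard elution order on apolar GC columns.
#'
#' @param carbon_range Integer pair, alkane carbon range.
#' @param rt_per_carbon Minutes per carbon number.
#' @param rt_intercept Minutes at carbon 0.
#' @param isoprenoid_offset Minutes by which Pr (Ph) trails nC17 (nC18).
#' @return data.frame with columns `identity`, `carbon`, `rt`.
#' @export
alkane_calibration <- function(carbon_range = c(10L, 35L),
                               rt_per_carbon = 1.2,
                               rt_intercept = -8,
                               isoprenoid_offset = 0.4) {
  stopifnot(length(carbon_range) == 2, rt_per_carbon > 0,
            isoprenoid_offset > 0, isoprenoid_offset < rt_per_carbon / 2)
  if (carbon_range[1] <= 4L || carbon_range[2] >= 40L ||
      carbon_range[1] >= carbon_range[2])
    stop("alkane carbon range must lie within (4, 40)")
  carbons <- carbon_range[1]:carbon_range[2]
  rt_n <- rt_intercept + rt_per_carbon * carbons
  out <- data.frame(
    identity = c(paste0("nC", carbons), "Pr", "Ph"),
    carbon = c(carbons, NA, NA),
    rt = c(rt_n,
           rt_intercept + rt_per_carbon * 17 + isoprenoid_offset,
           rt_intercept + rt_per_carbon * 18 + isoprenoid_offset),
    stringsAsFactors = FALSE)
  out[order(out$rt), ]
}

#' Assign detected peaks to the calibrated alkane / isoprenoid series
#'
#' Each peak takes the identity of the nearest calibrated retention time
#' within `rt_tolerance`; when several peaks claim one identity the tallest
#' wins and the rest stay unassigned. Diagnostic ratios nC17/Pr and nC18/Ph
#' are computed from baseline-corrected peak heights and are `NA` when either
#' member is missing.
#'
#' @param peaks data.frame from [detect_peaks()].
#' @param calibration data.frame from [alkane_calibration()]; `rt` must be
#'   monotone in carbon number over the nC entries.
#' @param rt_tolerance Assignment tolerance (minutes).
#' @return Object of class `alkane_profile`: list with `peaks` (assigned),
#'   `c17_pr_ratio`, `c18_ph_ratio`, `n_alkanes_present`,
#'   `pr_ph_dominance`.
#' @export
assign_series <- function(peaks, calibration = alkane_calibration(),
                          rt_tolerance = 0.2) {
  stopifnot(rt_tolerance > 0)
  ncal <- calibration[grepl("^nC", calibration$identity), ]
  if (is.unsorted(ncal$rt[order(ncal$carbon)], strictly = TRUE))
    stop("calibration must be strictly monotone in carbon number")

  if (nrow(peaks) > 0) {
    idx <- vapply(peaks$apex_rt, function(rt) {
      d <- abs(calibration$rt - rt)
      j <- which.min(d)
      if (d[j] <= rt_tolerance) j else NA_integer_
    }, integer(1))
    peaks$assignment <- ifelse(is.na(idx), "unassigned",
                               calibration$identity[idx])
    # one peak per identity: tallest claims it
    for (id in unique(peaks$assignment[peaks$assignment != "unassigned"])) {
      claimants <- which(peaks$assignment == id)
      if (length(claimants) > 1) {
        lose <- claimants[-which.max(peaks$height[claimants])]
        peaks$assignment[lose] <- "unassigned"
      }
    }
  }

  h <- function(id) {
    hit <- peaks$height[peaks$assignment == id]
    if (length(hit) == 1) hit else NA_real_
  }
  ratio <- function(a, b) {
    ha <- h(a); hb <- h(b)
    if (is.na(ha) || is.na(hb)) NA_real_ else ha / hb
  }
  is_alkane <- grepl("^nC", peaks$assignment)
  other <- peaks$height[is_alkane &
                          !peaks$assignment %in% c("nC17", "nC18")]
  other <- c(other, h("nC17"), h("nC18"))
  other <- other[!is.na(other)]
  pr_ph <- sum(c(h("Pr"), h("Ph")), na.rm = TRUE)
  dominance <- if (length(other) == 0) {
    if (pr_ph > 0) Inf else NA_real_
  } else pr_ph / median(other)

  structure(
    list(peaks = peaks,
         c17_pr_ratio = ratio("nC17", "Pr"),
         c18_ph_ratio = ratio("nC18", "Ph"),
         n_alkanes_present = sum(is_alkane),
         pr_ph_dominance = dominance),
    class = "alkane_profile")
}

#' Default thresholds for degradation scoring
#'
#' The field descriptions "slight" and "significant" UCM, "significantly
#' higher" Pr/Ph, and the moderate-degradation split are qualitative; these
#' fixed conventions make the rule set a total function. All are exposed so
#' a user can restate them.
#'
#' @param ucm_slight UCM index at or above which a UCM counts as slight.
#' @param ucm_significant UCM index at or above which a UCM counts as
#'   significant.
#' @param dominance_threshold Minimum (Pr+Ph) height over the median other
#'   n-alkane height for Pr/Ph to count as dominant.
#' @param residual_count_threshold Maximum surviving non-Pr/Ph alkane count
#'   for moderate degradation to score 3 rather than 2.
#' @return Named list of thresholds.
#' @export
scoring_thresholds <- function(ucm_slight = 0.10, ucm_significant = 0.35,
                               dominance_threshold = 2.0,
                               residual_count_threshold = 5L) {
  stopifnot(ucm_slight > 0, ucm_significant > ucm_slight,
            dominance_threshold > 0, residual_count_threshold >= 0)
  list(ucm_slight = ucm_slight, ucm_significant = ucm_significant,
       dominance_threshold = dominance_threshold,
       residual_count_threshold = as.integer(residual_count_threshold))
}

#' Score crude-oil biodegradation degree (0-4) from diagnostics
#'
#' Applies the 0-4 biodegradation rule set, evaluated 4 -> 0 with first
#' match: (4) no n-alkane assignments with significant UCM; (2/3)
#' significant UCM, nC17/Pr < 1 and nC18/Ph < 1, Pr and Ph dominant over the
#' remaining alkanes — 3 when at most `residual_count_threshold` non-Pr/Ph
#' alkanes survive, else 2; (1) slight UCM with both ratios > 1; (0)
#' otherwise with n-alkanes present. A profile with no n-alkanes and a UCM
#' index below the significant threshold is flagged indeterminate.
#'
#' @param profile An `alkane_profile` from [assign_series()].
#' @param ucm_index UCM index from [compute_ucm_index()].
#' @param thresholds List from [scoring_thresholds()].
#' @return Object of class `degradation_score`: list with `degree` (integer
#'   0-4 or `NA` when indeterminate), `indeterminate`, `ucm_index`,
#'   `diagnostics` (the profile).
#' @export
score_degradation <- function(profile, ucm_index,
                              thresholds = scoring_thresholds()) {
  stopifnot(inherits(profile, "alkane_profile"),
            ucm_index >= 0, ucm_index <= 1)
  th <- thresholds
  r17 <- profile$c17_pr_ratio
  r18 <- profile$c18_ph_ratio
  n_alk <- profile$n_alkanes_present
  dom <- profile$pr_ph_dominance

  degree <- NA_integer_
  if (n_alk == 0 && ucm_index >= th$ucm_significant) {
    degree <- 4L
  } else if (ucm_index >= th$ucm_significant &&
             !is.na(r17) && !is.na(r18) && r17 < 1 && r18 < 1 &&
             !is.na(dom) && dom >= th$dominance_threshold) {
    residual <- sum(grepl("^nC", profile$peaks$assignment) &
                      !profile$peaks$assignment %in% c("nC17", "nC18"))
    degree <- if (residual <= th$residual_count_threshold) 3L else 2L
  } else if (ucm_index >= th$ucm_slight &&
             !is.na(r17) && !is.na(r18) && r17 > 1 && r18 > 1) {
    degree <- 1L
  } else if (n_alk > 0) {
    degree <- 0L
  }
  structure(
    list(degree = degree, indeterminate = is.na(degree),
         ucm_index = ucm_index, diagnostics = profile),
    class = "degradation_score")
}

#' Score a chromatogram end to end
#'
#' Convenience wrapper: peak detection, series assignment, UCM index, rule
#' evaluation.
#'
#' @inheritParams detect_peaks
#' @inheritParams assign_series
#' @inheritParams score_degradation
#' @return A `degradation_score`.
#' @export
score_chromatogram <- function(chrom, calibration = alkane_calibration(),
                               thresholds = scoring_thresholds(),
                               min_snr = 5, min_prominence_fraction = 0.02,
                               baseline_window = 1.5, rt_tolerance = 0.2) {
  peaks <- detect_peaks(chrom, min_snr = min_snr,
                        min_prominence_fraction = min_prominence_fraction,
                        baseline_window = baseline_window)
  profile <- assign_series(peaks, calibration, rt_tolerance = rt_tolerance)
  ucm <- compute_ucm_index(chrom, baseline_window = baseline_window)
  score_degradation(profile, ucm, thresholds)
}

#' @export
print.degradation_score <- function(x, ...) {
  cat("Biodegradation score:",
      if (x$indeterminate) "indeterminate" else x$degree, "\n")
  cat(sprintf("  UCM index: %.3f | n-alkanes: %d | nC17/Pr: %s | nC18/Ph: %s\n",
              x$ucm_index, x$diagnostics$n_alkanes_present,
              formatC(x$diagnostics$c17_pr_ratio, digits = 3),
              formatC(x$diagnostics$c18_ph_ratio, digits = 3)))
  invisible(x)
}
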