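# Reporter dose-response metrics from plate-reader kinetics: normalization,
# induction ratios, EC200, delta-RLU, time-to-ratio-2 and cross-strain fold
# changes.

#' Normalize plate kinetics to cell density and subtract the background
#'
#' Optionally divides the reporter signal by the same well's OD600 (per-cell
#' normalization), then subtracts each well's time-zero value. Control wells
#' are processed identically.
#'
#' @param ts A `plate_timeseries` tibble (columns `time_min`, `well`,
#'   `dnt_ug_per_l`, `od600`, `signal`, `replicate`).
#' @param use_od Divide by OD600 before background subtraction
#'   (default TRUE).
#' @return The table with `signal` replaced by the normalized,
#'   background-subtracted value.
#' @export
normalize_and_background <- function(ts, use_od = TRUE) {
  ts <- as_plate_timeseries(ts)
  if (use_od) {
    if (any(ts$od600 <= 0)) stop("OD600 must be positive for normalization")
    ts$signal <- ts$signal / ts$od600
  }
  t0 <- ts[ts$time_min == 0, c("well", "signal")]
  if (!all(unique(ts$well) %in% t0$well)) {
    stop("every well needs a time-zero measurement")
  }
  ts$signal <- ts$signal - t0$signal[match(ts$well, t0$well)]
  attr(ts, "normalized") <- TRUE
  ts
}

#' @noRd
as_plate_timeseries <- function(ts) {
  req <- c("time_min", "well", "dnt_ug_per_l", "od600", "signal")
  if (!all(req %in% names(ts))) {
    stop("plate table must have columns: ", paste(req, collapse = ", "))
  }
  if (any(ts$time_min < 0)) stop("time points must be non-negative")
  if (!any(ts$dnt_ug_per_l == 0)) {
    stop("a DNT-free control series (dnt_ug_per_l == 0) is required")
  }
  if (!inherits(ts, "plate_timeseries")) {
    class(ts) <- c("plate_timeseries", class(ts))
  }
  ts
}

# Replicate-averaged signal of one concentration at each time point.
#' @noRd
mean_signal_series <- function(ts, dnt_ug_per_l) {
  sub <- ts[abs(ts$dnt_ug_per_l - dnt_ug_per_l) < 1e-9, ]
  if (!nrow(sub)) stop("no wells at ", dnt_ug_per_l, " ug/L")
  agg <- tapply(sub$signal, sub$time_min, mean)
  tibble::tibble(time_min = as.numeric(names(agg)), signal = as.numeric(agg))
}

#' Induction ratio at a given concentration and time
#'
#' Ratio of the (normalized, background-subtracted) replicate-averaged
#' sample signal to the DNT-free control at one time point.
#'
#' @param ts A normalized `plate_timeseries`
#'   (see [normalize_and_background()]).
#' @param dnt Sample concentration in ug/L.
#' @param time Time point in minutes (must be sampled).
#' @return Dimensionless ratio.
#' @export
induction_ratio <- function(ts, dnt, time) {
  ts <- as_plate_timeseries(ts)
  smp <- mean_signal_series(ts, dnt)
  ctl <- mean_signal_series(ts, 0)
  s <- smp$signal[smp$time_min == time]
  c0 <- ctl$signal[ctl$time_min == time]
  if (!length(s) || !length(c0)) {
    stop("time ", time, " min not measured for both sample and control")
  }
  if (c0 <= 0) stop("control signal is not positive at ", time, " min")
  s / c0
}

# Ratio series over all times where the control is positive.
#' @noRd
ratio_series <- function(ts, dnt) {
  smp <- mean_signal_series(ts, dnt)
  ctl <- mean_signal_series(ts, 0)
  stopifnot(identical(smp$time_min, ctl$time_min))
  ok <- ctl$signal > 0
  tibble::tibble(time_min = smp$time_min[ok],
                 ratio = smp$signal[ok] / ctl$signal[ok])
}

#' Maximal signal difference over the analysis window
#'
#' Max over time points within the window of (replicate-averaged sample
#' minus control) -- the delta-RLU statistic of a bioluminescent reporter.
#'
#' @param ts A `plate_timeseries` (raw RLU or normalized; the statistic is a
#'   plain difference).
#' @param dnt Sample concentration in ug/L.
#' @param window_min Analysis window in minutes (default 360, a 6 h
#'   exposure).
#' @return Maximal difference (same units as `signal`).
#' @export
max_delta_rlu <- function(ts, dnt, window_min = 360) {
  ts <- as_plate_timeseries(ts)
  smp <- mean_signal_series(ts, dnt)
  ctl <- mean_signal_series(ts, 0)
  keep <- smp$time_min <= window_min
  if (!any(keep)) stop("no time points within the analysis window")
  max(smp$signal[keep] - ctl$signal[keep])
}

#' Maximal induction ratios per concentration
#'
#' For each non-zero concentration in the table, the maximum induction ratio
#' over time points within the window. This is the response curve from which
#' [ec200()] is read.
#'
#' @inheritParams max_delta_rlu
#' @return Named numeric vector: concentration (ug/L) -> max ratio, sorted
#'   by concentration.
#' @export
max_induction_ratios <- function(ts, window_min = 360) {
  ts <- as_plate_timeseries(ts)
  concs <- sort(setdiff(unique(ts$dnt_ug_per_l), 0))
  out <- vapply(concs, function(cc) {
    rs <- ratio_series(ts, cc)
    keep <- rs$time_min <= window_min
    if (!any(keep)) stop("no time points within the analysis window")
    max(rs$ratio[keep])
  }, numeric(1))
  setNames(out, concs)
}

#' EC200: concentration at which the response doubles
#'
#' The detection-threshold statistic: the smallest concentration at which
#' the reporter signal in the presence of analyte is twice that in its
#' absence. If a measured concentration hits ratio 2 exactly it is returned
#' as-is; otherwise the crossing is interpolated linearly in
#' log10(concentration) between the bracketing measurements. The smallest
#' crossing is taken for non-monotone curves. When the ratio never reaches
#' 2, `NA` is returned with a classed `sortscreen_undefined` warning.
#'
#' @param response Named numeric vector: concentration -> maximal induction
#'   ratio (see [max_induction_ratios()]).
#' @param threshold Ratio defining the threshold (default 2).
#' @return Concentration in the same units as the names of `response`, or
#'   `NA` if undefined.
#' @examples
#' ec200(c("10" = 1.5, "100" = 3.0))  # ~21.5
#' @export
ec200 <- function(response, threshold = 2) {
  stopifnot(is.numeric(response), !is.null(names(response)),
            length(response) >= 1)
  conc <- as.numeric(names(response))
  if (anyNA(conc) || any(conc <= 0)) {
    stop("`response` names must be positive concentrations")
  }
  o <- order(conc)
  conc <- conc[o]
  r <- unname(response[o])
  hit <- which(r == threshold)
  exact <- if (length(hit)) conc[hit[1L]] else Inf
  crossing <- Inf
  for (i in seq_len(length(r) - 1)) {
    if (r[i] < threshold && r[i + 1] > threshold) {
      lg <- log10(conc[i]) +
        (threshold - r[i]) / (r[i + 1] - r[i]) *
        (log10(conc[i + 1]) - log10(conc[i]))
      crossing <- 10^lg
      break
    }
  }
  if (r[1] > threshold) {
    # already above threshold at the lowest tested concentration: the true
    # crossing lies below the measured range; report the lowest tested
    # concentration as a conservative upper bound
    crossing <- min(crossing, conc[1])
  }
  out <- min(exact, crossing)
  if (!is.finite(out)) return(undefined_value("EC200"))
  out
}

#' Time to reach a given induction ratio
#'
#' First time at which the induction ratio crosses the threshold, linearly
#' interpolated between the bracketing sampling points; an exact hit at a
#' sampled time is returned as-is. `NA` with a `sortscreen_undefined`
#' warning if the ratio never crosses.
#'
#' @param ts A normalized `plate_timeseries`.
#' @param dnt Sample concentration in ug/L.
#' @param threshold Ratio threshold (default 2).
#' @return Time in minutes, or `NA` if never crossed.
#' @export
time_to_ratio <- function(ts, dnt, threshold = 2) {
  ts <- as_plate_timeseries(ts)
  rs <- ratio_series(ts, dnt)
  if (!nrow(rs)) return(undefined_value("time to ratio"))
  hit <- which(rs$ratio == threshold)
  if (length(hit)) return(rs$time_min[hit[1L]])
  above <- which(rs$ratio > threshold)
  if (!length(above)) return(undefined_value("time to ratio"))
  i <- above[1L]
  if (i == 1L) return(rs$time_min[1L])
  t0 <- rs$time_min[i - 1L]; t1 <- rs$time_min[i]
  r0 <- rs$ratio[i - 1L]; r1 <- rs$ratio[i]
  t0 + (threshold - r0) / (r1 - r0) * (t1 - t0)
}

#' Bundle dose-response performance metrics
#'
#' @param ec200 Detection threshold concentration (ug/L), or `NA`.
#' @param max_delta_rlu Maximal signal difference over the window, or `NA`.
#' @param time_to_ratio2 Response time in minutes, or `NA`.
#' @param induction_ratios Optional named vector of per-concentration
#'   maximal ratios.
#' @return A `dose_response_metrics` list.
#' @export
dose_response_metrics <- function(ec200, max_delta_rlu, time_to_ratio2,
                                  induction_ratios = NULL) {
  structure(list(ec200 = ec200,
                 max_delta_rlu = max_delta_rlu,
                 time_to_ratio2 = time_to_ratio2,
                 induction_ratios = induction_ratios),
            class = "dose_response_metrics")
}

#' Compute all dose-response metrics from a plate table
#'
#' Normalizes (optional), derives the max-ratio response curve, and computes
#' the EC200, the delta-RLU *at* the EC200 concentration (log-linearly
#' interpolated between tested concentrations; flagged in the
#' `delta_rlu_interpolated` attribute), and the time to reach the ratio
#' threshold at the lowest tested concentration at or above the EC200.
#'
#' @param ts A `plate_timeseries` (raw).
#' @param window_min Analysis window (default 360 min).
#' @param threshold Ratio threshold (default 2).
#' @param use_od Per-cell normalization before ratios (default TRUE).
#' @return A [dose_response_metrics()].
#' @export
compute_dose_response <- function(ts, window_min = 360, threshold = 2,
                                  use_od = TRUE) {
  norm <- normalize_and_background(ts, use_od = use_od)
  resp <- max_induction_ratios(norm, window_min)
  e <- suppressWarnings(ec200(resp, threshold))
  if (is.na(e)) {
    return(dose_response_metrics(undefined_value("EC200"), NA_real_,
                                 NA_real_, resp))
  }
  concs <- as.numeric(names(resp))
  drlu <- vapply(concs, function(cc) max_delta_rlu(ts, cc, window_min),
                 numeric(1))
  d_at_ec <- if (any(concs == e)) {
    drlu[concs == e][1L]
  } else {
    # log-linear interpolation of delta-RLU at the EC200 concentration
    stats::approx(log10(concs), drlu, xout = log10(e), rule = 2)$y
  }
  tconc <- min(concs[concs >= e - 1e-12])
  t2 <- suppressWarnings(time_to_ratio(norm, tconc, threshold))
  out <- dose_response_metrics(e, d_at_ec, t2, resp)
  attr(out, "delta_rlu_interpolated") <- !any(concs == e)
  out
}

#' Fold-change comparison of two reporter strains
#'
#' Performance of a variant relative to a reference:
#' `threshold_fold = reference$ec200 / variant$ec200` (how much lower the
#' detection threshold is), `signal_fold = variant$max_delta_rlu /
#' reference$max_delta_rlu`, and the percent reduction in response time.
#' Undefined (`NA`) inputs propagate to `NA` outputs.
#'
#' @param reference,variant [dose_response_metrics()] objects.
#' @return List with `threshold_fold`, `signal_fold`,
#'   `response_time_reduction_pct`.
#' @examples
#' ref <- dose_response_metrics(70, 37000, 118)
#' var <- dose_response_metrics(10, 1707000, 72)
#' fold_metrics(ref, var)  # 7-fold, ~46-fold, ~39% faster
#' @export
fold_metrics <- function(reference, variant) {
  stopifnot(inherits(reference, "dose_response_metrics"),
            inherits(variant, "dose_response_metrics"))
  list(
    threshold_fold = reference$ec200 / variant$ec200,
    signal_fold = variant$max_delta_rlu / reference$max_delta_rlu,
    response_time_reduction_pct =
      100 * (reference$time_to_ratio2 - variant$time_to_ratio2) /
      reference$time_to_ratio2
  )
}
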