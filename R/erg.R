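#' @include AllClasses.R
NULL

#' Pre-stimulus baseline of an ERG trace
#'
#' Mean voltage over the pre-onset window; all amplitude features are
#' referenced to it, making them invariant to constant voltage offsets.
#'
#' @param trace an \linkS4class{ERGTrace} with >= 10 ms of pre-onset
#'   samples.
#' @return baseline voltage (uV).
#' @export
ergBaseline <- function(trace) {
  stopifnot(methods::is(trace, "ERGTrace"))
  pre <- trace@t < trace@onset
  if (!any(pre) || (trace@onset - trace@t[1]) < 0.010)
    stop("at least 10 ms of pre-onset record required for the baseline")
  mean(trace@v[pre])
}

#' a-wave amplitude at 7 ms post-stimulus
#'
#' The a-wave (photoreceptor dark-current suppression) is measured at a
#' fixed latency of 7 ms after stimulus onset: the magnitude of the
#' baseline-referenced voltage there, with linear interpolation between
#' samples.  The reading is taken on the OP-suppressed slow wave
#' (zero-phase low-pass just below the OP band) so that oscillatory
#' potentials and recording noise do not contaminate a single-sample read;
#' zero-phase filtering leaves the latency unbiased.
#'
#' @param trace an \linkS4class{ERGTrace} extending >= 7 ms past onset.
#' @param latencyS measurement latency (s, default 0.007).
#' @param smoothCutoffHz low-pass cutoff for the slow-wave read (Hz,
#'   default 50).
#' @return amplitude (uV, >= 0).
#' @examples
#' tr <- generateERGTrace(ERGTruth(aAmp = 150, opAmps = rep(0, 4)),
#'                        noiseSd = 0)
#' aWaveAmplitude(tr)
#' @export
aWaveAmplitude <- function(trace, latencyS = 0.007, smoothCutoffHz = 50) {
  stopifnot(methods::is(trace, "ERGTrace"))
  tMeasure <- trace@onset + latencyS
  if (tMeasure > trace@t[length(trace@t)])
    stop(sprintf("record ends before onset + %.0f ms", 1000 * latencyS))
  sm <- smoothForBPeak(trace@v, samplingRate(trace), smoothCutoffHz)
  v7 <- stats::approx(trace@t, sm, xout = tMeasure)$y
  abs(ergBaseline(trace) - v7)
}

# Zero-phase low-pass used to suppress OPs before locating the a/b extrema.
smoothForBPeak <- function(v, fs, cutoffHz = 50, order = 4) {
  if (cutoffHz >= fs / 2) return(v)
  bf <- signal::butter(order, cutoffHz / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, v))
}

#' b-wave amplitude and peak time
#'
#' Both extrema are located on an OP-smoothed copy of the trace (zero-phase
#' low-pass just below the OP band, so oscillatory potentials riding the
#' b-wave do not masquerade as its peak and no latency bias is introduced).
#' The a-trough is the minimum in the window (onset, onset +
#' \code{aWindowS}]; the b-peak is the maximum after the a-trough.
#' Amplitude is measured from the a-trough to the b-peak; peak time is
#' referenced to stimulus onset.  When no negative a-deflection exists the
#' amplitude is measured from baseline, with a warning.
#'
#' @param trace an \linkS4class{ERGTrace}.
#' @param aWindowS window after onset searched for the a-trough (s,
#'   default 0.05, bracketing rodent a-wave latencies).
#' @param smoothCutoffHz low-pass cutoff used to suppress OPs when locating
#'   the extrema (Hz, default 50, just under the 60 Hz OP band edge).
#' @return list with \code{bAmpUv} and \code{bPeakTimeS}.
#' @examples
#' tr <- generateERGTrace(ERGTruth(opAmps = rep(0, 4)), noiseSd = 0)
#' bWaveAmplitude(tr)
#' @export
bWaveAmplitude <- function(trace, aWindowS = 0.05, smoothCutoffHz = 50) {
  stopifnot(methods::is(trace, "ERGTrace"))
  base <- ergBaseline(trace)
  fs <- samplingRate(trace)
  post <- trace@t > trace@onset
  if (diff(range(trace@v[post])) == 0)
    stop("feature not found: no interior extrema after onset")
  sm <- smoothForBPeak(trace@v, fs, smoothCutoffHz)
  aWin <- post & trace@t <= trace@onset + aWindowS
  iTrough <- which(aWin)[which.min(sm[aWin])]
  vTrough <- sm[iTrough]
  after <- seq_along(sm) > iTrough
  if (!any(after)) stop("feature not found: record ends at the a-trough")
  iPeak <- which(after)[which.max(sm[after])]
  ref <- vTrough
  # an a-trough less than 1% of the b-excursion below baseline is filter
  # ripple, not an a-wave
  if (vTrough >= base - 0.01 * max(sm[iPeak] - base, 0)) {
    warning("no a-wave trough below baseline; b-amplitude measured from baseline")
    ref <- base
  }
  list(bAmpUv = max(sm[iPeak] - ref, 0),
       bPeakTimeS = trace@t[iPeak] - trace@onset,
       aTroughTimeS = trace@t[iTrough] - trace@onset)
}

#' Extract oscillatory potentials by Butterworth band-pass filtering
#'
#' Applies a fifth-order Butterworth band-pass (default 60--300 Hz, the
#' conventional mouse OP band) to the voltage trace.  By default the
#' filter is applied forward and backward (zero phase: peak times are
#' preserved, effective order doubles); a single-pass mode provides strict
#' fifth-order response at the cost of phase delay.
#'
#' @param trace an \linkS4class{ERGTrace}.
#' @param order filter order (default 5).
#' @param bandHz numeric(2), pass band in Hz (default c(60, 300)).
#' @param zeroPhase logical; forward-backward filtering (default TRUE).
#' @return An \linkS4class{ERGTrace} holding the band-passed voltages
#'   (same time base and metadata).
#' @examples
#' tr <- generateERGTrace(ERGTruth(), noiseSd = 0)
#' ops <- extractOPs(tr)
#' @export
extractOPs <- function(trace, order = 5, bandHz = c(60, 300),
                       zeroPhase = TRUE) {
  stopifnot(methods::is(trace, "ERGTrace"), length(bandHz) == 2)
  fs <- samplingRate(trace)
  if (fs <= 2 * bandHz[2])
    stop("sampling rate violates the Nyquist limit for the upper band edge")
  bf <- signal::butter(order, bandHz / (fs / 2), type = "pass")
  v <- if (zeroPhase) as.numeric(signal::filtfilt(bf, trace@v))
       else as.numeric(signal::filter(bf, trace@v))
  methods::initialize(trace, v = v)
}

#' OP1--OP4 peak amplitudes from a band-passed trace
#'
#' Amplitudes of the first four positive local maxima of the filtered
#' trace, in temporal order, within the window (onset +
#' \code{windowStartS}, onset + \code{windowEndS}], each measured from the
#' filtered-trace zero line.  Oscillatory potentials ride the rising limb
#' of the b-wave, so the search conventionally starts at the a-trough and
#' ends at the b-peak.  Positive peaks smaller than \code{minRelAmp} times
#' the largest peak in the window are treated as residual ripple, not
#' oscillatory potentials; peaks preceding the dominant OP that fall below
#' \code{leadRelAmp} of it are likewise rejected as slow-wave remnant (the
#' a-wave transient is broadband, so its filtered residue can form small
#' early peaks).  Fewer than four peaks yields NA padding and a warning.
#'
#' @param filtered an \linkS4class{ERGTrace} from \code{\link{extractOPs}}.
#' @param windowEndS end of the search window after onset (s); typically
#'   the b-peak time.
#' @param windowStartS start of the search window after onset (s,
#'   default 0); typically the a-trough time.
#' @param minRelAmp relative amplitude floor for accepting a peak
#'   (default 0.05).
#' @param leadRelAmp relative floor for peaks preceding the dominant peak
#'   (default 0.25).
#' @return numeric(4) of OP1--OP4 amplitudes (uV).
#' @export
opAmplitudes <- function(filtered, windowEndS, windowStartS = 0,
                         minRelAmp = 0.05, leadRelAmp = 0.25) {
  stopifnot(methods::is(filtered, "ERGTrace"))
  win <- filtered@t > filtered@onset + windowStartS &
         filtered@t <= filtered@onset + windowEndS
  v <- filtered@v
  idx <- which(win)
  idx <- idx[idx > 1 & idx < length(v)]
  isPeak <- v[idx] > 0 & v[idx] > v[idx - 1] & v[idx] >= v[idx + 1]
  peaks <- v[idx[isPeak]]
  if (length(peaks)) {
    iMax <- which.max(peaks)
    keep <- peaks >= minRelAmp * peaks[iMax] &
      (seq_along(peaks) >= iMax | peaks >= leadRelAmp * peaks[iMax])
    peaks <- peaks[keep]
  }
  if (length(peaks) < 4L) {
    warning(sprintf("only %d positive OP peaks found in the window; padding with NA",
                    length(peaks)))
    peaks <- c(peaks, rep(NA_real_, 4L - length(peaks)))
  }
  peaks[1:4]
}

#' Extract all ERG features from one trace
#'
#' Computes the a-wave amplitude at 7 ms, the a-trough-to-b-peak amplitude
#' and latency, and the OP1--OP4 peak amplitudes through the Butterworth
#' band-pass, in one call.
#'
#' @param trace an \linkS4class{ERGTrace}.
#' @param aLatencyS a-wave measurement latency (s, default 0.007).
#' @param order,bandHz,zeroPhase OP filter settings (see
#'   \code{\link{extractOPs}}).
#' @return An \linkS4class{ERGFeatures}.
#' @examples
#' ergFeatures(generateERGTrace(ERGTruth(), noiseSd = 0))
#' @export
ergFeatures <- function(trace, aLatencyS = 0.007, order = 5,
                        bandHz = c(60, 300), zeroPhase = TRUE) {
  b <- bWaveAmplitude(trace)
  ops <- withCallingHandlers(
    opAmplitudes(extractOPs(trace, order, bandHz, zeroPhase),
                 windowEndS = b$bPeakTimeS,
                 windowStartS = b$aTroughTimeS),
    warning = function(w) invokeRestart("muffleWarning"))
  new("ERGFeatures", aAmpUv = aWaveAmplitude(trace, aLatencyS),
      bAmpUv = b$bAmpUv, bPeakTimeS = b$bPeakTimeS, opAmpsUv = ops)
}

#' Amplitude-vs-intensity tables for grouped ERG series
#'
#' Extracts features from every trace and aggregates them per (group,
#' condition, flash intensity) cell as mean +/- SEM, averaging within
#' cells before any group statistics.
#'
#' @param traces list of \linkS4class{ERGTrace}.
#' @param groups character vector parallel to \code{traces} (default: one
#'   group "all").
#' @param ... passed to \code{\link{ergFeatures}}.
#' @return data.frame with one row per cell: group, condition, flash, n,
#'   and mean/sem columns for aAmp, bAmp, bPeakTime, op1--op4.
#' @export
analyzeERGSeries <- function(traces, groups = NULL, ...) {
  stopifnot(is.list(traces), length(traces) > 0)
  if (is.null(groups)) groups <- rep("all", length(traces))
  stopifnot(length(groups) == length(traces))
  feat <- lapply(traces, ergFeatures, ...)
  df <- data.frame(
    group = groups,
    condition = vapply(traces, function(x) x@condition, character(1)),
    flash = vapply(traces, function(x) x@flash, numeric(1)),
    aAmp = vapply(feat, function(f) f@aAmpUv, numeric(1)),
    bAmp = vapply(feat, function(f) f@bAmpUv, numeric(1)),
    bPeakTime = vapply(feat, function(f) f@bPeakTimeS, numeric(1)),
    op1 = vapply(feat, function(f) f@opAmpsUv[1], numeric(1)),
    op2 = vapply(feat, function(f) f@opAmpsUv[2], numeric(1)),
    op3 = vapply(feat, function(f) f@opAmpsUv[3], numeric(1)),
    op4 = vapply(feat, function(f) f@opAmpsUv[4], numeric(1))
  )
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  cells <- split(df, interaction(df$group, df$condition, df$flash, drop = TRUE))
  out <- do.call(rbind, lapply(cells, function(d) {
    row <- data.frame(group = d$group[1], condition = d$condition[1],
                      flash = d$flash[1], n = nrow(d))
    for (f in c("aAmp", "bAmp", "bPeakTime", "op1", "op2", "op3", "op4")) {
      row[[paste0(f, "Mean")]] <- mean(d[[f]])
      row[[paste0(f, "Sem")]] <- sem(d[[f]])
    }
    row
  }))
  out <- out[order(out$group, out$condition, out$flash), ]
  rownames(out) <- NULL
  out
}
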