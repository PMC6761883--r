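#' @include AllClasses.R synthetic-mosaic.R
NULL

# Gamma-shaped unimodal kernel, unit peak at tPeak, zero for tau <= 0.
gammaLobe <- function(tau, tPeak, shape) {
  out <- numeric(length(tau))
  pos <- tau > 0
  x <- tau[pos] / tPeak
  out[pos] <- x^shape * exp(shape * (1 - x))
  out
}

# Band-limit a lobe kernel below the OP band (zero-phase low-pass), shift
# its extremum to tPeak and renormalize to unit peak, so the slow a/b
# waves carry little energy into the oscillatory-potential passband.
# Causality (zero before onset) forces a residual onset transient whose
# band-passed ring would otherwise contaminate the OP epoch; the ring is
# cancelled there by subtracting the kernel's own band-passed component,
# gated to after the trough.
smoothLobe <- function(tau, tPeak, shape, fs, cutoffHz = 45,
                       ringCancel = FALSE) {
  k <- gammaLobe(tau, tPeak, shape)
  bf <- signal::butter(4, cutoffHz / (fs / 2), type = "low")
  k <- as.numeric(signal::filtfilt(bf, k))
  shift <- which.max(k) - which.min(abs(tau - tPeak))
  if (shift > 0) k <- c(k[-seq_len(shift)], rep(0, shift))
  else if (shift < 0) k <- c(rep(0, -shift), k[seq_len(length(k) + shift)])
  k[tau <= 0] <- 0
  if (ringCancel) {
    bp <- signal::butter(4, c(55, min(330, 0.45 * fs)) / (fs / 2),
                         type = "pass")
    gate <- rep(1, length(tau))
    gate[tau <= 0.006] <- 0
    ramp <- tau > 0.006 & tau < 0.009
    gate[ramp] <- sin(pi * (tau[ramp] - 0.006) / (2 * 0.003))^2
    for (i in 1:2) k <- k - gate * as.numeric(signal::filtfilt(bp, k))
  }
  k / max(k)
}

#' Generate a synthetic stimulus-locked ERG trace
#'
#' Constructs a flash response from design parameters: zero baseline before
#' stimulus onset; after onset, a negative a-lobe (smooth gamma-shaped
#' kernel with its trough at 7 ms) reaching \code{-aAmp}, a positive b-lobe
#' (slower smooth kernel) such that the a-trough-to-b-peak excursion equals
#' \code{bAmp} at latency \code{bPeakTime}, a damped oscillatory-potential
#' wavelet at \code{opFreq} whose first four positive peaks have amplitudes
#' \code{opAmps} (smooth spline envelope through the peak times), and
#' additive Gaussian noise.  The a/b lobes are band-limited below the OP
#' passband so that the slow waves and the oscillatory component are
#' spectrally separable, mirroring how oscillatory potentials ride the
#' b-wave in recorded responses.
#'
#' @param truth an \linkS4class{ERGTruth}.
#' @param fs sampling rate (Hz, >= 1000 so OPs are resolved).
#' @param durationS record length (s); must cover onset + bPeakTime.
#' @param noiseSd Gaussian noise SD (uV).
#' @param onsetS stimulus onset time (s, default 0.05).
#' @param flash flash intensity label (cd*s/m^2).
#' @param condition "scotopic" or "photopic".
#' @param opOnsetS delay of the OP wavelet after stimulus onset (s).
#' @param seed integer seed (used only when noiseSd > 0).
#' @return An \linkS4class{ERGTrace}.
#' @examples
#' tr <- generateERGTrace(ERGTruth(), fs = 5000, noiseSd = 0)
#' range(voltages(tr))
#' @export
generateERGTrace <- function(truth, fs = 5000, durationS = 0.35, noiseSd = 0,
                             onsetS = 0.05, flash = 377.2,
                             condition = "scotopic", opOnsetS = 0.015,
                             seed = 1) {
  stopifnot(methods::is(truth, "ERGTruth"))
  if (fs < 1000) stop("'fs' must be >= 1000 Hz to resolve oscillatory potentials")
  if (truth@opFreq > 0 && fs <= 2 * truth@opFreq)
    stop("'fs' violates the Nyquist limit for the OP carrier frequency")
  if (durationS <= onsetS + truth@bPeakTime)
    stop("'durationS' must cover stimulus onset plus the b-peak latency")
  t <- seq(0, durationS, by = 1 / fs)
  tau <- t - onsetS
  v <- numeric(length(t))
  if (truth@aAmp > 0 || truth@bAmp > 0) {
    aLobe <- smoothLobe(tau, 0.007, 4, fs, ringCancel = TRUE)
    bLobe <- smoothLobe(tau, truth@bPeakTime, 5, fs)
    # calibrate the two lobe scalars so the slow-wave component meets the
    # design exactly under the measurement convention (zero-phase low-pass
    # just below the OP band): value -aAmp at 7 ms, trough-to-peak
    # excursion bAmp.  The system is linear in (alpha, beta); extremum
    # locations depend on them only weakly, so a few fixed-point rounds
    # converge.
    lp <- signal::butter(4, min(50, 0.45 * fs) / (fs / 2), type = "low")
    Sa <- as.numeric(signal::filtfilt(lp, aLobe))
    Sb <- as.numeric(signal::filtfilt(lp, bLobe))
    alpha <- truth@aAmp
    beta <- truth@bAmp - truth@aAmp
    aWin <- which(tau > 0 & tau <= 0.05)
    i7 <- which.min(abs(tau - 0.007))
    for (it in 1:4) {
      s <- -alpha * Sa + beta * Sb
      i <- aWin[which.min(s[aWin])]
      j <- which.max(s)
      if (truth@aAmp == 0) {
        alpha <- 0
        if (max(Sb) > 0) beta <- truth@bAmp / max(Sb)
      } else if (truth@bAmp == truth@aAmp) {
        beta <- 0
        alpha <- truth@aAmp / Sa[i7]
      } else {
        A <- rbind(c(-Sa[i7], Sb[i7]),
                   c(Sa[i] - Sa[j], Sb[j] - Sb[i]))
        rhs <- c(-truth@aAmp, truth@bAmp)
        if (abs(det(A)) > 1e-12) {
          sol <- solve(A, rhs)
          alpha <- sol[1]; beta <- sol[2]
        }
      }
    }
    v <- -alpha * aLobe + beta * bLobe
  }
  if (any(truth@opAmps > 0) && truth@opFreq > 0) {
    f <- truth@opFreq
    peakTimes <- opOnsetS + (seq_len(4) - 0.75) / f
    # smooth envelope: soft half-cycle lead-in, spline through the four
    # designed peak amplitudes, decaying tail over two further cycles
    knotsX <- c(opOnsetS - 0.5 / f, peakTimes,
                peakTimes[4] + 1 / f, peakTimes[4] + 2 / f)
    knotsY <- c(0, truth@opAmps, 0.4 * truth@opAmps[4],
                0.1 * truth@opAmps[4])
    env <- stats::spline(knotsX, knotsY, xout = tau, method = "natural")$y
    env[tau < knotsX[1] | tau > knotsX[length(knotsX)]] <- 0
    env <- pmax(env, 0)
    v <- v + env * sin(2 * pi * f * (tau - opOnsetS))
  }
  if (noiseSd > 0)
    v <- v + withSeed(seed, stats::rnorm(length(v), 0, noiseSd))
  ERGTrace(t = t, v = v, onset = onsetS, flash = flash,
           condition = condition)
}

#' Flash-intensity grids of the scotopic and photopic protocols
#'
#' Both protocols step in 0.6 log-unit increments up to 377.2 cd*s/m^2;
#' the scotopic series spans ~7.2 log units (13 flashes, dimmest ~2.4e-5)
#' and the photopic series ~4.2 log units (8 flashes, dimmest ~0.024) on a
#' rod-saturating 30 cd/m^2 background.
#'
#' @return numeric vector of flash intensities (cd*s/m^2), ascending.
#' @examples
#' scotopicFlashGrid()
#' @export
scotopicFlashGrid <- function() 377.2 * 10^(-0.6 * (12:0))

#' @rdname scotopicFlashGrid
#' @export
photopicFlashGrid <- function() 377.2 * 10^(-0.6 * (7:0))
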