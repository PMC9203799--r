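## Trace analysis: uniform probe traces, spike counting, burst segmentation,
## Welch power spectral density estimation and power-law exponent fitting,
## plus a synthetic 1/f^beta generator used to validate the analysis chain.

#' Construct a probe trace
#'
#' A uniformly sampled scalar time series (times in ms).
#'
#' @param times sample times, ms; must be uniformly spaced (relative
#'   tolerance 1e-9).
#' @param values sampled values.
#' @param label trace label.
#' @return a \linkS4class{ProbeTrace}.
#' @export
probeTrace <- function(times, values, label = "trace") {
    obj <- new("ProbeTrace", times = as.numeric(times),
               values = as.numeric(values), label = as.character(label))
    validObject(obj)
    obj
}

#' Count spikes in a trace
#'
#' A spike is an upward crossing of \code{threshold}; crossings within
#' \code{refractoryMs} of the previous accepted spike are ignored.
#'
#' @param trace a \linkS4class{ProbeTrace} (membrane potential, mV) or a
#'   numeric vector with \code{times} supplied.
#' @param threshold detection threshold, mV.
#' @param refractoryMs dead time after each accepted spike, ms.
#' @param times sample times when \code{trace} is a plain vector.
#' @return a \linkS4class{SpikeTrain}.
#' @examples
#' tr <- probeTrace(seq(0, 100, by = 0.1),
#'                  50 * sin(seq(0, 100, by = 0.1)) - 30)
#' countSpikes(tr)
#' @export
countSpikes <- function(trace, threshold = -20, refractoryMs = 2,
                        times = NULL) {
    if (is(trace, "ProbeTrace")) {
        x <- trace@values; tt <- trace@times
    } else {
        x <- as.numeric(trace)
        if (is.null(times)) stop("supply 'times' for a plain numeric trace")
        tt <- as.numeric(times)
    }
    if (length(x) < 2)
        return(new("SpikeTrain", spikeTimes = numeric(0),
                   threshold = threshold, refractory = refractoryMs))
    up <- which(x[-1] >= threshold & x[-length(x)] < threshold) + 1L
    keep <- numeric(0)
    last <- -Inf
    for (i in up) {
        if (tt[i] - last >= refractoryMs) {
            keep <- c(keep, tt[i])
            last <- tt[i]
        }
    }
    new("SpikeTrain", spikeTimes = keep, threshold = threshold,
        refractory = refractoryMs)
}

#' Segment a spike train into bursts
#'
#' Consecutive spikes separated by at most \code{maxGapMs} belong to the
#' same burst; runs with fewer than \code{minSpikes} spikes are discarded.
#'
#' @param spikes a \linkS4class{SpikeTrain} or numeric spike times (ms).
#' @param maxGapMs maximum within-burst inter-spike interval, ms.
#' @param minSpikes minimum spikes for a run to count as a burst.
#' @return data.frame with one row per burst: \code{startMs}, \code{endMs},
#'   \code{durationMs}, \code{nSpikes}.
#' @export
detectBursts <- function(spikes, maxGapMs = 500, minSpikes = 10) {
    st <- if (is(spikes, "SpikeTrain")) spikes@spikeTimes
          else as.numeric(spikes)
    st <- sort(st)
    out <- data.frame(startMs = numeric(0), endMs = numeric(0),
                      durationMs = numeric(0), nSpikes = integer(0))
    if (!length(st)) return(out)
    grp <- cumsum(c(1, diff(st) > maxGapMs))
    for (g in unique(grp)) {
        s <- st[grp == g]
        if (length(s) >= minSpikes)
            out <- rbind(out, data.frame(startMs = s[1], endMs = s[length(s)],
                                         durationMs = s[length(s)] - s[1],
                                         nSpikes = length(s)))
    }
    rownames(out) <- NULL
    out
}

#' Welch power spectral density
#'
#' Averaged modified periodograms: periodic Hann window, 50\% overlap,
#' per-segment constant detrending, one-sided density scaling
#' (\code{Pxx = |X|^2 * 2 / (fs * sum(w^2))}, without doubling at DC and
#' Nyquist).  Frequencies are in Hz; the sampling rate is derived from the
#' trace's time grid (ms).
#'
#' @param trace a \linkS4class{ProbeTrace}, or a numeric vector with
#'   \code{fs} supplied.
#' @param segmentLength samples per segment; default
#'   \code{min(2^floor(log2(n/4)), 2^16)} capped to \code{n}.
#' @param overlap fractional overlap in [0, 1).
#' @param detrend "constant" (subtract the segment mean) or "none".
#' @param fs sampling rate in Hz when \code{trace} is a plain vector.
#' @return data.frame with \code{frequency} (Hz) and \code{power}
#'   (unit^2/Hz).
#' @export
welchPSD <- function(trace, segmentLength = NULL, overlap = 0.5,
                     detrend = c("constant", "none"), fs = NULL) {
    detrend <- match.arg(detrend)
    if (is(trace, "ProbeTrace")) {
        x <- trace@values
        fs <- sampleRate(trace)
    } else {
        x <- as.numeric(trace)
        if (is.null(fs)) stop("supply 'fs' for a plain numeric trace")
    }
    n <- length(x)
    if (n < 8) stop("trace too short for spectral estimation")
    if (is.null(segmentLength))
        segmentLength <- min(2^floor(log2(n / 4)), 2^16)
    L <- as.integer(min(segmentLength, n))
    if (L < 8) stop("segment length too short")
    step <- max(1L, as.integer(round(L * (1 - overlap))))
    starts <- seq(1L, n - L + 1L, by = step)
    w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1L)) / L)
    scale <- 2 / (fs * sum(w^2))
    nf <- L %/% 2L + 1L
    acc <- numeric(nf)
    for (s0 in starts) {
        seg <- x[s0:(s0 + L - 1L)]
        if (detrend == "constant") seg <- seg - mean(seg)
        X <- stats::fft(seg * w)[seq_len(nf)]
        P <- scale * (Re(X)^2 + Im(X)^2)
        P[1] <- P[1] / 2
        if (L %% 2L == 0L) P[nf] <- P[nf] / 2
        acc <- acc + P
    }
    data.frame(frequency = fs * (0:(nf - 1L)) / L,
               power = acc / length(starts))
}

#' Fit a power law to a spectrum
#'
#' Ordinary least squares of log10(power) on log10(frequency) restricted to
#' \code{[fMin, fMax]}; the reported exponent is \code{beta = -slope} of
#' the model \code{power ~ f^-beta}.
#'
#' @param psd data.frame with \code{frequency} and \code{power} columns
#'   (as returned by \code{\link{welchPSD}}).
#' @param fMin,fMax fit band, Hz.
#' @return a \linkS4class{PowerLawFit}.
#' @export
fitPowerLaw <- function(psd, fMin = 100, fMax = 5000) {
    stopifnot(is.data.frame(psd), all(c("frequency", "power") %in%
                                      names(psd)), fMin > 0, fMax > fMin)
    sel <- psd$frequency >= fMin & psd$frequency <= fMax & psd$power > 0
    if (sum(sel) < 3)
        stop("fewer than 3 positive spectral points in the fit band")
    lf <- log10(psd$frequency[sel])
    lp <- log10(psd$power[sel])
    fit <- stats::lm.fit(cbind(1, lf), lp)
    slope <- fit$coefficients[2]
    ssRes <- sum(fit$residuals^2)
    ssTot <- sum((lp - mean(lp))^2)
    new("PowerLawFit", beta = as.numeric(-slope),
        intercept = as.numeric(fit$coefficients[1]),
        fMin = fMin, fMax = fMax,
        rSquared = if (ssTot > 0) 1 - ssRes / ssTot else 1)
}

#' Synthesize a trace with a 1/f^beta spectrum
#'
#' Spectral synthesis: unit-variance Gaussian Fourier coefficients shaped
#' by \code{f^(-beta/2)} and inverse-transformed to a real series.  Useful
#' for validating the spectral chain end to end.  The generator uses (and
#' restores) R's random number stream, so results are reproducible under
#' \code{set.seed}.
#'
#' @param beta target spectral exponent.
#' @param n number of samples.
#' @param fs sampling rate, Hz.
#' @return a \linkS4class{ProbeTrace} labeled "synthetic".
#' @examples
#' set.seed(1)
#' tr <- synthPowerLawTrace(2.5, n = 2^14, fs = 40000)
#' fitPowerLaw(welchPSD(tr), 100, 5000)
#' @export
synthPowerLawTrace <- function(beta, n = 2^16, fs = 40000) {
    stopifnot(n >= 16, fs > 0)
    n <- as.integer(n)
    nf <- n %/% 2L
    f <- fs * seq_len(nf) / n
    amp <- f^(-beta / 2)
    re <- stats::rnorm(nf) * amp
    im <- stats::rnorm(nf) * amp
    spec <- complex(real = re, imaginary = im)
    if (n %% 2L == 0L) spec[nf] <- complex(real = re[nf], imaginary = 0)
    full <- c(0 + 0i, spec,
              if (n %% 2L == 0L) Conj(rev(spec[-nf])) else Conj(rev(spec)))
    x <- Re(stats::fft(full, inverse = TRUE)) / n
    x <- (x - mean(x)) / stats::sd(x)
    probeTrace(1000 / fs * (seq_len(n) - 1L), x, label = "synthetic")
}

#' Full trace analysis
#'
#' Runs the standard pipeline on one trace: spike detection, burst
#' segmentation and, if the trace (or its first burst) is long enough,
#' Welch spectrum and power-law fit over \code{[fMin, fMax]}.
#'
#' @param trace a \linkS4class{ProbeTrace}.
#' @param threshold,refractoryMs spike detection settings.
#' @param maxGapMs,minSpikes burst segmentation settings.
#' @param fMin,fMax power-law fit band, Hz.
#' @param spectrumOn "trace" (whole trace) or "burst" (first burst window).
#' @return list with \code{spikes} (\linkS4class{SpikeTrain}),
#'   \code{bursts} (data.frame), \code{psd} (data.frame or NULL) and
#'   \code{fit} (\linkS4class{PowerLawFit} or NULL).
#' @export
analyzeTrace <- function(trace, threshold = -20, refractoryMs = 2,
                         maxGapMs = 500, minSpikes = 10, fMin = 100,
                         fMax = 5000, spectrumOn = c("trace", "burst")) {
    spectrumOn <- match.arg(spectrumOn)
    spikes <- countSpikes(trace, threshold, refractoryMs)
    bursts <- detectBursts(spikes, maxGapMs, minSpikes)
    seg <- trace
    if (spectrumOn == "burst") {
        if (nrow(bursts) == 0) return(list(spikes = spikes, bursts = bursts,
                                           psd = NULL, fit = NULL))
        sel <- trace@times >= bursts$startMs[1] &
            trace@times <= bursts$endMs[1]
        seg <- probeTrace(trace@times[sel], trace@values[sel],
                          label = paste0(trace@label, ":burst1"))
    }
    psd <- NULL; fit <- NULL
    if (length(seg@times) >= 64) {
        psd <- welchPSD(seg)
        fit <- tryCatch(fitPowerLaw(psd, fMin, fMax), error = function(e)
            NULL)
    }
    list(spikes = spikes, bursts = bursts, psd = psd, fit = fit)
}
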