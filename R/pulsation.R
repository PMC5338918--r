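#' Simulate pulsatile apicomedial-myosin traces
#'
#' Generates one intensity trace per cell. Pulse event times start at an
#' independent uniform phase per cell (pulses are asynchronous between
#' cells) and advance by gaps drawn from
#' \code{Normal(meanInterval, sdInterval)} truncated (by resampling) to
#' exceed \code{pulseWidth}, so consecutive pulses never fully overlap. The
#' trace is \code{baseline + amplitude * sum_k exp(-(t - t_k)^2 / (2 *
#' (pulseWidth/4)^2))} sampled every \code{frameInterval} for
#' \code{nFrames}, plus Gaussian measurement noise of SD \code{noiseSd}.
#'
#' @param pcfg a [PulsationConfig-class].
#' @param nCells number of traces.
#' @param seed integer RNG seed.
#' @return A list of [PulseTrace-class] objects; \code{eventTimes} holds the
#'   generating ground truth.
#' @examples
#' tr <- generatePulseTraces(pulsationConfig(nFrames = 120), nCells = 3, seed = 1)
#' tr[[1]]
#' @seealso [detectPeaks()], [intervalStatistics()]
#' @export
generatePulseTraces <- function(pcfg, nCells, seed = 1L) {
  validObject(pcfg)
  totalT <- pcfg@nFrames * pcfg@frameInterval
  if (totalT < 2 * pcfg@meanInterval)
    warning("trace shorter than two mean intervals; interval estimates will be unreliable")
  set.seed(as.integer(seed))
  times <- (seq_len(pcfg@nFrames) - 1) * pcfg@frameInterval
  sig <- pcfg@pulseWidth / 4
  lapply(seq_len(nCells), function(i) {
    ev <- stats::runif(1, 0, pcfg@meanInterval)
    while (ev[length(ev)] < totalT + pcfg@pulseWidth) {
      gap <- stats::rnorm(1, pcfg@meanInterval, pcfg@sdInterval)
      while (gap <= pcfg@pulseWidth)
        gap <- stats::rnorm(1, pcfg@meanInterval, pcfg@sdInterval)
      ev <- c(ev, ev[length(ev)] + gap)
    }
    y <- rep(pcfg@baseline, pcfg@nFrames)
    for (tk in ev) y <- y + pcfg@amplitude * exp(-(times - tk)^2 / (2 * sig^2))
    if (pcfg@noiseSd > 0) y <- y + stats::rnorm(pcfg@nFrames, 0, pcfg@noiseSd)
    new("PulseTrace", times = times, intensities = y, peaks = integer(0),
        intervals = numeric(0), eventTimes = ev)
  })
}

#' Detect intensity peaks by prominence
#'
#' Deterministic local-maximum detection: candidate peaks are strict local
#' maxima (the first sample of a plateau); each candidate's topographic
#' prominence is its height above the higher of the two bases, where a base
#' is the minimum of the signal between the peak and the nearest sample
#' that exceeds it (or the trace end) on that side. Candidates below
#' \code{minProminence} are dropped, then peaks closer than
#' \code{minSeparation} to a taller accepted peak are suppressed (taller
#' first; ties broken towards the earlier sample).
#'
#' The trace is first smoothed with a short centred boxcar
#' (\code{smoothWindow} frames) to suppress single-frame shot noise; the
#' window is far shorter than any resolvable pulse, so apex positions move
#' by at most one frame. The default prominence threshold is twice the
#' median absolute deviation of the smoothed trace, a scale-free floor tied
#' to the noise level; the default 30 s separation matches the pulse
#' duration.
#'
#' @param x a numeric intensity vector or a [PulseTrace-class].
#' @param times sample times (s); defaults to the sample index for numeric
#'   input and to the stored frame times for a trace.
#' @param minProminence minimal prominence (a.u.); \code{NULL} for 2 * MAD.
#' @param minSeparation minimal peak separation in the units of
#'   \code{times}.
#' @param smoothWindow boxcar width in frames (odd; 1 disables smoothing).
#' @return For numeric input, an integer vector of peak indices. For a
#'   [PulseTrace-class], the trace with \code{peaks} and \code{intervals}
#'   filled in.
#' @examples
#' y <- dnorm(seq(-5, 5, 0.1))
#' detectPeaks(y, minProminence = 0.1)
#' @export
setGeneric("detectPeaks", function(x, times = NULL, minProminence = NULL,
                                   minSeparation = 30, smoothWindow = 5L) {
  standardGeneric("detectPeaks")
})

#' @rdname detectPeaks
#' @export
setMethod("detectPeaks", "numeric", function(x, times = NULL,
                                             minProminence = NULL,
                                             minSeparation = 30,
                                             smoothWindow = 5L) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples to detect peaks")
  if (is.null(times)) times <- seq_len(n)
  if (smoothWindow > 1L) {
    k <- rep(1 / smoothWindow, smoothWindow)
    x <- as.numeric(stats::filter(x, k, sides = 2))
    # centred boxcar is undefined at the ends; extend with the edge values
    half <- smoothWindow %/% 2L
    x[seq_len(half)] <- x[half + 1L]
    x[(n - half + 1L):n] <- x[n - half]
  }
  if (is.null(minProminence)) minProminence <- 2 * stats::mad(x)
  if (minProminence <= 0) minProminence <- .Machine$double.eps

  cand <- integer(0)
  i <- 2L
  while (i < n) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) cand <- c(cand, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(cand)) return(integer(0))

  prom <- vapply(cand, function(p) {
    l <- p - 1L
    lmin <- x[p]
    while (l >= 1L && x[l] <= x[p]) { lmin <- min(lmin, x[l]); l <- l - 1L }
    r <- p + 1L
    rmin <- x[p]
    while (r <= n && x[r] <= x[p]) { rmin <- min(rmin, x[r]); r <- r + 1L }
    x[p] - max(lmin, rmin)
  }, 0)
  cand <- cand[prom >= minProminence]
  if (!length(cand)) return(integer(0))

  ord <- cand[order(-x[cand], cand)]
  keep <- integer(0)
  for (p in ord) {
    if (!length(keep) || all(abs(times[keep] - times[p]) >= minSeparation))
      keep <- c(keep, p)
  }
  sort(keep)
})

#' @rdname detectPeaks
#' @export
setMethod("detectPeaks", "PulseTrace", function(x, times = NULL,
                                                minProminence = NULL,
                                                minSeparation = 30,
                                                smoothWindow = 5L) {
  pk <- detectPeaks(x@intensities, times = x@times,
                    minProminence = minProminence,
                    minSeparation = minSeparation,
                    smoothWindow = smoothWindow)
  x@peaks <- pk
  x@intervals <- if (length(pk) > 1L) diff(x@times[pk]) else numeric(0)
  x
})

#' Pooled inter-pulse interval statistics
#'
#' Pools the inter-peak intervals of a collection of traces and reports
#' their mean and sample standard deviation with counts, the convention
#' behind "mean +/- s.d., n cells, k pulses" summaries. Per-cell mean
#' intervals are reported alongside.
#'
#' @param traces list of [PulseTrace-class] objects; traces without
#'   detected peaks are run through [detectPeaks()] with the given settings
#'   first.
#' @param ... passed on to [detectPeaks()].
#' @return A list with \code{mean}, \code{sd}, \code{nCells} (traces
#'   contributing at least one interval), \code{nIntervals},
#'   \code{perCellMean} and the pooled \code{intervals} vector (seconds).
#' @examples
#' tr <- generatePulseTraces(pulsationConfig(nFrames = 240), 5, seed = 1)
#' intervalStatistics(tr)$mean
#' @export
intervalStatistics <- function(traces, ...) {
  traces <- lapply(traces, function(tr) {
    if (!length(tr@peaks)) detectPeaks(tr, ...) else tr
  })
  ints <- lapply(traces, function(tr) tr@intervals)
  pooled <- unlist(ints)
  if (!length(pooled)) stop("no inter-peak intervals detected in any trace")
  list(mean = mean(pooled),
       sd = if (length(pooled) > 1L) stats::sd(pooled) else NA_real_,
       nCells = sum(lengths(ints) > 0L),
       nIntervals = length(pooled),
       perCellMean = vapply(ints, function(v)
         if (length(v)) mean(v) else NA_real_, 0),
       intervals = pooled)
}
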