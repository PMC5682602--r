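#' @include AllClasses.R
NULL

#' Framewise displacement from realignment parameters
#'
#' Per-frame head-motion summary: the sum of absolute values of the
#' differentiated rigid-body realignment estimates, with the three rotations
#' converted from radians to millimetres as arc length on a sphere of
#' `rotationRadiusMm` (50 mm by convention). The first frame has no
#' predecessor and is assigned FD = 0.
#'
#' @param rp Numeric matrix with one row per frame and 6 columns: three
#'   translations (mm) followed by three rotations (radians). See
#'   [readRealignment()] for column-order and unit conversion of files.
#' @param rotationRadiusMm Sphere radius for the rotation arc length
#'   (default 50 mm).
#' @return Numeric vector of framewise displacement in mm, length
#'   `nrow(rp)`.
#' @examples
#' rp <- matrix(0, 10, 6); rp[5:10, 1] <- 0.1   # one 0.1 mm x-step
#' framewiseDisplacement(rp)
#' @export
framewiseDisplacement <- function(rp, rotationRadiusMm = 50) {
  rp <- as.matrix(rp)
  if (nrow(rp) < 2L) stop("at least 2 frames are required")
  if (ncol(rp) != 6L) stop("expected 6 realignment parameters per frame")
  if (any(!is.finite(rp))) stop("non-finite realignment parameters")
  d <- abs(diff(rp))
  d[, 4:6] <- d[, 4:6] * rotationRadiusMm
  c(0, rowSums(d))
}

#' Scaled signal-intensity difference
#'
#' Per-frame mean squared difference in signal intensity from one time point
#' to the next, divided by the grand mean signal. Intended for volume-mean
#' intensities; when applied to parcel-averaged channels the mean square is
#' taken over channels, an approximation of the volumewise quantity.
#'
#' @param x Numeric matrix (time in rows, channels in columns), numeric
#'   vector (single channel), or a [ParcelTimeSeries-class].
#' @return Numeric vector of unitless scaled differences, first frame 0.
#' @examples
#' scaledIntensityDiff(c(10, 10, 30, 10))  # D(3) = 400/15
#' @export
scaledIntensityDiff <- function(x) {
  if (is(x, "ParcelTimeSeries")) x <- as.matrix(x)
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("at least 2 frames are required")
  gm <- mean(x)
  if (!is.finite(gm) || gm <= 0)
    stop("grand mean signal must be positive to scale intensity differences")
  d <- diff(x)
  c(0, rowMeans(d^2) / gm)
}

#' Build a censoring mask from motion and intensity spikes
#'
#' Frames with framewise displacement above `fdThresh` (default 0.3 mm) or
#' scaled signal-intensity difference above `sidThresh` (default 10) are
#' marked as spikes. Around every spike at frame `t` a temporal mask is
#' expanded: with `expand = "four"` (default) the four frames
#' `{t-1, t, t+1, t+2}` are censored (one volume before and two after the
#' spike); with `expand = "two"` only `{t, t+1}`. Expansions are clipped at
#' the series boundaries (and, when `segments` is supplied, at segment
#' boundaries) and overlapping expansions merge. Censoring is idempotent:
#' frames already censored stay censored with their original provenance.
#'
#' @param fd Per-frame framewise displacement (mm).
#' @param sid Per-frame scaled intensity difference; may be `NULL` to censor
#'   on motion only.
#' @param fdThresh Motion threshold in mm (default 0.3).
#' @param sidThresh Intensity threshold (default 10).
#' @param expand `"four"` (t-1..t+2) or `"two"` (t, t+1).
#' @param segments Optional integer segment labels; expansion does not cross
#'   segment boundaries when given.
#' @return A [CensorMask-class]; spike frames carry provenance `"motion"` or
#'   `"intensity"` (motion takes precedence when both exceed threshold),
#'   expansion frames `"expansion"`.
#' @examples
#' fd <- rep(0, 120); fd[11] <- 0.5
#' sum(censored(buildCensorMask(fd, NULL)))  # 4 frames
#' @export
buildCensorMask <- function(fd, sid = NULL, fdThresh = 0.3, sidThresh = 10,
                            expand = c("four", "two"), segments = NULL) {
  expand <- match.arg(expand)
  n <- length(fd)
  if (!is.null(sid) && length(sid) != n)
    stop("'fd' and 'sid' must have the same length")
  motion <- is.finite(fd) & fd > fdThresh
  intensity <- if (is.null(sid)) rep(FALSE, n) else
    (is.finite(sid) & sid > sidThresh)
  spikes <- motion | intensity
  cen <- rep(FALSE, n)
  reason <- rep("", n)
  if (any(spikes)) {
    off <- if (expand == "four") -1:2 else 0:1
    seg <- if (is.null(segments)) rep(1L, n) else as.integer(segments)
    for (t in which(spikes)) {
      idx <- t + off
      idx <- idx[idx >= 1L & idx <= n & seg[pmin(pmax(idx, 1L), n)] == seg[t]]
      cen[idx] <- TRUE
      reason[idx[reason[idx] == ""]] <- "expansion"
    }
    reason[motion] <- "motion"
    reason[intensity & !motion] <- "intensity"
  }
  CensorMask(cen, reason)
}

#' Apply or replace the censoring mask of a time series
#'
#' @param series A [ParcelTimeSeries-class].
#' @param mask A [CensorMask-class] of matching length.
#' @return The series with the new mask attached.
#' @export
applyCensorMask <- function(series, mask) {
  stopifnot(is(series, "ParcelTimeSeries"), is(mask, "CensorMask"))
  if (length(mask) != nFrames(series))
    stop("mask length does not match the number of frames")
  initialize(series, censorMask = mask)
}

#' Nuisance residualization by ordinary least squares
#'
#' Removes confound effects from every region's time course by OLS
#' projection. The design matrix always contains an intercept; user
#' confound columns and (when `censorIndicators = TRUE`, the default) one
#' indicator column per censored frame are appended, so censored frames
#' have exactly-zero residuals and no influence on the fit — the
#' regression analogue of frame deletion. Collinear columns are dropped
#' with a warning. Residualization is a projection: applying it twice with
#' the same confounds equals applying it once.
#'
#' @param series A [ParcelTimeSeries-class].
#' @param confounds Optional numeric matrix (frames x k) of confound
#'   regressors, e.g. realignment parameters or tissue signals.
#' @param censorIndicators Add per-censored-frame indicator columns
#'   (default `TRUE`).
#' @return A [ParcelTimeSeries-class] of residuals with the same censor
#'   mask and segment labels.
#' @export
residualize <- function(series, confounds = NULL, censorIndicators = TRUE) {
  stopifnot(is(series, "ParcelTimeSeries"))
  y <- as.matrix(series)
  n <- nrow(y)
  X <- matrix(1, n, 1)
  colnames(X) <- "intercept"
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != n)
      stop("confound matrix must have one row per frame")
    X <- cbind(X, confounds)
  }
  cen <- censored(series)
  if (censorIndicators && any(cen)) {
    ind <- matrix(0, n, sum(cen))
    ind[cbind(which(cen), seq_len(sum(cen)))] <- 1
    X <- cbind(X, ind)
  }
  y[!is.finite(y)] <- 0  # censored frames may carry junk; zeros are inert
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X))
    warning(sprintf("dropped %d collinear confound column(s)",
                    ncol(X) - fit$rank))
  res <- as.matrix(fit$residuals)
  dimnames(res) <- dimnames(y)
  initialize(series, values = res)
}

.bandpassVector <- function(x, tr, low, high) {
  n <- length(x)
  f <- (seq_len(n) - 1) / (n * tr)
  f <- pmin(f, 1 / tr - f)  # two-sided frequency of each DFT bin
  keep <- f >= low & f <= high
  Re(stats::fft(stats::fft(x) * keep, inverse = TRUE)) / n
}

#' Band-pass filter a parcel time series
#'
#' Zero-phase ideal (frequency-domain) band-pass filter applied to each
#' region independently: DFT coefficients outside `[low, high]` Hz are set
#' to zero, including the DC component. This is the rectangular filter
#' conventionally used in resting-state functional-connectivity pipelines.
#' Censored frames are linearly interpolated before filtering (an ideal
#' filter is undefined on a gapped series) and remain censored afterwards.
#'
#' @param series A [ParcelTimeSeries-class] with known TR.
#' @param low,high Pass band in Hz (defaults 0.009 and 0.08).
#' @return A filtered [ParcelTimeSeries-class] with the same censor mask.
#' @export
bandpass <- function(series, low = 0.009, high = 0.08) {
  stopifnot(is(series, "ParcelTimeSeries"), low >= 0, high > low)
  nyquist <- 1 / (2 * tr(series))
  if (high >= nyquist)
    stop(sprintf("high cutoff %.4g Hz must be below the Nyquist frequency %.4g Hz",
                 high, nyquist))
  y <- as.matrix(series)
  cen <- censored(series)
  n <- nrow(y)
  if (any(cen)) {
    if (all(cen)) stop("all frames are censored")
    tt <- seq_len(n)
    y <- apply(y, 2, function(col)
      stats::approx(tt[!cen], col[!cen], xout = tt, rule = 2)$y)
  }
  out <- apply(y, 2, .bandpassVector, tr = tr(series), low = low, high = high)
  dimnames(out) <- dimnames(as.matrix(series))
  initialize(series, values = out)
}

#' Data-sufficiency check
#'
#' A subject is usable overall when at least `minTotal` (default 300)
#' un-censored time points remain; the quintile-based internal-consistency
#' analysis additionally requires at least `minPerSegment` (default 100)
#' un-censored time points in every one of the `nSegments` contiguous
#' segments.
#'
#' @param mask A [CensorMask-class] or a [ParcelTimeSeries-class].
#' @param segments Integer segment labels; taken from the series when `mask`
#'   is a [ParcelTimeSeries-class]. When absent, the frames are labeled as
#'   `nSegments` equal contiguous blocks.
#' @param minTotal Minimum total un-censored frames (default 300).
#' @param minPerSegment Minimum un-censored frames per segment (default
#'   100).
#' @param nSegments Number of segments when labels must be constructed
#'   (default 5).
#' @return List with `usableOverall`, `usableSegments`, `totalUncensored`
#'   and `segmentCounts`.
#' @examples
#' m <- CensorMask(rep(FALSE, 600))
#' sufficiencyCheck(m)$usableOverall
#' @export
sufficiencyCheck <- function(mask, segments = NULL, minTotal = 300,
                             minPerSegment = 100, nSegments = 5L) {
  if (is(mask, "ParcelTimeSeries")) {
    if (is.null(segments)) segments <- segmentLabels(mask)
    mask <- censorMask(mask)
  }
  stopifnot(is(mask, "CensorMask"))
  n <- length(mask)
  if (is.null(segments) || length(unique(segments)) < 2L)
    segments <- makeSegmentLabels(n, nSegments)
  keep <- !censored(mask)
  counts <- tapply(keep, segments, sum)
  list(usableOverall = sum(keep) >= minTotal,
       usableSegments = all(counts >= minPerSegment),
       totalUncensored = sum(keep),
       segmentCounts = as.integer(counts))
}
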