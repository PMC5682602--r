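#' @include AllClasses.R
NULL

.withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

#' Construct a simulation specification
#'
#' See [SimSpec-class] for the meaning of every parameter. Defaults mirror
#' the study conditions behind the built-in norms: 41 default-mode regions
#' (14 anterior, 2 posterior-cingulate), five 120-frame task blocks at TR
#' 2.5 s, block Pearson correlations 0.56 (anterior, Fisher-Z 0.63), 0.44
#' (posterior-to-anterior and within-PCC, Fisher-Z 0.47) and 0.34
#' (background, chosen so the whole-network average is about 0.39), a
#' whole-network metric mean of 0.39 with total SD 0.07 split to a design
#' ICC of 0.62, and a 1% motion-spike rate.
#'
#' @param nRegions,nAnterior,nPcc Node counts (defaults 41, 14, 2).
#' @param rAnterior,rPcc,rPostAnt,rBackground Block Pearson correlations.
#' @param nFrames,tr Series length (default 600) and repetition time (s).
#' @param nSubjects,nSessions Cohort dimensions (defaults 126, 2).
#' @param metricMean Population metric mean (default 0.39).
#' @param sdBetween,sdWithin Between-/within-subject SDs of the metric
#'   shift; defaults split a total SD of 0.07 to a design ICC of 0.62.
#' @param spikeRate,spikeMagnitude Motion-spike rate per frame (default
#'   0.01) and translation step in mm (default 0.5).
#' @param arCoef AR(1) coefficient (default 0; zero keeps the closed-form
#'   correlation targets exact).
#' @param seed Integer seed.
#' @return A validated [SimSpec-class].
#' @export
simSpec <- function(nRegions = 41, nAnterior = 14, nPcc = 2,
                    rAnterior = 0.56, rPcc = 0.44, rPostAnt = 0.44,
                    rBackground = 0.34, nFrames = 600, tr = 2.5,
                    nSubjects = 126, nSessions = 2, metricMean = 0.39,
                    sdBetween = 0.07 * sqrt(0.62),
                    sdWithin = 0.07 * sqrt(0.38),
                    spikeRate = 0.01, spikeMagnitude = 0.5, arCoef = 0,
                    seed = 1L) {
  new("SimSpec", nRegions = as.integer(nRegions),
      nAnterior = as.integer(nAnterior), nPcc = as.integer(nPcc),
      rAnterior = rAnterior, rPcc = rPcc, rPostAnt = rPostAnt,
      rBackground = rBackground, nFrames = as.integer(nFrames), tr = tr,
      nSubjects = as.integer(nSubjects), nSessions = as.integer(nSessions),
      metricMean = metricMean, sdBetween = sdBetween, sdWithin = sdWithin,
      spikeRate = spikeRate, spikeMagnitude = spikeMagnitude,
      arCoef = arCoef, seed = as.integer(seed))
}

#' Design reliability implied by a simulation specification
#'
#' `designIcc()` returns the intraclass correlation of the generative
#' subject/session model, `sdBetween^2 / (sdBetween^2 + sdWithin^2)`.
#' `designAlpha()` returns the Cronbach's alpha implied for `k` parallel
#' conditions with that inter-condition correlation `rho`:
#' `k rho / (1 + (k - 1) rho)` (the Spearman-Brown stepped-up reliability).
#'
#' @param spec A [SimSpec-class].
#' @param k Number of conditions for alpha (default 5 quintiles).
#' @return Scalar design ICC or alpha.
#' @export
designIcc <- function(spec) {
  stopifnot(is(spec, "SimSpec"))
  vb <- spec@sdBetween^2
  vw <- spec@sdWithin^2
  if (vb + vw == 0) return(NaN)
  vb / (vb + vw)
}

#' @rdname designIcc
#' @export
designAlpha <- function(spec, k = 5) {
  rho <- designIcc(spec)
  k * rho / (1 + (k - 1) * rho)
}

#' Solve variance components for a design reliability
#'
#' Convenience inverse of [designIcc()]/[designAlpha()]: splits a total
#' metric SD into between- and within-subject components achieving a target
#' ICC (`targetAlpha = NULL`) or a target Cronbach's alpha for `k`
#' conditions.
#'
#' @param totalSd Total metric SD (default 0.07, whole-network scale).
#' @param targetIcc Target design ICC.
#' @param targetAlpha Target design alpha (overrides `targetIcc`).
#' @param k Conditions for the alpha target (default 5).
#' @return Named numeric vector `c(sdBetween, sdWithin)`.
#' @examples
#' reliabilityComponents(targetIcc = 0.62)
#' reliabilityComponents(targetAlpha = 0.70)
#' @export
reliabilityComponents <- function(totalSd = 0.07, targetIcc = 0.62,
                                  targetAlpha = NULL, k = 5) {
  rho <- if (!is.null(targetAlpha)) {
    stopifnot(targetAlpha > 0, targetAlpha < 1)
    targetAlpha / (k - (k - 1) * targetAlpha)
  } else targetIcc
  stopifnot(rho > 0, rho < 1)
  c(sdBetween = totalSd * sqrt(rho), sdWithin = totalSd * sqrt(1 - rho))
}

#' Region labels implied by a simulation specification
#'
#' The first `nAnterior` regions form the anterior block, the next `nPcc`
#' the posterior-cingulate block, and the rest the background.
#'
#' @param spec A [SimSpec-class].
#' @return Named list of region-id character vectors: `anterior`, `pcc`,
#'   `background`, `all`, plus the matching [SubNetworkSpec-class] objects
#'   in `subnetworks`.
#' @export
simRegions <- function(spec) {
  ids <- sprintf("R%02d", seq_len(spec@nRegions))
  ant <- ids[seq_len(spec@nAnterior)]
  pcc <- ids[spec@nAnterior + seq_len(spec@nPcc)]
  bg <- setdiff(ids, c(ant, pcc))
  list(anterior = ant, pcc = pcc, background = bg, all = ids,
       subnetworks = list(
         whole_dmn = SubNetworkSpec("whole_dmn", ids),
         anterior = SubNetworkSpec("anterior", ant),
         posterior_to_anterior = SubNetworkSpec("posterior_to_anterior",
                                                pcc, ant, between = TRUE)))
}

#' Target correlation matrix of a simulation specification
#'
#' Builds the block-structured Pearson correlation matrix (within-anterior,
#' within-PCC, posterior-to-anterior cross block, background) and verifies
#' positive definiteness.
#'
#' @param spec A [SimSpec-class].
#' @param scale Optional multiplier applied to all off-diagonal entries on
#'   the Fisher-Z scale (used for subject-level shifts; default 1).
#' @return Correlation matrix with region-id dimnames.
#' @export
targetCorrelation <- function(spec, scale = 1) {
  reg <- simRegions(spec)
  ids <- reg$all
  n <- length(ids)
  r <- matrix(spec@rBackground, n, n, dimnames = list(ids, ids))
  r[reg$anterior, reg$anterior] <- spec@rAnterior
  r[reg$pcc, reg$pcc] <- spec@rPcc
  r[reg$pcc, reg$anterior] <- spec@rPostAnt
  r[reg$anterior, reg$pcc] <- spec@rPostAnt
  diag(r) <- 1
  if (scale != 1) {
    z <- atanh(r[upper.tri(r)]) * scale
    r[upper.tri(r)] <- tanh(z)
    r <- t(r)
    r[upper.tri(r)] <- tanh(z)
    diag(r) <- 1
  }
  ev <- min(eigen(r, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0)
    stop(sprintf("target correlation matrix is not positive definite (smallest eigenvalue %.3g)",
                 ev))
  r
}

#' Sub-network averages implied by the target correlations
#'
#' The population values of average |Fisher-Z| connectivity under the
#' specification's correlation targets (the values the estimator converges
#' to as frames grow).
#'
#' @param spec A [SimSpec-class].
#' @return Named numeric vector: `whole_dmn`, `anterior`,
#'   `posterior_to_anterior`.
#' @export
impliedAverages <- function(spec) {
  r <- targetCorrelation(spec)
  z <- abs(atanh(r))
  diag(z) <- 0
  cm <- ConnectivityMatrix(z, regionIds = rownames(r))
  reg <- simRegions(spec)
  vapply(reg$subnetworks, function(s) averageConnectivity(cm, s), numeric(1))
}

#' Simulate one subject's parcel time series and realignment trace
#'
#' Frames are drawn from a zero-mean multivariate normal whose correlation
#' matrix carries the specification's block structure (optionally passed
#' through an AR(1) filter, which preserves the zero-lag cross
#' correlations). Realignment parameters are smooth low-amplitude noise
#' plus step-like spikes exceeding the 0.3 mm framewise-displacement
#' threshold at the specified per-frame rate. Output is deterministic given
#' `spec@seed`; the caller's RNG state is left untouched.
#'
#' @param spec A [SimSpec-class].
#' @param scale Off-diagonal Fisher-Z multiplier (subject-level shift;
#'   default 1).
#' @param seed Overrides `spec@seed` when given.
#' @return List with `series` (a [ParcelTimeSeries-class] labeled as five
#'   contiguous segments when the frame count divides evenly, otherwise one
#'   block), `rp` (frames x 6 realignment matrix: translations mm,
#'   rotations radians), `spikeFrames` (injected spike positions) and
#'   `subnetworks` (the specification's [SubNetworkSpec-class] list).
#' @examples
#' sim <- simulateSubject(simSpec(nFrames = 300, seed = 42))
#' sim$series
#' @export
simulateSubject <- function(spec, scale = 1, seed = spec@seed) {
  stopifnot(is(spec, "SimSpec"))
  r <- targetCorrelation(spec, scale = scale)
  n <- spec@nFrames
  p <- spec@nRegions
  .withSeed(seed, {
    x <- matrix(stats::rnorm(n * p), n, p) %*% chol(r)
    if (spec@arCoef != 0) {
      x <- apply(x, 2, function(col)
        as.numeric(stats::filter(col, spec@arCoef, method = "recursive")))
      x <- x * sqrt(1 - spec@arCoef^2)
    }
    colnames(x) <- rownames(r)
    rp <- cbind(
      vapply(1:3, function(i)
        as.numeric(stats::filter(stats::rnorm(n, 0, 0.004), 0.95,
                                 method = "recursive")), numeric(n)),
      vapply(1:3, function(i)
        as.numeric(stats::filter(stats::rnorm(n, 0, 5e-5), 0.95,
                                 method = "recursive")), numeric(n)))
    nSpikes <- stats::rbinom(1, n - 2L, spec@spikeRate)
    spikeFrames <- sort(sample(2:(n - 1L), nSpikes))
    for (s in spikeFrames)  # step offset: one FD spike at the step frame
      rp[s:n, 1] <- rp[s:n, 1] + spec@spikeMagnitude *
        (if (s %% 2 == 0) 1 else -1)
    segs <- if (n %% 5L == 0L) makeSegmentLabels(n, 5L) else rep(1L, n)
    list(series = ParcelTimeSeries(x, tr = spec@tr,
                                   segmentLabels = segs),
         rp = rp, spikeFrames = spikeFrames,
         subnetworks = simRegions(spec)$subnetworks)
  })
}

#' Simulate a cohort with known design reliability
#'
#' Generates subjects-by-conditions metric panels whose population
#' reliability is known by construction. Each subject's metric level is
#' `metricMean + b_s` with `b_s ~ N(0, sdBetween^2)`; each condition
#' (session or quintile) adds an independent perturbation
#' `e ~ N(0, sdWithin^2)`, so the design ICC equals
#' `sdBetween^2 / (sdBetween^2 + sdWithin^2)` and the design alpha over k
#' quintiles follows the Spearman-Brown formula (see [designAlpha()]).
#'
#' With `mode = "panel"` (default) the metric values are drawn directly
#' from this two-level model — the fast route for reliability studies.
#' With `mode = "series"` each subject/session is generated as a full time
#' series whose off-diagonal Fisher-Z targets are scaled to the subject's
#' level, pushed through [connectivityMatrix()] and
#' [averageConnectivity()]; estimation noise then adds to the within-subject
#' variance, so the realized ICC falls below the design value unless the
#' frame count is large.
#'
#' @param spec A [SimSpec-class].
#' @param mode `"panel"` or `"series"`.
#' @param nQuintiles Conditions in the quintile panel (default 5).
#' @param seed Overrides `spec@seed` when given.
#' @return List with `sessionPanel` (subjects x sessions
#'   [MetricPanel-class]), `quintilePanel` (subjects x quintiles),
#'   `designIcc` and `designAlpha`.
#' @examples
#' ch <- simulateCohort(simSpec(nSubjects = 20, seed = 3))
#' iccAgreement(ch$sessionPanel)
#' @export
simulateCohort <- function(spec, mode = c("panel", "series"),
                           nQuintiles = 5L, seed = spec@seed) {
  stopifnot(is(spec, "SimSpec"), spec@nSubjects >= 3L)
  mode <- match.arg(mode)
  ns <- spec@nSubjects
  nk <- spec@nSessions
  .withSeed(seed, {
    b <- stats::rnorm(ns, 0, spec@sdBetween)
    sess <- spec@metricMean + b +
      matrix(stats::rnorm(ns * nk, 0, spec@sdWithin), ns, nk)
    quin <- spec@metricMean + b +
      matrix(stats::rnorm(ns * nQuintiles, 0, spec@sdWithin), ns, nQuintiles)
    if (mode == "series") {
      base <- impliedAverages(spec)[["whole_dmn"]]
      sub <- simRegions(spec)$subnetworks
      estimate <- function(level) {
        s <- simulateSubject(spec, scale = level / base,
                             seed = as.integer(stats::runif(1, 1, 2^30)))
        averageConnectivity(connectivityMatrix(s$series), sub$whole_dmn)
      }
      sess[] <- vapply(as.vector(sess), estimate, numeric(1))
      quin[] <- vapply(as.vector(quin), estimate, numeric(1))
    }
    rownames(sess) <- rownames(quin) <- sprintf("S%03d", seq_len(ns))
    colnames(sess) <- sprintf("session%d", seq_len(nk))
    colnames(quin) <- sprintf("quintile%d", seq_len(nQuintiles))
    list(sessionPanel = MetricPanel(sess, sample = "simulated"),
         quintilePanel = MetricPanel(quin, sample = "simulated"),
         designIcc = designIcc(spec),
         designAlpha = designAlpha(spec, nQuintiles))
  })
}

#' Synthetic 333-region parcellation metadata
#'
#' A deterministic, fully synthetic stand-in parcellation table with the
#' structural properties of the reference 333-region cortical scheme: 333
#' regions, 41 labeled `Default`, of which 14 are frontal-lobe regions with
#' centroids within 15 mm of the midline (the anterior set, including one
#' region exactly at the 15 mm boundary) and 2 are posterior-cingulate
#' regions. Coordinates are synthetic grid values, not real centroids; the
#' table exists so the full pipeline can run and be validated without any
#' download.
#'
#' @return Data frame in the [loadParcellation()] column layout, already
#'   validated with `scheme = "cortical333"`.
#' @examples
#' parc <- syntheticParcellation()
#' lengths(deriveSubnetworks(parc)["anterior"])
#' @export
syntheticParcellation <- function() {
  antX <- c(0, 2, -2, 4, -4, 6, -6, 8, -8, 10, -10, 12, -12, 15)
  ant <- data.frame(ParcelID = 1:14, Community = "Default",
                    Centroid_x = antX,
                    Centroid_y = 45 + (0:13) %% 5 * 4,
                    Centroid_z = 10 + (0:13) %% 4 * 8, Lobe = "Frontal")
  pcc <- data.frame(ParcelID = 15:16, Community = "Default",
                    Centroid_x = c(-5, 5), Centroid_y = c(-50, -52),
                    Centroid_z = c(28, 30), Lobe = "PCC")
  # other Default regions: lateral frontal (|x| > 15) and parietal/temporal
  oth <- data.frame(ParcelID = 17:41, Community = "Default",
                    Centroid_x = rep(c(-40, 40, -25, 25, -50), 5),
                    Centroid_y = rep(c(20, -60, 30, -65, 10), each = 5),
                    Centroid_z = rep(c(15, 35, -5, 25, 0), 5),
                    Lobe = rep(c("Frontal", "Parietal", "Frontal",
                                 "Parietal", "Temporal"), 5))
  nOther <- 333 - 41
  comm <- rep(c("Visual", "SMhand", "Auditory", "CinguloOperc",
                "FrontoParietal", "DorsalAttn", "VentralAttn", "Salience"),
              length.out = nOther)
  rest <- data.frame(ParcelID = 42:333, Community = comm,
                     Centroid_x = round(60 * sin(1:nOther)),
                     Centroid_y = round(70 * cos(1:nOther)),
                     Centroid_z = round(40 * sin(2 * (1:nOther))),
                     Lobe = rep(c("Occipital", "Parietal", "Temporal",
                                  "Frontal", "Insula"),
                                length.out = nOther))
  tab <- rbind(ant, pcc, oth, rest)
  suppressMessages(validateParcellation(tab, scheme = "cortical333"))
}
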