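#' Simulate a Fluo-4 spontaneous-spiking recording with known ground truth
#'
#' Forward-simulates somatic Ca2+ transients as they appear in a
#' single-wavelength recording. Per cell, spike times are drawn from a
#' homogeneous Poisson process within each epoch at that epoch's rate;
#' each spike contributes an instantaneous rise of amplitude A (dF/F0 units,
#' log-normal across spikes) followed by a single-exponential decay. The
#' fluorescence model is
#' \deqn{F(t) = f_0\, e^{-t/\tau_b}\bigl(1 + \sum_i A_i e^{-(t - t_i)/\tau}
#'   [t \ge t_i]\bigr) + \varepsilon(t)}
#' with i.i.d. Gaussian noise \eqn{\varepsilon}. The default plan emulates a
#' 1 frame/s recording with a 4-minute spontaneous baseline followed by a
#' 4-minute epoch in which activity is pharmacologically abolished.
#'
#' Randomness is consumed from one documented stream per cell, derived from
#' the master seed by counter, so cell k's trace does not depend on how many
#' cells are simulated.
#'
#' @param nCells number of cells.
#' @param dt frame interval, seconds.
#' @param plan an [EpochPlan-class]; epoch labels must match
#'   \code{names(epochRates)}. Default [fluo4Plan()] (baseline + treatment,
#'   240 s each). The recording length is the plan's total frame count.
#' @param epochRates named numeric, spikes/min per epoch label (rates >= 0).
#' @param amplitudeMedian,amplitudeSdLog log-normal amplitude law
#'   (median in dF/F0 units; dispersion = sd of log amplitude).
#' @param decayTau transient decay time constant, seconds.
#' @param f0Range range of the per-cell baseline intensity f0 (a.u.),
#'   drawn uniformly.
#' @param bleachTau photobleaching time constant, seconds (Inf = no bleach).
#' @param noiseSd additive Gaussian noise SD (a.u.).
#' @param seed integer master seed; fixed seed gives bit-identical output.
#' @param duration optional total recording duration in seconds; must be a
#'   multiple of \code{dt} and agree with the plan's total frame count.
#' @return a list with elements \code{traces} (a [TraceSet-class]),
#'   \code{truth} (data frame \code{cell_id, time_s, frame, amplitude}; one
#'   row per true spike, \code{frame} is the 0-based frame on which the rise
#'   lands) and \code{plan}.
#' @examples
#' sim <- simulateSpiking(nCells = 3, seed = 42)
#' head(sim$truth)
#' @export
simulateSpiking <- function(nCells = 30, dt = 1, plan = fluo4Plan(dt = dt),
                            epochRates = c(baseline = 3, ttx = 0),
                            amplitudeMedian = 0.5, amplitudeSdLog = 0.5,
                            decayTau = 2, f0Range = c(80, 120),
                            bleachTau = Inf, noiseSd = 0.02, seed = 1,
                            duration = NULL) {
  nCells <- assertCount(nCells, "nCells")
  dt <- assertScalar(dt, "dt", lower = 1e-12)
  if (!is.null(duration)) {
    k <- duration / dt
    if (abs(k - round(k)) > 1e-9)
      stop("'duration' is not a multiple of dt", call. = FALSE)
    if (nFrames(plan) != round(k))
      stop("'duration' does not match the plan's total frame count",
           call. = FALSE)
  }
  assertScalar(decayTau, "decayTau", lower = 1e-12)
  assertScalar(noiseSd, "noiseSd", lower = 0)
  assertScalar(bleachTau, "bleachTau", lower = 1e-12, allowInf = TRUE)
  if (any(epochRates < 0)) stop("epoch rates must be >= 0", call. = FALSE)
  if (!setequal(names(epochRates), epochLabels(plan)))
    stop("names(epochRates) must match the plan's epoch labels", call. = FALSE)

  n <- nFrames(plan)
  times <- dt * (seq_len(n) - 1L)
  seeds <- cellSeeds(seed, nCells)
  values <- matrix(0, n, nCells,
                   dimnames = list(NULL, paste0("cell_", seq_len(nCells))))
  truth <- vector("list", nCells)

  for (k in seq_len(nCells)) {
    set.seed(seeds[k])
    f0 <- stats::runif(1L, f0Range[1L], f0Range[2L])
    st <- numeric(0)
    for (lab in epochLabels(plan)) {
      w <- epochWindow(plan, lab)
      t0 <- w[["start"]] * dt
      t1 <- w[["end"]] * dt
      lambda <- epochRates[[lab]] / 60 * (t1 - t0)
      m <- stats::rpois(1L, lambda)
      # spike times placed so the rise lands on a frame inside the epoch
      # that generated it (the last dt of the epoch maps to its first frame
      # of effect in the next epoch and is therefore not used)
      if (m > 0) st <- c(st, sort(stats::runif(m, t0, t1 - dt)))
    }
    amp <- if (length(st)) stats::rlnorm(length(st),
                                         meanlog = log(amplitudeMedian),
                                         sdlog = amplitudeSdLog) else numeric(0)
    sig <- rep(1, n)
    for (i in seq_along(st)) {
      on <- times >= st[i]
      sig[on] <- sig[on] + amp[i] * exp(-(times[on] - st[i]) / decayTau)
    }
    bleach <- if (is.finite(bleachTau)) exp(-times / bleachTau) else 1
    noise <- if (noiseSd > 0) stats::rnorm(n, 0, noiseSd) else 0
    values[, k] <- f0 * bleach * sig + noise
    truth[[k]] <- if (length(st))
      data.frame(cell_id = colnames(values)[k], time_s = st,
                 frame = as.integer(ceiling(st / dt - 1e-9)),
                 amplitude = amp, stringsAsFactors = FALSE)
    else NULL
  }
  truth <- do.call(rbind, truth)
  if (is.null(truth))
    truth <- data.frame(cell_id = character(0), time_s = numeric(0),
                        frame = integer(0), amplitude = numeric(0))
  list(traces = TraceSet(times, values, dye = "Fluo-4",
                         meta = list(seed = seed, noise_sd = noiseSd)),
       truth = truth, plan = plan)
}

# concentration program of one SOCE experiment on the frame grid.
# Within the TG and add-back epochs the kinetic shape is normalized by its
# maximum over the epoch's frames, so the discrete peak equals exactly
# basal + delta (the programmed rise above basal).
soceConcProgram <- function(plan, dt, basalCa, storeReleaseDelta, storeRiseTau,
                            storeDecayTau, soceDelta, soceRiseTau,
                            ionoCa, egtaCa) {
  n <- nFrames(plan)
  conc <- rep(basalCa, n)
  relT <- function(lab) {
    w <- epochWindow(plan, lab)
    list(idx = seq.int(w[["start"]] + 1L, w[["end"]]),
         t = (seq.int(w[["start"]], w[["end"]] - 1L) - w[["start"]]) * dt)
  }
  tg <- relT("tg")
  shape <- (1 - exp(-tg$t / storeRiseTau)) * exp(-tg$t / storeDecayTau)
  if (max(shape) > 0) shape <- shape / max(shape)
  conc[tg$idx] <- basalCa + storeReleaseDelta * shape
  ca <- relT("caadd")
  shape <- 1 - exp(-ca$t / soceRiseTau)
  if (max(shape) > 0) shape <- shape / max(shape)
  conc[ca$idx] <- basalCa + soceDelta * shape
  conc[relT("iono")$idx] <- ionoCa
  conc[relT("egta")$idx] <- egtaCa
  conc
}

#' Simulate a Fura-2 SOCE experiment with known ground truth
#'
#' Forward-simulates the five-epoch store-operated Ca2+ entry protocol
#' (basal in zero-Ca2+ buffer, thapsigargin store release, Ca2+ add-back,
#' ionomycin saturation, EGTA chelation; default 12/84/60/24/24 frames at
#' 5 s, i.e. 17 min). The true per-cell concentration program c(t) is
#' piecewise: constant basal; a rise-and-decay store-release transient whose
#' frame-grid peak equals exactly \code{basalCa + storeReleaseDelta}; a
#' saturating SOCE plateau peaking at exactly \code{basalCa + soceDelta};
#' then the calibration levels \code{ionoCa} (default \code{Inf}: true dye
#' saturation, so the ratio equals Rmax exactly) and \code{egtaCa} (default
#' 0 nM, so the ratio equals Rmin).
#'
#' Channels follow the inverse of the Grynkiewicz relation: the ratio is
#' \deqn{R(t) = \frac{c\,R_{max} + K_d\,SF\,R_{min}}{c + K_d\,SF}}
#' and the 380 nm channel interpolates hyperbolically between its
#' Ca2+-free intensity (\code{sf * f380Bound}) and Ca2+-bound intensity
#' (\code{f380Bound}) with half-point Kd*SF, so that
#' \code{F340 = R * F380} and the two-channel model is algebraically exact
#' under the Grynkiewicz inversion. Independent Gaussian noise is added per
#' channel and frame.
#'
#' @param nCells number of cells.
#' @param dt frame interval, seconds (default 5).
#' @param plan an [EpochPlan-class] with epochs \code{basal, tg, caadd,
#'   iono, egta}; default [socePlan()].
#' @param basalCa resting cytosolic concentration, nM.
#' @param storeReleaseDelta peak rise above basal during thapsigargin, nM.
#' @param storeRiseTau,storeDecayTau store-release transient kinetics, s.
#' @param soceDelta sustained rise above basal after Ca2+ add-back, nM.
#' @param soceRiseTau SOCE plateau rise time constant, s.
#' @param ionoCa concentration during ionomycin, nM (\code{Inf} = saturation).
#' @param egtaCa concentration during EGTA, nM.
#' @param kd,sf,rmin,rmax true calibration constants, scalar or per cell.
#' @param f380Bound Ca2+-bound 380 nm intensity, a.u.
#' @param noiseSd per-channel additive Gaussian noise SD, a.u.
#' @param seed integer master seed (one derived stream per cell).
#' @return list with \code{traces} (a [RatioTraceSet-class]), \code{truth}
#'   (list: \code{conc} true frames x cells concentration matrix in nM;
#'   \code{constants} data frame of per-cell kd, sf, rmin, rmax;
#'   \code{basal}, \code{store_release_delta}, \code{soce_delta}) and
#'   \code{plan}.
#' @examples
#' sim <- simulateSOCE(nCells = 2, seed = 7)
#' sim$truth$constants
#' @export
simulateSOCE <- function(nCells = 25, dt = 5, plan = socePlan(dt = dt),
                         basalCa = 50, storeReleaseDelta = 120,
                         storeRiseTau = 15, storeDecayTau = 60,
                         soceDelta = 200, soceRiseTau = 15,
                         ionoCa = Inf, egtaCa = 0,
                         kd = 225, sf = 2, rmin = 0.5, rmax = 5,
                         f380Bound = 100, noiseSd = 0, seed = 1) {
  nCells <- assertCount(nCells, "nCells")
  dt <- assertScalar(dt, "dt", lower = 1e-12)
  for (lab in c("basal", "tg", "caadd", "iono", "egta"))
    if (!hasEpoch(plan, lab))
      stop(sprintf("SOCE plan must contain an epoch labelled '%s'", lab),
           call. = FALSE)
  assertScalar(basalCa, "basalCa", lower = 0)
  assertScalar(storeReleaseDelta, "storeReleaseDelta", lower = 0)
  assertScalar(soceDelta, "soceDelta", lower = 0)
  assertScalar(ionoCa, "ionoCa", lower = 0, allowInf = TRUE)
  assertScalar(egtaCa, "egtaCa", lower = 0)
  assertScalar(noiseSd, "noiseSd", lower = 0)
  kd <- perCell(kd, nCells, "kd")
  sf <- perCell(sf, nCells, "sf")
  rmin <- perCell(rmin, nCells, "rmin")
  rmax <- perCell(rmax, nCells, "rmax")
  if (any(kd <= 0) || any(sf <= 0) || any(rmin >= rmax))
    stop("require kd > 0, sf > 0 and rmin < rmax", call. = FALSE)

  n <- nFrames(plan)
  times <- dt * (seq_len(n) - 1L)
  ids <- paste0("cell_", seq_len(nCells))
  conc <- soceConcProgram(plan, dt, basalCa, storeReleaseDelta, storeRiseTau,
                          storeDecayTau, soceDelta, soceRiseTau, ionoCa,
                          egtaCa)
  concTruth <- matrix(conc, n, nCells, dimnames = list(NULL, ids))
  a340 <- a380 <- matrix(0, n, nCells, dimnames = list(NULL, ids))
  seeds <- cellSeeds(seed, nCells)
  for (k in seq_len(nCells)) {
    ks <- kd[k] * sf[k]
    R <- ifelse(is.infinite(conc), rmax[k],
                (conc * rmax[k] + ks * rmin[k]) / (conc + ks))
    Fb <- ifelse(is.infinite(conc), f380Bound,
                 f380Bound * (sf[k] * ks + conc) / (ks + conc))
    set.seed(seeds[k])
    n340 <- if (noiseSd > 0) stats::rnorm(n, 0, noiseSd) else 0
    n380 <- if (noiseSd > 0) stats::rnorm(n, 0, noiseSd) else 0
    a340[, k] <- R * Fb + n340
    a380[, k] <- Fb + n380
  }
  traces <- RatioTraceSet(times, a340, a380,
                          meta = list(seed = seed, noise_sd = noiseSd))
  list(traces = traces,
       truth = list(conc = concTruth,
                    constants = data.frame(cell_id = ids, kd = kd, sf = sf,
                                           rmin = rmin, rmax = rmax,
                                           stringsAsFactors = FALSE),
                    basal = basalCa, store_release_delta = storeReleaseDelta,
                    soce_delta = soceDelta),
       plan = plan)
}
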