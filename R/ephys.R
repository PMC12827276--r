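# Trial layout: 5 ms bins, 180 per trial = 40 pre + 100 stimulus + 40 post
# (200 ms + 500 ms + 200 ms), aligned so bin 1 starts 200 ms before onset.
BIN_W <- 0.005
N_BINS <- 180L
PRE_BINS <- 1:40
STIM_BINS <- 41:140
POST_BINS <- 141:180

#' Bin spike times into the trial tensor
#'
#' Aligns sorted spike times to stimulus onsets and counts them into the
#' 180 x 5 ms trial layout (200 ms pre, 500 ms stimulus, 200 ms post), with
#' half-open bins \[t, t + 5 ms).  Spikes outside every trial window are
#' ignored; overlapping trial windows raise a warning (spikes are then
#' counted in every window they fall into).
#'
#' @param spikes data.frame with columns `unit_id`, `time_s`.
#' @param trials data.frame with columns `trial_id`, `onset_s` and any
#'   per-trial covariates (e.g. `irradiance`, `led_row`, `led_col`).
#' @return Object of class `trial_counts`: integer array
#'   (unit x trial x 180) plus the trial table and bin layout.
#' @export
bin_trials <- function(spikes, trials) {
  stopifnot(all(c("unit_id", "time_s") %in% names(spikes)),
            all(c("trial_id", "onset_s") %in% names(trials)))
  if (nrow(trials) == 0) stop("no trials supplied")
  if (is.unsorted(trials$onset_s, strictly = TRUE))
    stop("trial onset times must be strictly increasing")
  if (any(diff(trials$onset_s) < N_BINS * BIN_W - 0.200))
    warning("trial windows overlap; spikes will be counted in each")
  if (any(!is.finite(spikes$time_s))) stop("spike times must be finite")
  units <- sort(unique(spikes$unit_id))
  if (!length(units)) units <- "u0"
  counts <- array(0L, dim = c(length(units), nrow(trials), N_BINS),
                  dimnames = list(unit = as.character(units),
                                  trial = as.character(trials$trial_id),
                                  bin = NULL))
  ui <- match(spikes$unit_id, units)
  nu <- length(units); nt <- nrow(trials)
  w0 <- trials$onset_s - 0.200
  w1 <- trials$onset_s + 0.700
  # half-open bins; the epsilon guards against times like onset + k*5 ms
  # rounding just below their bin edge in floating point
  to_bin <- function(t, start)
    pmin(pmax(floor((t - start) / BIN_W + 1e-9), 0), N_BINS - 1) + 1
  if (all(diff(w0) >= N_BINS * BIN_W)) {
    # non-overlapping windows: one pass with findInterval
    ti <- findInterval(spikes$time_s, w0)
    ok <- ti >= 1 & spikes$time_s < w1[pmax(ti, 1)]
    if (any(ok)) {
      b <- to_bin(spikes$time_s[ok], w0[ti[ok]])
      lin <- (b - 1) * nu * nt + (ti[ok] - 1) * nu + ui[ok]
      counts[] <- counts + array(tabulate(lin, nbins = nu * nt * N_BINS),
                                 dim = dim(counts))
    }
  } else {
    for (t in seq_len(nt)) {
      ok <- spikes$time_s >= w0[t] & spikes$time_s < w1[t]
      if (any(ok)) {
        b <- to_bin(spikes$time_s[ok], w0[t])
        lin <- (b - 1) * nu + ui[ok]
        add <- tabulate(lin, nbins = nu * N_BINS)
        counts[, t, ] <- counts[, t, ] + matrix(add, nrow = nu)
      }
    }
  }
  structure(list(counts = counts, trials = trials, units = units,
                 bin_w = BIN_W, pre = PRE_BINS, stim = STIM_BINS,
                 post = POST_BINS),
            class = "trial_counts")
}

#' Re-bin the trial tensor to 25 ms
#'
#' Sums each block of five 5 ms bins, matching the 25 ms on/off structure of
#' the 20 Hz, 50% duty stimulation protocol (36 bins per trial).
#'
#' @param tc a `trial_counts`.
#' @return unit x trial x 36 integer array.
#' @export
rebin_25ms <- function(tc) {
  stopifnot(inherits(tc, "trial_counts"))
  d <- dim(tc$counts)
  arr <- array(tc$counts, dim = c(d[1], d[2], 5, d[3] / 5))
  apply(arr, c(1, 2, 4), sum)
}

#' Background firing statistics per unit
#'
#' The background is the spiking in the two 200 ms periods flanking the
#' stimulus.  Per-trial background counts are scaled by 500/400 to the
#' stimulus-window duration; mean and standard deviation are taken across
#' trials (or across individual background bins with `sigma = "bins"`).
#'
#' @param tc a `trial_counts`.
#' @param sigma `"trials"` (default) or `"bins"`.
#' @return data.frame with `unit`, `bg_mean`, `bg_sd` on the
#'   stimulus-window count scale, and `bg_rate_hz`.
#' @export
background_stats <- function(tc, sigma = c("trials", "bins")) {
  stopifnot(inherits(tc, "trial_counts"))
  sigma <- match.arg(sigma)
  if (dim(tc$counts)[2] < 1) stop("at least one trial is required")
  bg_bins <- c(tc$pre, tc$post)
  scale <- length(tc$stim) / length(bg_bins)          # 100/80
  per_trial <- apply(tc$counts[, , bg_bins, drop = FALSE], c(1, 2), sum) * scale
  if (sigma == "trials") {
    bg_sd <- apply(per_trial, 1, stats::sd)
  } else {
    # sd over individual background bins, propagated to the 100-bin sum
    per_bin <- tc$counts[, , bg_bins, drop = FALSE]
    bg_sd <- apply(per_bin, 1, stats::sd) * sqrt(length(tc$stim))
  }
  data.frame(unit = dimnames(tc$counts)$unit,
             bg_mean = rowMeans(per_trial),
             bg_sd = bg_sd,
             bg_rate_hz = rowMeans(per_trial) /
               (length(tc$stim) * tc$bin_w))
}

#' Classify units as time-locked to the stimulus
#'
#' A unit is time-locked when its mean stimulus-window spike count per trial
#' exceeds the background mean by more than `k` background standard
#' deviations (one-sided), background statistics per [background_stats()].
#'
#' @param tc a `trial_counts`.
#' @param k threshold in background standard deviations (default 2).
#' @param sigma passed to [background_stats()].
#' @return data.frame with `unit`, `stim_mean`, `bg_mean`, `bg_sd`,
#'   `time_locked`.
#' @export
classify_time_locked <- function(tc, k = 2, sigma = c("trials", "bins")) {
  bg <- background_stats(tc, sigma = match.arg(sigma))
  stim_mean <- rowMeans(apply(tc$counts[, , tc$stim, drop = FALSE],
                              c(1, 2), sum))
  data.frame(unit = bg$unit, stim_mean = stim_mean,
             bg_mean = bg$bg_mean, bg_sd = bg$bg_sd,
             time_locked = stim_mean > bg$bg_mean + k * bg$bg_sd)
}

#' Peri-stimulus time histogram
#'
#' 25 ms-binned average spike counts per trial with each unit's mean
#' background (per 25 ms bin) subtracted before averaging across units.
#'
#' @param tc a `trial_counts`.
#' @param units character vector of unit ids to include (default all).
#' @return data.frame with `t_s` (bin start relative to stimulus onset) and
#'   `rate` (background-subtracted spikes per trial per 25 ms bin).
#' @export
psth <- function(tc, units = NULL) {
  stopifnot(inherits(tc, "trial_counts"))
  all_units <- dimnames(tc$counts)$unit
  if (is.null(units)) units <- all_units
  sel <- match(units, all_units)
  if (!length(sel) || anyNA(sel)) stop("unit selection is empty or unknown")
  arr25 <- rebin_25ms(tc)[sel, , , drop = FALSE]
  per_unit <- apply(arr25, c(1, 3), mean)             # unit x 36
  bg_bins25 <- c(1:8, 29:36)
  bg_per_bin <- rowMeans(per_unit[, bg_bins25, drop = FALSE])
  trace <- colMeans(sweep(per_unit, 1, bg_per_bin))
  data.frame(t_s = (seq_len(36) - 1) * 0.025 - 0.200, rate = trace)
}

# per-unit, per-level mean background-subtracted stimulus counts
unit_level_response <- function(tc, level) {
  stopifnot(length(level) == dim(tc$counts)[2])
  bg <- background_stats(tc)
  stim <- apply(tc$counts[, , tc$stim, drop = FALSE], c(1, 2), sum)
  lv <- sort(unique(level))
  resp <- vapply(lv, function(l)
    rowMeans(stim[, level == l, drop = FALSE]) - bg$bg_mean,
    numeric(nrow(stim)))
  matrix(resp, nrow = nrow(stim), dimnames = list(bg$unit, lv))
}

#' Dose-response curve and activation threshold
#'
#' Pools background-subtracted spikes per trial across units at each
#' irradiance level (pooled mean, pooled SEM = sd of unit means / sqrt(n)),
#' fits a logistic curve with floor fixed at zero,
#' y = ymax / (1 + exp(-(x - x0) / s)), and reports the threshold irradiance
#' where the fit crosses `threshold_spikes` spikes per trial
#' (5 = 50% success on 10 pulses).
#'
#' @param tc a `trial_counts` whose trial table has an `irradiance` column
#'   (or supply `level`).
#' @param units unit ids to pool (default all; typically the time-locked set).
#' @param level per-trial irradiance, mW mm^-2.
#' @param threshold_spikes threshold criterion, spikes per trial.
#' @return List with `points` (level, mean, sem, n), `fit` (coefficients or
#'   `NULL`), `threshold` (mW mm^-2 or `NA`) and `flag`.
#' @export
dose_response <- function(tc, units = NULL, level = tc$trials$irradiance,
                          threshold_spikes = 5) {
  stopifnot(inherits(tc, "trial_counts"))
  if (length(unique(level)) < 3)
    stop("at least 3 irradiance levels are required")
  resp <- unit_level_response(tc, level)
  if (!is.null(units)) resp <- resp[dimnames(resp)[[1]] %in% units, , drop = FALSE]
  if (!nrow(resp)) stop("unit selection is empty")
  lv <- as.numeric(colnames(resp))
  pts <- data.frame(level = lv,
                    mean = colMeans(resp),
                    sem = apply(resp, 2, stats::sd) / sqrt(nrow(resp)),
                    n = nrow(resp))
  # multistart over the slope; a bounded quasi-Newton fallback handles
  # step-like saturating data where the logistic gradient degenerates
  logis3 <- function(p, x) p[1] / (1 + exp(-(x - p[2]) / p[3]))
  cand <- list()
  for (s0 in diff(range(lv)) / c(2, 5, 20)) {
    f <- tryCatch(
      minpack.lm::nlsLM(mean ~ ymax / (1 + exp(-(level - x0) / s)),
                        data = pts,
                        start = list(ymax = max(pts$mean, 1e-3),
                                     x0 = stats::median(lv), s = s0),
                        lower = c(ymax = 0, x0 = -Inf, s = 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(f))
      cand[[length(cand) + 1]] <- list(par = stats::coef(f),
                                       dev = stats::deviance(f))
    o <- tryCatch(
      stats::optim(c(ymax = max(pts$mean, 1e-3), x0 = stats::median(lv),
                     s = s0),
                   function(p) sum((pts$mean - logis3(p, lv))^2),
                   method = "L-BFGS-B",
                   lower = c(1e-6, min(lv) - diff(range(lv)), 1e-3),
                   upper = c(Inf, max(lv) + diff(range(lv)), Inf)),
      error = function(e) NULL)
    if (!is.null(o))
      cand[[length(cand) + 1]] <- list(par = o$par, dev = o$value)
  }
  if (!length(cand))
    return(list(points = pts, fit = NULL, threshold = NA_real_,
                flag = "fit_failed"))
  cf <- cand[[which.min(vapply(cand, `[[`, 0, "dev"))]]$par
  if (cf[["ymax"]] <= threshold_spikes)
    return(list(points = pts, fit = cf, threshold = NA_real_,
                flag = "no_crossing"))
  thr <- cf[["x0"]] - cf[["s"]] * log(cf[["ymax"]] / threshold_spikes - 1)
  list(points = pts, fit = cf, threshold = unname(thr), flag = "ok")
}

#' Weighted Gaussian fit of the spatial response profile
#'
#' Fits y = y0 + A exp(-(x - mu)^2 / (2 sigma^2)) to per-position responses,
#' weighted by 1/SEM^2, with initial values (y0, mu, A, sigma) =
#' (0, -500, 50, 200) and box bounds (\[0, 2\], \[-900, 0\], \[0, 200\],
#' \[100, 1000\]); x is the stimulation-site position in micrometres
#' relative to the recording-probe edge (negative into the array).
#'
#' @param row_responses data.frame with `position_um`, `mean`, `sem`
#'   (sem > 0).
#' @param start,lower,upper override the default initialisation and bounds.
#' @return Object of class `gaussian_fit`: coefficients, standard errors,
#'   `fwhm_um` (2 sqrt(2 ln 2) sigma), `chisq_red` (dof = n - 4).
#' @export
spatial_fit <- function(row_responses,
                        start = c(y0 = 0, mu = -500, A = 50, sigma = 200),
                        lower = c(y0 = 0, mu = -900, A = 0, sigma = 100),
                        upper = c(y0 = 2, mu = 0, A = 200, sigma = 1000)) {
  d <- row_responses
  stopifnot(all(c("position_um", "mean", "sem") %in% names(d)))
  if (nrow(d) < 4) stop("at least 4 points are required for a 4-parameter fit")
  if (any(d$sem <= 0)) stop("SEMs must be positive")
  x <- d$position_um
  model <- function(p) p[1] + p[3] * exp(-(x - p[2])^2 / (2 * p[4]^2))
  jac_w <- function(p) {
    E <- exp(-(x - p[2])^2 / (2 * p[4]^2))
    cbind(1, p[3] * E * (x - p[2]) / p[4]^2, E,
          p[3] * E * (x - p[2])^2 / p[4]^3) / d$sem
  }
  obj <- function(p) sum(((d$mean - model(p)) / d$sem)^2)
  grad <- function(p) -2 * drop(crossprod(jac_w(p), (d$mean - model(p)) / d$sem))
  run <- function(p0) stats::optim(pmin(pmax(p0, lower), upper), obj, grad,
                                   method = "L-BFGS-B", lower = lower,
                                   upper = upper,
                                   control = list(maxit = 1000,
                                                  factr = 1e4))
  # stated initialisation plus a data-driven fallback, keeping the better
  # optimum (the box-constrained surface can trap a single start)
  alt <- c(y0 = min(d$mean), mu = x[which.max(d$mean)],
           A = max(d$mean) - min(d$mean), sigma = unname(start["sigma"]))
  fits <- list(run(unname(start)), run(unname(alt)))
  fit <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  cf <- stats::setNames(fit$par, c("y0", "mu", "A", "sigma"))
  pred <- model(fit$par)
  dof <- nrow(d) - 4
  chisq <- fit$value                         # residuals are SEM-weighted
  J <- jac_w(fit$par)
  se <- tryCatch({
    cov <- solve(crossprod(J)) * if (dof > 0) chisq / dof else 1
    stats::setNames(sqrt(diag(cov)), names(cf))
  }, error = function(e) stats::setNames(rep(NA_real_, 4), names(cf)))
  structure(list(coef = cf, se = se,
                 fwhm_um = unname(2 * sqrt(2 * log(2)) * cf[["sigma"]]),
                 chisq_red = if (dof > 0) chisq / dof else NA_real_,
                 dof = dof, fitted = pred),
            class = "gaussian_fit")
}

#' Band-pass filter and common-average-reference raw extracellular data
#'
#' Zero-phase Butterworth band-pass (300 Hz - 5.5 kHz) per channel followed
#' by subtraction of the across-channel mean at every sample.
#'
#' @param x numeric matrix, samples x channels.
#' @param fs sampling rate, Hz (> 11 kHz so the 5.5 kHz corner is below
#'   Nyquist).
#' @param band filter corners, Hz.
#' @param order Butterworth order.
#' @return Filtered, re-referenced matrix of the same shape.
#' @export
preprocess_raw <- function(x, fs, band = c(300, 5500), order = 3) {
  x <- as.matrix(x)
  if (fs <= 2 * band[2])
    stop("sampling rate must exceed twice the upper band edge")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  filt <- apply(x, 2, function(ch) signal::filtfilt(bf, ch))
  filt - rowMeans(filt)
}

#' Multi-unit activity detection by threshold crossing
#'
#' Events are negative-going crossings of -k sigma per channel, where sigma
#' is the robust noise estimate median(|x|)/0.6745; crossings within the
#' refractory period of a previous event are suppressed.
#'
#' @param x filtered matrix, samples x channels (output of
#'   [preprocess_raw()]).
#' @param fs sampling rate, Hz.
#' @param k threshold multiplier (default 5).
#' @param refractory_s dead time after each event, s.
#' @return List (one element per channel) of event times in seconds.
#' @export
mua_detect <- function(x, fs, k = 5, refractory_s = 0.001) {
  x <- as.matrix(x)
  lapply(seq_len(ncol(x)), function(ch) {
    v <- x[, ch]
    sig <- stats::median(abs(v)) / 0.6745
    if (sig == 0) return(numeric(0))
    thr <- -k * sig
    cross <- which(v[-1] < thr & v[-length(v)] >= thr) + 1
    if (!length(cross)) return(numeric(0))
    keep <- cross[c(TRUE, diff(cross) > refractory_s * fs)]
    # enforce refractory sequentially (diff-based pass can chain)
    out <- keep[1]
    for (t in keep[-1]) if (t - out[length(out)] > refractory_s * fs)
      out <- c(out, t)
    out / fs
  })
}
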