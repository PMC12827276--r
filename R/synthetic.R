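# Seeded generators emulating the experimental protocols: per-LED L-I
# curves with fabrication scatter, stimulus-locked Poisson spike trains and
# go/no-go behavioural event streams.  All are pure functions of
# (seed, parameters): the global RNG state is saved and restored.

#' Default electrical/optical power model of one micro-LED
#'
#' A quadratic optical-power law with an assumed forward voltage of 3.0 V at
#' 3 mA drive (electrical power = V * I); used as the default input to the
#' thermal source builder and the synthetic calibration generator.
#'
#' @param a1,a2 linear/quadratic optical coefficients, mW per mA (mA^2).
#' @param v_fwd forward voltage, V.
#' @return List with functions `electrical_mW(I_mA)` and `optical_mW(I_mA)`.
#' @export
default_li_model <- function(a1 = 0.25, a2 = 0.01, v_fwd = 3.0) {
  list(electrical_mW = function(I_mA) v_fwd * I_mA,
       optical_mW = function(I_mA) pmax(a1 * I_mA + a2 * I_mA^2, 0))
}

#' Ground-truth parameter set for the synthetic generators
#'
#' @param baseline_hz per-unit background firing rate.
#' @param ed50 irradiance of half-maximal locked response, mW mm^-2.
#' @param slope logistic slope of the dose response, mW mm^-2.
#' @param max_spikes_per_trial saturating stimulus-locked spikes per
#'   10-pulse trial.
#' @param sigma_um spatial Gaussian kernel width (100-1000 um).
#' @param go_lick_p initial go-response probability per trial.
#' @param nogo_lick_p no-go response probability.
#' @param background_lick_hz background lick rate.
#' @param learning_increment per-session increment of `go_lick_p` toward 1.
#' @return List of class `ground_truth`.
#' @export
ground_truth <- function(baseline_hz = 2, ed50 = 2.5, slope = 0.5,
                         max_spikes_per_trial = 12, sigma_um = 250,
                         go_lick_p = 0.5, nogo_lick_p = 0.2,
                         background_lick_hz = 0.1,
                         learning_increment = 0.05) {
  stopifnot(baseline_hz >= 0, max_spikes_per_trial >= 0,
            sigma_um >= 100, sigma_um <= 1000,
            go_lick_p >= 0, go_lick_p <= 1,
            nogo_lick_p >= 0, nogo_lick_p <= 1,
            background_lick_hz >= 0)
  structure(as.list(environment()), class = "ground_truth")
}

# closed-form expected locked spikes/trial for a truth at (irradiance, dx)
truth_locked_spikes <- function(truth, irradiance, dx_um = 0) {
  truth$max_spikes_per_trial /
    (1 + exp(-(irradiance - truth$ed50) / truth$slope)) *
    exp(-dx_um^2 / (2 * truth$sigma_um^2))
}

# irradiance at which the expected locked response crosses `spikes`/trial
truth_threshold <- function(truth, spikes = 5, dx_um = 0) {
  top <- truth$max_spikes_per_trial * exp(-dx_um^2 / (2 * truth$sigma_um^2))
  if (top <= spikes) return(NA_real_)
  truth$ed50 - truth$slope * log(top / spikes - 1)
}

#' Generate a synthetic 100-LED calibration set
#'
#' Quadratic current-to-irradiance curves with multiplicative lognormal
#' per-LED scatter emulating fabrication variability; a configurable
#' fraction of LEDs is flagged non-functional (zero output).
#'
#' @param seed RNG seed.
#' @param n number of LEDs (> 0).
#' @param variability lognormal sdlog of the per-LED efficiency (>= 0).
#' @param frac_dead fraction flagged non-functional.
#' @param currents_mA measurement sweep.
#' @param li base L-I model ([default_li_model()]).
#' @param csi_per_mW irradiance delivered per mW of optical output
#'   (scene-dependent calibration constant).
#' @return data.frame with `led_id`, `row`, `col`, `current_mA`,
#'   `power_mW`, `electrical_mW`, `csi`, `functional`.
#' @export
gen_led_array <- function(seed = 1, n = 100, variability = 0.1,
                          frac_dead = 0.02,
                          currents_mA = seq(0.5, 10, by = 0.5),
                          li = default_li_model(), csi_per_mW = 4.4) {
  if (n <= 0) stop("n must be positive")
  stopifnot(variability >= 0, frac_dead >= 0, frac_dead < 1)
  withr::with_seed(seed, {
    eff <- stats::rlnorm(n, 0, variability)
    dead <- stats::runif(n) < frac_dead
    side <- ceiling(sqrt(n))
    grid <- expand.grid(row = 0:(side - 1), col = 0:(side - 1))[seq_len(n), ]
    do.call(rbind, lapply(seq_len(n), function(i) {
      p <- if (dead[i]) 0 * currents_mA else eff[i] * li$optical_mW(currents_mA)
      data.frame(led_id = i, row = grid$row[i], col = grid$col[i],
                 current_mA = currents_mA, power_mW = p,
                 electrical_mW = li$electrical_mW(currents_mA),
                 csi = p * csi_per_mW, functional = !dead[i])
    }))
  })
}

#' Generate synthetic spike and trial tables
#'
#' Inhomogeneous-Poisson spike trains: a constant baseline plus a
#' stimulus-locked rate active only during the ten 25 ms pulse-on epochs
#' (20 Hz, 50% duty), scaled by a logistic dose response in irradiance and
#' a Gaussian falloff with lateral LED-probe distance.  Trials step through
#' LED positions and irradiance levels in pseudorandom order at one trial
#' per second (500 ms stimulus + 500 ms wait).
#'
#' @param seed RNG seed.
#' @param truth a [ground_truth()].
#' @param n_units number of units (>= 1).
#' @param n_trials trials per LED/irradiance combination (>= 1).
#' @param levels irradiance levels, mW mm^-2 (protocol default: the five
#'   tested cortical irradiances).
#' @param positions_um LED positions relative to the probe edge, um
#'   (negative into the array; 200 um pitch).
#' @return List with `spikes` (unit_id, time_s), `trials` (trial_id,
#'   led_row, led_col, irradiance, position_um, onset_s) and `truth`.
#' @export
gen_ephys <- function(seed = 1, truth = ground_truth(), n_units = 16,
                      n_trials = 50,
                      levels = c(1.0, 1.2, 2.8, 3.2, 4.6),
                      positions_um = -seq(0, 900, by = 200) * 1) {
  stopifnot(n_units >= 1, n_trials >= 1)
  if (truth$baseline_hz < 0 || truth$max_spikes_per_trial < 0)
    stop("rates must be non-negative")
  combos <- expand.grid(level = levels, pos = positions_um)
  plan <- combos[rep(seq_len(nrow(combos)), n_trials), ]
  withr::with_seed(seed, {
    plan <- plan[sample.int(nrow(plan)), ]
    plan$onset_s <- seq_len(nrow(plan)) * 1.0
    pulse_starts <- seq(0, by = 0.050, length.out = 10)
    sp <- vector("list", n_units)
    for (u in seq_len(n_units)) {
      # baseline across the whole session (plus margins)
      t_max <- max(plan$onset_s) + 1
      n_bg <- stats::rpois(1, truth$baseline_hz * t_max)
      t_bg <- sort(stats::runif(n_bg, 0, t_max))
      t_ev <- t_bg
      for (tr in seq_len(nrow(plan))) {
        mu <- truth_locked_spikes(truth, plan$level[tr], plan$pos[tr])
        n_ev <- stats::rpois(1, mu)
        if (n_ev > 0) {
          ep <- sample.int(10, n_ev, replace = TRUE)
          t_ev <- c(t_ev, plan$onset_s[tr] + pulse_starts[ep] +
                      stats::runif(n_ev, 0, 0.025))
        }
      }
      sp[[u]] <- data.frame(unit_id = sprintf("u%02d", u),
                            time_s = sort(t_ev))
    }
    spikes <- do.call(rbind, sp)
  })
  trials <- data.frame(trial_id = seq_len(nrow(plan)),
                       led_row = 0L,
                       led_col = as.integer(-plan$pos / 200),
                       irradiance = plan$level,
                       position_um = plan$pos,
                       onset_s = plan$onset_s)
  list(spikes = spikes, trials = trials, truth = truth)
}

#' Generate synthetic behavioural sessions
#'
#' Lick (or beam-break) event streams: a background Poisson process plus a
#' stimulus-conditioned response with exponential latency (mean 150 ms);
#' the go-response probability increments session over session toward 1
#' (learning).  Freely-behaving sessions emit beam intervals whose in-window
#' cumulative duration crosses the 75% criterion on responded trials.
#'
#' @param seed RNG seed.
#' @param truth a [ground_truth()].
#' @param n_sessions number of sessions.
#' @param trials_per_session trials per session.
#' @param mode `"association"`, `"discrimination"` or `"freely"`.
#' @return List of sessions; each has `trials`, and `licks` (head-fixed) or
#'   `beam` (freely), plus `p_go` used.
#' @export
gen_behavior <- function(seed = 1, truth = ground_truth(), n_sessions = 1,
                         trials_per_session = 300,
                         mode = c("discrimination", "association",
                                  "freely")) {
  mode <- match.arg(mode)
  if (truth$go_lick_p > 1 || truth$go_lick_p < 0 ||
      truth$nogo_lick_p > 1 || truth$nogo_lick_p < 0)
    stop("response probabilities must lie in [0, 1]")
  lapply(seq_len(n_sessions), function(s) {
    p_go <- min(truth$go_lick_p + (s - 1) * truth$learning_increment, 1)
    plan <- sequence_trials(mode, trials_per_session, seed = seed + 1000 * s)
    withr::with_seed(seed + 1000 * s + 1, {
      if (mode == "freely") {
        # in-beam time: responders dwell past the criterion, others leave early
        respond <- ifelse(plan$type == "go",
                          stats::runif(nrow(plan)) < p_go,
                          stats::runif(nrow(plan)) < truth$nogo_lick_p)
        dwell <- ifelse(respond,
                        stats::runif(nrow(plan), 0.80, 1.0),
                        stats::runif(nrow(plan), 0.05, 0.60))
        beam <- data.frame(start_s = plan$onset_s,
                           end_s = plan$onset_s + dwell)
        list(trials = plan, beam = beam, p_go = p_go)
      } else {
        t_end <- max(plan$onset_s) + 3
        n_bg <- stats::rpois(1, truth$background_lick_hz * t_end)
        licks <- stats::runif(n_bg, 0, t_end)
        respond <- ifelse(plan$type == "go",
                          stats::runif(nrow(plan)) < p_go,
                   ifelse(plan$type == "nogo",
                          stats::runif(nrow(plan)) < truth$nogo_lick_p,
                          FALSE))
        lat <- pmin(stats::rexp(nrow(plan), 1 / 0.150), 2.2)
        # a responded trial produces a short lick bout
        bout <- lapply(which(respond), function(i)
          plan$onset_s[i] + lat[i] + c(0, 0.12, 0.25))
        licks <- sort(c(licks, unlist(bout)))
        list(trials = plan, licks = licks, p_go = p_go)
      }
    })
  })
}
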