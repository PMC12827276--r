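# Protocol defaults: head-fixed sessions use a fixed 2.3 s response window,
# randomised 1-2 s inter-trial interval, 3-5 s no-lick period and 5-7 s
# false-alarm penalty; freely-behaving sessions use a 1 s response window
# with a 75% cumulative beam-break criterion, 3-4 s time-out and 1-2 s
# refractory period.

#' Generate a go/no-go trial plan
#'
#' Draws trial types and timing for one session.  The association protocol
#' presents go trials with 90% probability (otherwise blank); discrimination
#' presents go/no-go/blank with probabilities 47.5/47.5/5%; the
#' freely-behaving protocol uses the same go/no-go mix without blanks.
#'
#' @param protocol `"association"`, `"discrimination"` or `"freely"`.
#' @param n_trials number of trials (>= 1).
#' @param seed RNG seed; same seed gives an identical plan.
#' @param p override the type probabilities, a named vector over
#'   `go`, `nogo`, `blank` summing to 1.
#' @return data.frame with `trial_id`, `type`, `iti_s`, `no_lick_s`,
#'   `onset_s`, `response_window_s` and mode attributes.
#' @export
sequence_trials <- function(protocol = c("association", "discrimination",
                                         "freely"),
                            n_trials, seed = 1, p = NULL) {
  protocol <- match.arg(protocol)
  stopifnot(n_trials >= 1)
  if (is.null(p))
    p <- switch(protocol,
                association = c(go = 0.90, nogo = 0, blank = 0.10),
                discrimination = c(go = 0.475, nogo = 0.475, blank = 0.05),
                freely = c(go = 0.5, nogo = 0.5, blank = 0))
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("type probabilities must be non-negative and sum to 1")
  rw <- if (protocol == "freely") 1.0 else 2.3
  withr::with_seed(seed, {
    type <- sample(names(p), n_trials, replace = TRUE, prob = p)
    if (protocol == "freely") {
      refractory <- stats::runif(n_trials, 1, 2)
      approach <- stats::runif(n_trials, 0.5, 3)   # time to re-enter the beam
      onset <- cumsum(refractory + approach + rw)
      data.frame(trial_id = seq_len(n_trials), type = type,
                 iti_s = refractory, no_lick_s = 0,
                 onset_s = onset - rw, response_window_s = rw)
    } else {
      iti <- stats::runif(n_trials, 1, 2)
      no_lick <- stats::runif(n_trials, 3, 5)
      onset <- cumsum(iti + no_lick + rw) - rw
      data.frame(trial_id = seq_len(n_trials), type = type,
                 iti_s = iti, no_lick_s = no_lick,
                 onset_s = onset, response_window_s = rw)
    }
  }) -> plan
  attr(plan, "protocol") <- protocol
  attr(plan, "mode") <- if (protocol == "freely") "freely" else "headfixed"
  plan
}

#' Score a head-fixed lick session
#'
#' A single lick within the half-open response window \[onset, onset + W)
#' registers a response: go -> hit (reward at the first lick) or miss;
#' no-go -> false alarm (penalty) or correct rejection; blank trials are
#' recorded as `blank_lick`/`blank_nolick` and never rewarded or penalised.
#'
#' @param trials trial plan (see [sequence_trials()]), columns `trial_id`,
#'   `type`, `onset_s`, `response_window_s`.
#' @param licks numeric vector of lick timestamps, s.
#' @return data.frame with `trial_id`, `type`, `outcome`, `latency_s`,
#'   `n_licks` (licks inside the window).
#' @export
score_headfixed <- function(trials, licks) {
  if (is.unsorted(licks)) {
    warning("lick times were unordered; sorting")
    licks <- sort(licks)
  }
  W <- trials$response_window_s
  out <- lapply(seq_len(nrow(trials)), function(i) {
    in_win <- licks[licks >= trials$onset_s[i] &
                    licks < trials$onset_s[i] + W[i]]
    licked <- length(in_win) > 0
    outcome <- switch(trials$type[i],
      go = if (licked) "hit" else "miss",
      nogo = if (licked) "false_alarm" else "correct_rejection",
      blank = if (licked) "blank_lick" else "blank_nolick")
    data.frame(trial_id = trials$trial_id[i], type = trials$type[i],
               outcome = outcome,
               latency_s = if (licked) in_win[1] - trials$onset_s[i]
                           else NA_real_,
               n_licks = length(in_win))
  })
  do.call(rbind, out)
}

# total overlap (s) of intervals [start, end] with window [w0, w1)
interval_overlap <- function(start, end, w0, w1) {
  sum(pmax(0, pmin(end, w1) - pmax(start, w0)))
}

#' Score a freely-behaving beam-break session
#'
#' A trial is a response when the cumulative in-beam time inside the 1 s
#' response window reaches at least 75% of the window; intervals spanning
#' the window edges contribute only their intersection.
#'
#' @param trials trial plan with `trial_id`, `type`, `onset_s`,
#'   `response_window_s`.
#' @param beam data.frame with `start_s`, `end_s` beam-break intervals.
#' @param criterion fraction of the response window required (default 0.75).
#' @return data.frame with `trial_id`, `type`, `outcome`, `in_beam_s`.
#' @export
score_freely <- function(trials, beam, criterion = 0.75) {
  stopifnot(all(c("start_s", "end_s") %in% names(beam)))
  if (nrow(beam) > 1) {
    o <- order(beam$start_s)
    beam <- beam[o, ]
    if (any(beam$start_s[-1] < beam$end_s[-nrow(beam)])) {
      warning("overlapping beam intervals; merging")
      merged <- beam[1, ]
      for (i in 2:nrow(beam)) {
        last <- nrow(merged)
        if (beam$start_s[i] <= merged$end_s[last])
          merged$end_s[last] <- max(merged$end_s[last], beam$end_s[i])
        else merged <- rbind(merged, beam[i, ])
      }
      beam <- merged
    }
  }
  out <- lapply(seq_len(nrow(trials)), function(i) {
    w0 <- trials$onset_s[i]
    w1 <- w0 + trials$response_window_s[i]
    tb <- interval_overlap(beam$start_s, beam$end_s, w0, w1)
    responded <- tb >= criterion * trials$response_window_s[i]
    outcome <- switch(trials$type[i],
      go = if (responded) "hit" else "miss",
      nogo = if (responded) "false_alarm" else "correct_rejection",
      blank = if (responded) "blank_lick" else "blank_nolick")
    data.frame(trial_id = trials$trial_id[i], type = trials$type[i],
               outcome = outcome, in_beam_s = tb)
  })
  do.call(rbind, out)
}

#' Session accuracy with background-lick correction
#'
#' For head-fixed sessions, a licked trial only counts as a response when
#' its in-window lick count exceeds the session's background by more than
#' 2 sigma; the background is estimated from inter-trial licks, normalised
#' per response-window-equivalent duration.  Association accuracy is the
#' percentage of go trials with a valid response; discrimination accuracy is
#' (valid go responses + no-go non-responses) / (go + no-go).  Freely-moving
#' accuracy is the proportion of correct trials (hits + correct rejections).
#' Blank trials never enter the denominator.
#'
#' @param outcomes output of [score_headfixed()] or [score_freely()].
#' @param trials the trial plan used for scoring.
#' @param licks lick timestamps (head-fixed modes; used for the background
#'   estimate).
#' @param mode `"association"`, `"discrimination"` or `"freely"`.
#' @param k background threshold in standard deviations.
#' @return List with `accuracy_pct`, `background` (rate mean/sd per window),
#'   and `valid` per-trial logical (head-fixed) or `NULL`.
#' @export
session_accuracy <- function(outcomes, trials, licks = NULL,
                             mode = c("discrimination", "association",
                                      "freely"),
                             k = 2) {
  mode <- match.arg(mode)
  nb <- outcomes$type != "blank"
  if (!any(nb)) stop("no non-blank trials in session")
  if (mode == "freely") {
    correct <- outcomes$outcome %in% c("hit", "correct_rejection")
    return(list(accuracy_pct = 100 * mean(correct[nb]),
                background = NULL, valid = NULL))
  }
  stopifnot(!is.null(licks))
  W <- trials$response_window_s
  # background: licks between the end of each response window and the next
  # trial's onset, scaled to counts per response-window duration
  win_end <- trials$onset_s + W
  iti_start <- win_end[-length(win_end)]
  iti_end <- trials$onset_s[-1]
  dur <- iti_end - iti_start
  ok <- dur > 0
  if (!any(ok)) stop("no inter-trial time; background lick rate undefined")
  bg_counts <- vapply(which(ok), function(i)
    sum(licks >= iti_start[i] & licks < iti_end[i]) / dur[i] * W[i], 0)
  bg_mean <- mean(bg_counts); bg_sd <- stats::sd(bg_counts)
  valid_resp <- outcomes$n_licks > bg_mean + k * bg_sd
  go <- outcomes$type == "go"; nogo <- outcomes$type == "nogo"
  acc <- if (mode == "association") {
    100 * sum(go & valid_resp) / sum(go)
  } else {
    100 * (sum(go & valid_resp) + sum(nogo & !valid_resp)) /
      sum(go | nogo)
  }
  list(accuracy_pct = acc,
       background = c(mean = bg_mean, sd = bg_sd),
       valid = valid_resp)
}

#' Best consecutive-trial accuracy
#'
#' Maximum accuracy over every window of `window` consecutive trials
#' (blank trials slide with the window but are excluded from the accuracy
#' denominator); ties resolve to the earliest window.  Sessions shorter
#' than `window` are scored whole and flagged.
#'
#' @param outcomes scored outcomes in trial order, with a `correct` column
#'   or the standard `outcome`/`type` columns (correct = hit or correct
#'   rejection; for association-style scoring pass `correct` explicitly).
#' @param window number of consecutive trials (default 500).
#' @return List with `accuracy_pct`, `start` (first trial index of the best
#'   window), `whole_session` flag.
#' @export
best_window_accuracy <- function(outcomes, window = 500) {
  if (!nrow(outcomes)) stop("no outcomes supplied")
  correct <- if ("correct" %in% names(outcomes)) outcomes$correct
             else outcomes$outcome %in% c("hit", "correct_rejection")
  counted <- outcomes$type != "blank"
  n <- nrow(outcomes)
  if (n < window)
    return(list(accuracy_pct = 100 * sum(correct & counted) / sum(counted),
                start = 1L, whole_session = TRUE))
  cs_c <- cumsum(c(0, correct & counted))
  cs_n <- cumsum(c(0, counted))
  starts <- seq_len(n - window + 1)
  num <- cs_c[starts + window] - cs_c[starts]
  den <- cs_n[starts + window] - cs_n[starts]
  acc <- ifelse(den > 0, num / den, 0)
  best <- which.max(acc)
  list(accuracy_pct = 100 * acc[best], start = best, whole_session = FALSE)
}
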