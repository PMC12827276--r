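# Go/no-go trial sequencing, scoring and accuracy.

test_that("trial plans draw the protocol type mix", {
  plan <- sequence_trials("discrimination", 10000, seed = 2)
  frac <- table(factor(plan$type, c("go", "nogo", "blank"))) / 10000
  for (p in list(c("go", 0.475), c("nogo", 0.475), c("blank", 0.05))) {
    ci <- 3 * sqrt(as.numeric(p[2]) * (1 - as.numeric(p[2])) / 10000)
    expect_lt(abs(frac[[p[1]]] - as.numeric(p[2])), ci + 1e-9)
  }
  assoc <- sequence_trials("association", 500, seed = 3)
  expect_equal(sum(assoc$type == "nogo"), 0)
  expect_identical(sequence_trials("freely", 50, seed = 9),
                   sequence_trials("freely", 50, seed = 9))
  expect_error(sequence_trials("discrimination", 10, p = c(go = 0.7, nogo = 0.7,
                                                           blank = -0.4)),
               "probabilities")
  # timing randomisation stays in the stated ranges
  expect_true(all(plan$iti_s >= 1 & plan$iti_s <= 2))
  expect_true(all(plan$no_lick_s >= 3 & plan$no_lick_s <= 5))
  expect_equal(unique(plan$response_window_s), 2.3)
})

test_that("head-fixed scoring applies the lick rules at the boundaries", {
  trials <- data.frame(trial_id = 1:4, type = c("go", "nogo", "go", "blank"),
                       onset_s = c(10, 20, 30, 40),
                       response_window_s = 2.3)
  licks <- c(10.5, 22.2, 32.4, 40.1)
  oc <- score_headfixed(trials, licks)
  expect_equal(oc$outcome, c("hit", "false_alarm", "miss", "blank_lick"))
  expect_equal(oc$latency_s[1], 0.5)
  expect_true(is.na(oc$latency_s[3]))      # lick at +2.4 s is outside 2.3 s
  expect_warning(score_headfixed(trials, c(22.2, 10.5)), "unordered")
})

test_that("freely-behaving scoring uses the 75% cumulative criterion", {
  trials <- data.frame(trial_id = 1:3, type = c("go", "nogo", "go"),
                       onset_s = c(10, 20, 30), response_window_s = 1)
  beam <- data.frame(start_s = c(10.0, 20.1, 29.5),
                     end_s = c(10.8, 20.84, 30.5))
  oc <- score_freely(trials, beam)
  expect_equal(oc$outcome[1], "hit")                 # 0.8 s >= 0.75 s
  expect_equal(oc$outcome[2], "correct_rejection")   # 0.74 s < 0.75 s
  # interval spanning the window edge counts only its intersection
  expect_equal(oc$in_beam_s[3], 0.5)
  expect_equal(oc$outcome[3], "miss")
  expect_warning(score_freely(trials,
                              data.frame(start_s = c(10, 10.4),
                                         end_s = c(10.6, 10.9))),
                 "overlap")
})

test_that("interval clipping matches a brute-force oracle", {
  withr::with_seed(12, {
    for (rep in 1:20) {
      w0 <- stats::runif(1, 0, 10); w1 <- w0 + 1
      a <- sort(stats::runif(8, 0, 11))
      b <- pmin(a + stats::runif(8, 0, 0.5), c(a[-1], Inf))  # disjoint
      got <- cortiled:::interval_overlap(a, b, w0, w1)
      # oracle: fine time grid membership
      tt <- seq(0, 12, by = 1e-4)
      inb <- rep(FALSE, length(tt))
      for (i in seq_along(a)) inb <- inb | (tt >= a[i] & tt < b[i])
      oracle <- sum(inb & tt >= w0 & tt < w1) * 1e-4
      expect_lt(abs(got - oracle), 5e-3)
    }
  })
})

test_that("every non-blank trial maps to exactly one of four outcomes", {
  s <- gen_behavior(seed = 21, n_sessions = 1, trials_per_session = 300)[[1]]
  oc <- score_headfixed(s$trials, s$licks)
  nb <- oc$type != "blank"
  expect_true(all(oc$outcome[nb] %in%
                  c("hit", "miss", "correct_rejection", "false_alarm")))
  expect_true(all(oc$outcome[!nb] %in% c("blank_lick", "blank_nolick")))
  expect_equal(nrow(oc), nrow(s$trials))
})

test_that("session accuracy applies the background-lick correction", {
  trials <- sequence_trials("discrimination", 200, seed = 8)
  # zero licks: association accuracy 0
  oc0 <- score_headfixed(trials, numeric(0))
  a0 <- session_accuracy(oc0, trials, numeric(0), mode = "association")
  expect_equal(a0$accuracy_pct, 0)
  # perfect discriminator: lick on every go, never otherwise
  licks <- trials$onset_s[trials$type == "go"] + 0.3
  ocp <- score_headfixed(trials, licks)
  ap <- session_accuracy(ocp, trials, licks, mode = "discrimination")
  expect_equal(ap$accuracy_pct, 100)
  # generated sessions with known response probability land on it
  tr <- ground_truth(go_lick_p = 0.8, nogo_lick_p = 0.2,
                     background_lick_hz = 0)
  s <- gen_behavior(seed = 9, truth = tr, trials_per_session = 500)[[1]]
  oc <- score_headfixed(s$trials, s$licks)
  acc <- session_accuracy(oc, s$trials, s$licks, mode = "discrimination")
  expect_lt(abs(acc$accuracy_pct - 80), 3 * sqrt(0.8 * 0.2 / 500) * 100 + 1)
  # freely mode scores proportion correct
  sf <- gen_behavior(seed = 10, truth = tr, mode = "freely",
                     trials_per_session = 400)[[1]]
  ocf <- score_freely(sf$trials, sf$beam)
  af <- session_accuracy(ocf, sf$trials, mode = "freely")
  expect_lt(abs(af$accuracy_pct - 80), 3 * sqrt(0.8 * 0.2 / 400) * 100 + 1)
  expect_gte(af$accuracy_pct, 0); expect_lte(af$accuracy_pct, 100)
})

test_that("best-window accuracy equals the brute-force scan", {
  withr::with_seed(5, {
    n <- 1200
    oc <- data.frame(type = sample(c("go", "nogo", "blank"), n, TRUE,
                                   c(0.475, 0.475, 0.05)),
                     correct = stats::runif(n) < 0.7)
  })
  got <- best_window_accuracy(oc, window = 500)
  # oracle: explicit O(n w) scan
  best <- -1; best_i <- NA
  for (i in 1:(n - 499)) {
    w <- oc[i:(i + 499), ]
    a <- sum(w$correct & w$type != "blank") / sum(w$type != "blank")
    if (a > best) { best <- a; best_i <- i }
  }
  expect_equal(got$accuracy_pct, 100 * best)
  expect_equal(got$start, best_i)
  # alternating outcomes give 50% in any window
  alt <- data.frame(type = rep("go", 600),
                    correct = rep(c(TRUE, FALSE), 300))
  expect_equal(best_window_accuracy(alt, window = 500)$accuracy_pct, 50)
  # an embedded perfect block is found
  blk <- data.frame(type = rep("go", 1500),
                    correct = c(rep(FALSE, 400), rep(TRUE, 500),
                                rep(FALSE, 600)))
  expect_equal(best_window_accuracy(blk, window = 500)$accuracy_pct, 100)
  short <- best_window_accuracy(alt[1:100, ], window = 500)
  expect_true(short$whole_session)
  expect_error(best_window_accuracy(alt[0, ]), "outcomes")
})

test_that("learning sessions produce monotonically improving accuracy", {
  tr <- ground_truth(go_lick_p = 0.35, nogo_lick_p = 0.2,
                     background_lick_hz = 0.05, learning_increment = 0.06)
  ss <- gen_behavior(seed = 14, truth = tr, n_sessions = 10,
                     trials_per_session = 400)
  accs <- vapply(ss, function(s) {
    oc <- score_headfixed(s$trials, s$licks)
    session_accuracy(oc, s$trials, s$licks, "discrimination")$accuracy_pct
  }, 0)
  rho <- stats::cor(seq_along(accs), accs, method = "spearman")
  expect_gt(rho, 0.9)
})
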