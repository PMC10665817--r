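test_that("speed_from_coords implements the two-point formula", {
  # stationary point
  expect_equal(as.numeric(speed_from_coords(rep(1, 5), rep(2, 5), 0:4)),
               rep(0, 4))
  # 3-4-5 triangle per 1-s step
  n <- 11
  sp <- speed_from_coords(3 * (0:10), 4 * (0:10), 0:10)
  expect_equal(as.numeric(sp), rep(5, 10))
  expect_equal(attr(sp, "time_s"), 1:10)

  # random walk vs an independent elementwise loop oracle
  set.seed(3)
  x <- cumsum(rnorm(100)); y <- cumsum(rnorm(100))
  t <- cumsum(runif(100, 0.5, 1.5))
  got <- as.numeric(speed_from_coords(x, y, t))
  oracle <- vapply(2:100, function(i)
    sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2) / (t[i] - t[i - 1]),
    numeric(1))
  expect_equal(got, oracle, tolerance = 1e-12)

  expect_error(speed_from_coords(1:3, 1:3, c(0, 1, 1)), class = "ff_data_error")
})

test_that("mobility_score min-max normalizes per session", {
  tr <- mobility_score(c(0, 5, 10), time_s = 0:2)
  expect_equal(tr$mobility, c(0, 0.5, 1))
  expect_false(attr(tr, "degenerate"))

  const <- mobility_score(rep(2, 10), time_s = 0:9)
  expect_equal(const$mobility, rep(0, 10))
  expect_true(attr(const, "degenerate"))

  set.seed(1)
  any_tr <- mobility_score(rexp(100), time_s = 0:99)
  expect_equal(min(any_tr$mobility), 0)
  expect_equal(max(any_tr$mobility), 1)
})

test_that("detect_bouts applies the threshold and duration rules", {
  rate <- 10
  # fully immobile session: one immobility bout, no mobility bout
  tr <- make_track(rep(0.05, 101), rate)
  b <- detect_bouts(tr)
  expect_equal(nrow(b), 1)
  expect_equal(b$label, "immobility")
  expect_equal(c(b$start_s, b$end_s), c(0, 10))

  # a 1.5-s sub-threshold run is too short to count
  tr2 <- make_track(c(rep(0.05, 15), rep(0.8, 85)), rate)
  b2 <- detect_bouts(tr2)
  expect_equal(b2$label, "mobility")
  expect_equal(nrow(b2), 1)

  # boundary strictness: a sample exactly at 0.1 is mobile
  tr3 <- make_track(c(rep(0.1, 30), rep(0.8, 30)), rate)
  expect_equal(detect_bouts(tr3)$label, "mobility")
  tr4 <- make_track(c(rep(0.0999, 30), rep(0.8, 30)), rate)
  expect_equal(detect_bouts(tr4)$label[1], "immobility")

  # duration boundary: exactly 2.0 s counts, one sample less does not
  tr5 <- make_track(c(rep(0.05, 20), rep(0.8, 80)), rate)  # run spans 2.0 s
  expect_true("immobility" %in% detect_bouts(tr5)$label)
  tr6 <- make_track(c(rep(0.05, 19), rep(0.8, 81)), rate)  # spans 1.9 s
  expect_false("immobility" %in% detect_bouts(tr6)$label)
})

test_that("detect_bouts matches a run-length oracle on a square wave", {
  rate <- 10
  m <- rep(c(rep(0.05, 30), rep(0.8, 30)), 5)  # 3 s / 3 s alternation, 30 s
  b <- detect_bouts(make_track(m, rate))
  imm <- b[b$label == "immobility", ]
  mob <- b[b$label == "mobility", ]
  expect_equal(nrow(imm), 5)
  expect_equal(nrow(mob), 5)
  expect_equal(imm$end_s, c(3, 9, 15, 21, 27), tolerance = 1e-9)
  # tiling invariant
  expect_equal(sum(b$end_s - b$start_s),
               attr(b, "session_end_s") - attr(b, "session_start_s"),
               tolerance = 1e-9)
  expect_true(all(b$start_s[-1] == b$end_s[-nrow(b)]))
})

test_that("detect_bouts recovers bouts planted by the generator", {
  ses <- generate_session(small_config(duration_s = 300))
  b <- detect_bouts(ses$behavior)
  planted <- ses$ground_truth$bouts
  got_onsets <- b$start_s[b$label == "mobility" & b$start_s > 0]
  true_onsets <- planted$start_s[planted$label == "mobility"]
  expect_equal(length(got_onsets), length(true_onsets))
  expect_lt(max(abs(got_onsets - true_onsets)), 0.15)
})

test_that("detect_consumption merges, thresholds and stays idempotent", {
  # single sufficient contact
  one <- event_series(start_s = 10.0, end_s = 10.8, label = "lick")
  expect_equal(as.data.frame(detect_consumption(one)),
               data.frame(start_s = 10.0, end_s = 10.8), ignore_attr = TRUE)
  # merge across a 0.3-s gap
  merged <- detect_consumption(event_series(start_s = c(5.0, 5.5),
                                            end_s = c(5.2, 6.3)))
  expect_equal(as.data.frame(merged), data.frame(start_s = 5.0, end_s = 6.3),
               ignore_attr = TRUE)
  # a 0.3-s isolated contact is dropped
  expect_equal(nrow(detect_consumption(
    event_series(start_s = 3.0, end_s = 3.3))), 0)

  # boundary cases one sample either side of each threshold
  # gap exactly 1.0 s does NOT merge; 0.99 s does
  split2 <- detect_consumption(event_series(start_s = c(1.0, 2.6),
                                            end_s = c(1.6, 3.2)))
  expect_equal(nrow(split2), 2)
  join2 <- detect_consumption(event_series(start_s = c(1.0, 2.59),
                                           end_s = c(1.6, 3.2)))
  expect_equal(nrow(join2), 1)
  # duration exactly 0.5 s kept, 0.49 s dropped
  expect_equal(nrow(detect_consumption(
    event_series(start_s = 1, end_s = 1.5))), 1)
  expect_equal(nrow(detect_consumption(
    event_series(start_s = 1, end_s = 1.49))), 0)

  # idempotence: feeding the output back returns it unchanged
  licks <- generate_lick_train(small_config())
  ev <- detect_consumption(licks)
  expect_equal(as.data.frame(detect_consumption(ev)), as.data.frame(ev))
  # order-insensitivity
  o <- sample(nrow(licks))
  shuffled <- event_series(start_s = licks$start_s[o], end_s = licks$end_s[o])
  expect_equal(as.data.frame(detect_consumption(shuffled)),
               as.data.frame(ev))

  expect_error(detect_consumption(
    event_series(times_s = c(1, 2))), class = "ff_data_error")
})

test_that("select_events returns onsets at boundaries and cleared random times", {
  rate <- 10
  m <- rep(c(rep(0.05, 100), rep(0.8, 100)), 3)  # 10-s alternating bouts
  b <- detect_bouts(make_track(m, rate))
  ev <- select_events(b, n_random = 5, window_s = 6, seed = 1)
  expect_named(ev, c("mobility_onset", "immobility_onset",
                     "random_mobility", "random_immobility"))
  expect_equal(ev$mobility_onset$time_s, c(10, 30, 50), tolerance = 1e-9)
  expect_equal(ev$immobility_onset$time_s, c(20, 40), tolerance = 1e-9)
  # random events have >= window/2 clearance inside their bouts
  for (kind in c("random_mobility", "random_immobility")) {
    for (tt in ev[[kind]]$time_s) {
      host <- b[b$start_s <= tt & b$end_s >= tt, ]
      expect_gte(tt - host$start_s, 3)
      expect_gte(host$end_s - tt, 3)
    }
  }
  # seeded determinism
  ev2 <- select_events(b, n_random = 5, window_s = 6, seed = 1)
  expect_identical(ev, ev2)

  # an immobility bout too short for the window yields empty + warning
  m3 <- c(rep(0.8, 100), rep(0.05, 40), rep(0.8, 100))  # 4-s immobility
  b3 <- detect_bouts(make_track(m3, rate))
  expect_warning(
    ev3 <- select_events(b3, kinds = "random_immobility", n_random = 5,
                         window_s = 6, seed = 1),
    class = "ff_no_eligible_bout_warning")
  expect_equal(nrow(ev3$random_immobility), 0)
})

test_that("ANY-maze style state exports parse into intervals", {
  df <- data.frame(Time = seq(0, 5, by = 0.5),
                   State = c(0, 1, 1, 0, 0, 1, 1, 1, 0, 0, 0))
  p <- tempfile(fileext = ".csv"); utils::write.csv(df, p, row.names = FALSE)
  ev <- read_anymaze_events(p, label = "laser")
  expect_equal(ev$start_s, c(0.5, 2.5))
  expect_equal(ev$end_s, c(1.5, 4.0))
  expect_error(read_anymaze_events(p, state_col = "Laser"),
               class = "ff_format_error")
})

test_that("DeepLabCut coordinate exports parse by body part", {
  lines <- c("scorer,model,model,model,model,model,model",
             "bodyparts,head,head,head,tail,tail,tail",
             "coords,x,y,likelihood,x,y,likelihood",
             "0,1.0,2.0,0.99,5.0,6.0,0.98",
             "1,1.5,2.5,0.97,5.5,6.5,0.96")
  p <- tempfile(fileext = ".csv"); writeLines(lines, p)
  head_xy <- read_dlc_coords(p, "head", rate_hz = 20)
  expect_equal(head_xy$x, c(1.0, 1.5))
  expect_equal(head_xy$y, c(2.0, 2.5))
  expect_equal(head_xy$time_s, c(0, 0.05))
  tail_xy <- read_dlc_coords(p, "tail")
  expect_equal(tail_xy$x, c(5.0, 5.5))
  expect_error(read_dlc_coords(p, "ear"), class = "ff_format_error")
})
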