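# Session-log tools: completeness, histograms, events, transitions,
# time series and pattern mining

test_that("filter_complete keeps exactly the face-detected frames and flags
           attempt eligibility", {
  fr0 <- make_frames(6, complete = rep(FALSE, 6))
  out0 <- filter_complete(fr0)
  expect_equal(nrow(out0), 0)
  expect_false(attr(out0, "eligible"))

  comp <- c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE)
  fr <- make_frames(10, complete = comp)
  out <- filter_complete(fr)
  expect_equal(nrow(out), 4)
  expect_equal(out$frame_index, which(comp))
  expect_true(attr(out, "eligible"))
  # conservation: complete + discarded = total
  expect_equal(nrow(out) + sum(!comp), attr(out, "n_total"))
})

test_that("modality histograms are normalized conditional distributions", {
  fr <- make_frames(8, sound = c("no", "yes", "yes", "no", "yes", "no", "no", "no"),
                    state = c(3L, 0L, 0L, 5L, 0L, 2L, 2L, 8L))
  h <- modality_histogram(fr, "Sound")
  expect_equal(unname(h["0"]), 1.0)  # all active frames in state 0
  expect_equal(sum(h), 1.0)
  expect_equal(attr(h, "n"), 3)

  h2 <- modality_histogram(fr, "LEDs")  # never active
  expect_true(attr(h2, "empty"))
  expect_false(anyNA(h2))
  expect_equal(sum(h2), 0)

  # Animation is active for any value other than None
  fr2 <- make_frames(4, animation = c("None", "Stand", "Default", "None"),
                     state = c(1L, 4L, 6L, 1L))
  h3 <- modality_histogram(fr2, "Animation")
  expect_equal(unname(h3[c("4", "6")]), c(0.5, 0.5))
  expect_error(modality_histogram(fr2, "Gaze"), "'arg'")

  tab <- modality_histogram_table(fr)
  expect_equal(dim(tab), c(4, 10))
  expect_equal(rowSums(tab[, -1]), c(0, 1, 0, 0), ignore_attr = TRUE)
})

test_that("event detection finds inactive-to-active outsets", {
  fr <- make_frames(4, sound = c("no", "no", "yes", "yes"))
  ev <- detect_events(fr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$k, 3)
  expect_equal(ev$modality, "Sound")

  # constant activity yields no events
  fr2 <- make_frames(5, speaking = rep("yes", 5),
                     animation = rep("Default", 5))
  expect_equal(nrow(detect_events(fr2)), 0)

  # simultaneous outsets yield one record per modality
  fr3 <- make_frames(3, sound = c("no", "yes", "yes"),
                     leds = c("no", "yes", "no"),
                     animation = c("None", "Stand", "Stand"))
  ev3 <- detect_events(fr3)
  expect_equal(nrow(ev3), 3)
  expect_equal(sort(ev3$modality), c("Animation", "LEDs", "Sound"))
  expect_equal(ev3$value[ev3$modality == "Animation"], "Stand")
})

test_that("event detection matches the exhaustive adjacent-pair scan on a
           random action script", {
  set.seed(81)
  n <- 200
  fr <- make_frames(
    n,
    animation = sample(c("None", "Disappointed", "Default", "Stand"), n,
                       replace = TRUE, prob = c(0.6, 0.1, 0.2, 0.1)),
    sound = sample(c("no", "yes"), n, TRUE),
    leds = sample(c("no", "yes"), n, TRUE, prob = c(0.8, 0.2)),
    speaking = sample(c("no", "yes"), n, TRUE))
  ev <- detect_events(fr)
  brute <- brute_events(fr)
  expect_equal(nrow(ev), nrow(brute))
  key <- function(d) sort(paste(d$k, d$modality))
  expect_equal(key(ev), key(brute))
})

test_that("a state transition at an event requires s[k-1] != s[k+lag]", {
  states <- c(6L, 6L, 0L, 0L, 0L)
  ev <- data.frame(k = 3L, modality = "Animation", value = "Stand")
  tr <- count_transitions(states, ev, lag = 1)
  expect_equal(tr$transitions$label, "60")
  expect_equal(tr$tally$yes[tr$tally$modality == "Animation"], 1L)

  tr0 <- count_transitions(c(0L, 0L, 0L),
                           data.frame(k = 2L, modality = "Sound",
                                      value = "yes"), lag = 1)
  expect_equal(nrow(tr0$transitions), 0)
  expect_equal(tr0$tally$no[tr0$tally$modality == "Sound"], 1L)

  # out-of-bounds events are skipped, not clamped
  trb <- count_transitions(c(1L, 2L, 3L),
                           data.frame(k = c(1L, 3L),
                                      modality = c("LEDs", "LEDs"),
                                      value = "yes"), lag = 1)
  expect_equal(sum(trb$tally$yes) + sum(trb$tally$no), 0)
  expect_error(count_transitions(states, ev, lag = 4), "lag")
})

test_that("transition tallies equal a brute-force recount on random series
           for all three lags", {
  set.seed(82)
  states <- sample(0:8, 500, replace = TRUE)
  ev <- data.frame(k = sort(sample(500, 60)),
                   modality = sample(c("Animation", "Sound", "LEDs",
                                       "Speaking"), 60, replace = TRUE),
                   value = "yes", stringsAsFactors = FALSE)
  for (lag in 1:3) {
    got <- count_transitions(states, ev, lag)
    want <- brute_transitions(states, ev, lag)
    expect_equal(stats::setNames(got$tally$yes, got$tally$modality), want$yes)
    expect_equal(stats::setNames(got$tally$no, got$tally$modality), want$no)
    expect_equal(sort(rep(got$transitions$label, got$transitions$count)),
                 want$labels)
    # yes + no = in-bounds events
    in_bounds <- sum(ev$k - 1 >= 1 & ev$k + lag <= length(states))
    expect_equal(sum(got$tally$yes) + sum(got$tally$no), in_bounds)
  }
  tt <- transition_table(states, ev)
  expect_equal(nrow(tt), 15)  # 4 modalities + TOTAL, per lag
  for (l in 1:3) {
    s <- tt[tt$lag == l, ]
    expect_equal(s$yes[s$modality == "TOTAL"],
                 sum(s$yes[s$modality != "TOTAL"]))
  }
})

test_that("state time series carries gap markers and round-trips CSV", {
  comp <- rep(c(TRUE, FALSE), 5)
  fr <- make_frames(10, complete = comp)
  ts <- state_timeseries(fr, states = c(0L, 8L, 0L, 6L, 6L))
  expect_s3_class(ts, "state_series")
  expect_equal(is.na(ts$state), !comp)

  all_comp <- state_timeseries(make_frames(4), states = c(1L, 1L, 2L, 2L))
  expect_false(anyNA(all_comp$state))

  f <- withr::local_tempfile(fileext = ".csv")
  write_state_series(ts, f)
  back <- read_state_series(f)
  expect_equal(back$state, ts$state)
  expect_equal(back$timestamp, ts$timestamp)
  expect_equal(back$complete, ts$complete)

  png_f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(png_f, width = 400, height = 200)
  plot(ts)
  grDevices::dev.off()
  expect_gt(file.info(png_f)$size, 0)
})

test_that("pattern equivalence collapses repeated states up to runs of 3", {
  expect_equal(collapse_runs("8806"), "806")
  expect_equal(collapse_runs("80006"), "806")

  pm <- mine_patterns(as.integer(strsplit("8066", "")[[1]]))
  expect_equal(nrow(pm$occurrences), 1)
  expect_equal(pm$occurrences$class, "806")
  expect_equal(pm$occurrences$variant, "8066")
  expect_equal(pm$occurrences$frames, 4L)

  # a run of four 0s breaks the equivalence (max_run = 3)
  pm2 <- mine_patterns(as.integer(strsplit("800006", "")[[1]]))
  expect_equal(nrow(pm2$occurrences), 0)

  # a window with only 2 distinct states is not an occurrence
  pm3 <- mine_patterns(as.integer(strsplit("0800", "")[[1]]))
  expect_equal(nrow(pm3$occurrences), 0)
})

test_that("pattern occurrences equal the exhaustive substring oracle on
           random series", {
  set.seed(83)
  for (rep in 1:25) {
    s <- sample(0:4, sample(5:30, 1), replace = TRUE)
    pm <- mine_patterns(s)
    brute <- brute_patterns(s)
    expect_equal(nrow(pm$occurrences), nrow(brute))
    key <- function(d) sort(paste(d$start, d$end, d$variant, d$class))
    expect_equal(key(pm$occurrences), key(brute))
  }
})

test_that("per-class totals equal the sum of their variants' counts", {
  set.seed(84)
  series <- lapply(1:8, function(i) sample(0:3, 40, replace = TRUE))
  pm <- mine_patterns(series)
  for (cl in pm$classes$class) {
    vars <- pm$occurrences$class == cl
    expect_equal(pm$classes$count[pm$classes$class == cl], sum(vars))
    v <- pm$variants[vapply(pm$variants$variant, collapse_runs,
                            character(1)) == cl, ]
    expect_equal(sum(v$count), sum(vars))
  }
})

test_that("modality profiles over pattern frames conserve the spanned-frame
           total across modalities", {
  fr <- make_frames(10, speaking = rep("yes", 10),
                    sound = c(rep("no", 6), rep("yes", 4)),
                    animation = rep(c("None", "Default"), 5))
  occ <- data.frame(attempt = 1L, start = 2L, end = 4L,
                    variant = "806", class = "806", frames = 3L)
  prof <- pattern_modality_profile(occ, list(fr))
  expect_equal(attr(prof, "n_frames"), 3L)
  expect_equal(unname(prof$Speaking["yes"]), 3L)
  for (m in names(prof)) expect_equal(sum(prof[[m]]), 3L)

  # multiple occurrences: counts equal a direct tally
  occ2 <- rbind(occ, data.frame(attempt = 1L, start = 6L, end = 9L,
                                variant = "1213", class = "1213",
                                frames = 4L))
  prof2 <- pattern_modality_profile(occ2, list(fr))
  idx <- c(2:4, 6:9)
  expect_equal(unname(prof2$Sound["yes"]), sum(fr$sound[idx] == "yes"))
  expect_equal(unname(prof2$Animation["Default"]),
               sum(fr$animation[idx] == "Default"))
  for (m in names(prof2)) expect_equal(sum(prof2[[m]]), length(idx))
})

test_that("the frame-log dialect round-trips and rejects malformed files", {
  fr <- make_frames(12, complete = c(rep(TRUE, 8), rep(FALSE, 4)),
                    sound = rep(c("no", "yes"), 6))
  f <- withr::local_tempfile(fileext = ".csv")
  write_frame_log(fr, f)
  hdr <- readLines(f, n = 1)
  expect_match(hdr, "^timestamp,animation,sound,leds,speaking,x0,y0,")
  back <- read_frame_log(f)
  expect_equal(back$sound, fr$sound)
  expect_equal(is_complete(back), is_complete(fr))
  expect_equal(back$x0, fr$x0, tolerance = 1e-9)

  # missing landmark column is named in the error
  df2 <- utils::read.csv(f)
  df2$x0 <- NULL
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df2, f2, row.names = FALSE)
  expect_error(read_frame_log(f2), "x0")

  # invalid action values are rejected
  df3 <- utils::read.csv(f, colClasses = "character")
  df3$animation[1] <- "Jump"
  f3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df3, f3, row.names = FALSE)
  expect_error(read_frame_log(f3), "animation")
})
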