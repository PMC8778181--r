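# Session-log analysis: frames, events, state transitions, state time
# series and run-collapsed sequence patterns.
#
# A frame is one 3 Hz sample of the robot's four action modalities
# (Animation, Sound, LEDs, Speaking) plus, when the face was detected, the
# 68 landmarks. A frame is complete iff it carries both. An event is the
# outset (inactive -> active transition) of a modality. All per-attempt
# counting below runs over the ordered series of complete frames.

.MODALITIES <- c("Animation", "Sound", "LEDs", "Speaking")
.ANIMATION_VALUES <- c("None", "Disappointed", "Default", "Stand")
.BINARY_VALUES <- c("no", "yes")

.LANDMARK_COLS <- as.vector(rbind(paste0("x", 0:67), paste0("y", 0:67)))
.FRAME_COLS <- c("timestamp", "animation", "sound", "leds", "speaking",
                 .LANDMARK_COLS)

#' Read a frame log
#'
#' The frame-log CSV dialect has header
#' `timestamp,animation,sound,leds,speaking,x0,y0,...,x67,y67`; animation
#' takes values None/Disappointed/Default/Stand, the binary modalities
#' no/yes, and empty landmark cells mark a non-complete frame (no face
#' detection).
#'
#' @param path CSV file in the frame-log dialect.
#' @return a data.frame of frames, one row per 3 Hz sample.
#' @export
read_frame_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(timestamp = "character",
                                       animation = "character",
                                       sound = "character",
                                       leds = "character",
                                       speaking = "character"))
  missing_cols <- setdiff(.FRAME_COLS, names(df))
  if (length(missing_cols))
    stop("frame log ", path, ": missing column '", missing_cols[1L], "'")
  bad_anim <- setdiff(unique(df$animation), .ANIMATION_VALUES)
  if (length(bad_anim))
    stop("frame log ", path, ": invalid animation value '", bad_anim[1L], "'")
  for (col in c("sound", "leds", "speaking")) {
    bad <- setdiff(unique(df[[col]]), .BINARY_VALUES)
    if (length(bad))
      stop("frame log ", path, ": invalid ", col, " value '", bad[1L], "'")
  }
  for (col in .LANDMARK_COLS) df[[col]] <- as.numeric(df[[col]])
  df[, .FRAME_COLS, drop = FALSE]
}

#' Write a frame log
#'
#' @param frames data.frame with the frame-log columns (extra columns such
#'   as `state` or `attempt_id` are dropped from the file).
#' @param path output CSV path.
#' @export
write_frame_log <- function(frames, path) {
  missing_cols <- setdiff(.FRAME_COLS, names(frames))
  if (length(missing_cols))
    stop("frames: missing column '", missing_cols[1L], "'")
  out <- frames[, .FRAME_COLS, drop = FALSE]
  for (col in .LANDMARK_COLS)
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         sprintf("%.12g", out[[col]]))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Completeness of frames
#'
#' A frame is complete iff all 136 landmark coordinates are present (the
#' face was detected) alongside the always-present robot-action values.
#'
#' @param frames frame data.frame.
#' @return logical vector, one element per frame.
#' @export
is_complete <- function(frames) {
  lm <- as.matrix(frames[, .LANDMARK_COLS, drop = FALSE])
  rowSums(is.na(lm)) == 0L
}

#' Keep only the complete frames of an attempt
#'
#' Frames where the face was not detected are discarded; the remaining
#' ordered complete frames form the series on which events, transitions and
#' patterns are counted. An attempt with at least one complete frame is
#' *eligible*.
#'
#' @param frames frame data.frame (one attempt).
#' @return the complete frames, with the original row positions in column
#'   `frame_index` and attributes `n_total` and `eligible`.
#' @export
filter_complete <- function(frames) {
  keep <- is_complete(frames)
  out <- frames[keep, , drop = FALSE]
  out$frame_index <- which(keep)
  rownames(out) <- NULL
  attr(out, "n_total") <- nrow(frames)
  attr(out, "eligible") <- any(keep)
  out
}

#' Convert complete frames to face trees
#'
#' @param frames complete frames (rows with any missing landmark raise an
#'   error).
#' @return list of `face_tree` objects, one per row.
#' @export
frames_to_trees <- function(frames) {
  lm <- as.matrix(frames[, .LANDMARK_COLS, drop = FALSE])
  if (any(is.na(lm)))
    stop("frames_to_trees: non-complete frames present; filter_complete first")
  lapply(seq_len(nrow(lm)), function(i)
    build_face_tree(matrix(lm[i, ], ncol = 2L, byrow = TRUE),
                    provenance = i))
}

# active indicator per modality; Animation is active for any value but None
.modality_active <- function(frames, modality) {
  switch(modality,
         Animation = frames$animation != "None",
         Sound     = frames$sound == "yes",
         LEDs      = frames$leds == "yes",
         Speaking  = frames$speaking == "yes",
         stop("unknown modality '", modality, "'"))
}

#' Modality-conditional state histogram
#'
#' Normalized distribution over the nine states of the complete frames
#' during which the given modality was active (Animation: any value other
#' than None; binary modalities: yes). Interpreted as an empirical
#' probability mass function of the child's state conditional on the
#' stimulus.
#'
#' @param frames complete frames carrying a `state` column (0-8).
#' @param modality one of `"Animation"`, `"Sound"`, `"LEDs"`, `"Speaking"`.
#' @return named numeric vector over the states 0-8 summing to 1, with
#'   attributes `n` (active frames) and `empty` (`TRUE`, with an all-zero
#'   vector, when no frame was active).
#' @export
modality_histogram <- function(frames, modality) {
  modality <- match.arg(modality, .MODALITIES)
  if (is.null(frames$state)) stop("frames must carry a 'state' column")
  act <- .modality_active(frames, modality)
  counts <- tabulate(frames$state[act] + 1L, nbins = 9L)
  n <- sum(counts)
  h <- if (n > 0L) counts / n else rep(0, 9L)
  names(h) <- as.character(0:8)
  structure(h, n = n, empty = n == 0L)
}

#' Table of the four modality histograms
#'
#' @param frames complete frames with a `state` column.
#' @return 4 x 9 data.frame (modalities x states) of probability masses.
#' @export
modality_histogram_table <- function(frames) {
  tab <- t(vapply(.MODALITIES, function(m)
    as.numeric(modality_histogram(frames, m)), numeric(9L)))
  out <- data.frame(modality = .MODALITIES, tab, check.names = FALSE)
  names(out)[-1L] <- as.character(0:8)
  rownames(out) <- NULL
  out
}

#' Detect robot-action events in a complete-frame series
#'
#' An event is the outset of a robot action: a frame where a modality
#' transitions from inactive to active (Animation: from None to any other
#' value; binary modalities: no to yes). Simultaneous outsets yield one
#' record per modality. Indices `k` are 1-based positions in the supplied
#' (complete-frame) series.
#'
#' @param frames ordered complete frames of one attempt.
#' @return data.frame with columns `k`, `modality`, `value` (the action
#'   value at the outset), ordered by `k`.
#' @export
detect_events <- function(frames) {
  n <- nrow(frames)
  recs <- list()
  if (n >= 2L) {
    for (m in .MODALITIES) {
      act <- .modality_active(frames, m)
      k <- which(!act[-n] & act[-1L]) + 1L
      if (length(k)) {
        val <- switch(m, Animation = frames$animation[k],
                      Sound = frames$sound[k], LEDs = frames$leds[k],
                      Speaking = frames$speaking[k])
        recs[[m]] <- data.frame(k = k, modality = m, value = val,
                                stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(recs))
    return(data.frame(k = integer(0), modality = character(0),
                      value = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, recs)
  out <- out[order(out$k, match(out$modality, .MODALITIES)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Event-triggered state-transition counts
#'
#' For an event at position `k` of a state series, a state transition occurs
#' iff the state before the event differs from the one `lag` frames after
#' it: `s[k-1] != s[k+lag]`, `lag` in 1-3 to allow for response time lag. A
#' transition is labeled by the two-digit string "ab" with `a = s[k-1]` and
#' `b = s[k+lag]`. Events whose `k-1` or `k+lag` fall outside the series are
#' skipped.
#'
#' @param states integer vector of states 0-8 (the complete-frame series).
#' @param events data.frame from [detect_events()].
#' @param lag 1, 2 or 3.
#' @return list with `transitions` (data.frame `modality`, `from`, `to`,
#'   `label`, `count`) and `tally` (data.frame `modality`, `yes`, `no`).
#' @export
count_transitions <- function(states, events, lag = 1) {
  if (!lag %in% 1:3) stop("lag must be 1, 2 or 3")
  n <- length(states)
  rows <- list(); yes <- no <- integer(length(.MODALITIES))
  names(yes) <- names(no) <- .MODALITIES
  for (i in seq_len(nrow(events))) {
    k <- events$k[i]; m <- events$modality[i]
    if (k - 1L < 1L || k + lag > n) next
    a <- states[k - 1L]; b <- states[k + lag]
    if (a != b) {
      yes[m] <- yes[m] + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        modality = m, from = a, to = b, label = paste0(a, b),
        stringsAsFactors = FALSE)
    } else no[m] <- no[m] + 1L
  }
  trans <- if (length(rows)) {
    d <- do.call(rbind, rows)
    agg <- stats::aggregate(list(count = rep(1L, nrow(d))),
                            by = d[c("modality", "from", "to", "label")],
                            FUN = sum)
    agg[order(match(agg$modality, .MODALITIES), agg$label), , drop = FALSE]
  } else data.frame(modality = character(0), from = integer(0),
                    to = integer(0), label = character(0), count = integer(0))
  rownames(trans) <- NULL
  list(transitions = trans,
       tally = data.frame(modality = .MODALITIES, yes = as.integer(yes),
                          no = as.integer(no), row.names = NULL))
}

#' Transition tallies for all three lags
#'
#' @param states integer state series.
#' @param events data.frame from [detect_events()].
#' @return data.frame modality x lag with `yes`/`no` counts plus a TOTAL row
#'   per lag.
#' @export
transition_table <- function(states, events) {
  out <- do.call(rbind, lapply(1:3, function(l) {
    t <- count_transitions(states, events, l)$tally
    t$lag <- l
    t
  }))
  tot <- do.call(rbind, lapply(1:3, function(l) {
    s <- out[out$lag == l, ]
    data.frame(modality = "TOTAL", yes = sum(s$yes), no = sum(s$no), lag = l)
  }))
  rbind(out, tot)[order(c(out$lag, tot$lag)), c("modality", "lag", "yes", "no")]
}

#' State time series of an attempt
#'
#' The per-frame sequence of states with explicit gap markers (`NA`) at the
#' non-complete frames, ready for plotting or CSV export.
#'
#' @param frames all frames of one attempt (complete or not), in order.
#' @param states integer states 0-8 for the complete frames, in order; or
#'   `NULL` if `frames` already carries a `state` column on complete rows.
#' @return object of class `state_series`: data.frame with columns
#'   `timestamp`, `complete`, `state` (`NA` at gaps).
#' @export
state_timeseries <- function(frames, states = NULL) {
  comp <- is_complete(frames)
  st <- rep(NA_integer_, nrow(frames))
  if (is.null(states)) {
    if (is.null(frames$state))
      stop("supply 'states' or a 'state' column on the frames")
    st[comp] <- as.integer(frames$state[comp])
  } else {
    if (length(states) != sum(comp))
      stop("length(states) must equal the number of complete frames")
    st[comp] <- as.integer(states)
  }
  structure(data.frame(timestamp = frames$timestamp, complete = comp,
                       state = st, stringsAsFactors = FALSE),
            class = c("state_series", "data.frame"))
}

#' @export
print.state_series <- function(x, ...) {
  cat("State series:", nrow(x), "frames,", sum(x$complete), "complete,",
      sum(!x$complete), "gaps\n")
  invisible(x)
}

#' @export
plot.state_series <- function(x, ...) {
  idx <- seq_len(nrow(x))
  graphics::plot(idx, x$state, type = "p", pch = 16, cex = 0.5,
                 ylim = c(-1, 8), yaxt = "n", xlab = "frame (3 Hz)",
                 ylab = "state", main = "Child states over an attempt", ...)
  graphics::axis(2, at = 0:8, labels = 0:8, las = 1)
  gaps <- idx[!x$complete]
  if (length(gaps))
    graphics::points(gaps, rep(-1, length(gaps)), pch = 4, cex = 0.4,
                     col = "grey40")
  graphics::mtext("x = no face detection", side = 1, line = 4, cex = 0.7)
  invisible(x)
}

#' Write/read a state series as CSV
#'
#' Round-trips losslessly: gaps are empty `state` cells.
#'
#' @param series a `state_series`.
#' @param path CSV path.
#' @export
write_state_series <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_state_series
#' @export
read_state_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(timestamp = "character"))
  df$state <- as.integer(df$state)
  df$complete <- as.logical(df$complete)
  structure(df, class = c("state_series", "data.frame"))
}

# run-length tokenization of a state vector
.state_runs <- function(states) {
  r <- rle(as.integer(states))
  data.frame(symbol = r$values, length = r$lengths,
             end = cumsum(r$lengths),
             start = cumsum(r$lengths) - r$lengths + 1L)
}

#' Mine run-collapsed state-sequence patterns
#'
#' A child's state series is read as a string over the alphabet 0-8. Two
#' substrings are *equivalent* when they collapse to the same symbol
#' sequence after removing successive repetitions of up to `max_run`; e.g.
#' "806", "8066", "8806" and "80006" all belong to the equivalence class
#' "806". An occurrence is a window of `n_runs` consecutive maximal runs
#' containing at least `min_distinct` distinct states with every run length
#' at most `max_run`. Occurrences are counted as maximal run windows, so an
#' occurrence of "8066" is not additionally counted as "806". Patterns never
#' span attempts.
#'
#' @param series_list list of integer state vectors (one per attempt), or a
#'   single vector.
#' @param min_distinct minimum number of distinct states in a window
#'   (default 3).
#' @param max_run maximum run length within a pattern (default 3; at 3 Hz a
#'   run of up to three repeats is read as the same behavior at different
#'   speed).
#' @param n_runs window length in runs (default 3).
#' @return object of class `pattern_miner`: `occurrences` (data.frame
#'   `attempt`, `start`, `end`, `variant`, `class`, `frames`), `classes`
#'   (per-class data.frame `class`, `count`, `frames`), `variants`
#'   (per-variant counts with their class).
#' @export
mine_patterns <- function(series_list, min_distinct = 3, max_run = 3,
                          n_runs = 3) {
  if (!is.list(series_list)) series_list <- list(series_list)
  occ <- list()
  for (a in seq_along(series_list)) {
    s <- as.integer(series_list[[a]])
    if (any(!is.na(s) & (s < 0L | s > 8L)))
      stop("states must be in 0..8")
    if (length(s) < n_runs || anyNA(s)) {
      if (anyNA(s)) stop("state series must not contain NA; split at gaps")
      next
    }
    runs <- .state_runs(s)
    nr <- nrow(runs)
    if (nr < n_runs) next
    for (w in seq_len(nr - n_runs + 1L)) {
      win <- runs[w:(w + n_runs - 1L), ]
      if (length(unique(win$symbol)) < min_distinct) next
      if (any(win$length > max_run)) next
      start <- win$start[1L]; end <- win$end[n_runs]
      occ[[length(occ) + 1L]] <- data.frame(
        attempt = a, start = start, end = end,
        variant = paste(rep(win$symbol, win$length), collapse = ""),
        class = paste(win$symbol, collapse = ""),
        frames = end - start + 1L, stringsAsFactors = FALSE)
    }
  }
  occurrences <- if (length(occ)) do.call(rbind, occ) else
    data.frame(attempt = integer(0), start = integer(0), end = integer(0),
               variant = character(0), class = character(0),
               frames = integer(0), stringsAsFactors = FALSE)
  variants <- aggregate_pattern_counts(occurrences, "variant")
  classes <- aggregate_pattern_counts(occurrences, "class")
  structure(list(occurrences = occurrences, classes = classes,
                 variants = variants,
                 config = list(min_distinct = min_distinct,
                               max_run = max_run, n_runs = n_runs)),
            class = "pattern_miner")
}

#' Aggregate pattern occurrences
#'
#' Sums occurrence counts and spanned frames per variant or per equivalence
#' class. The per-class total equals the sum of its variants' counts.
#'
#' @param occurrences occurrence data.frame (from [mine_patterns()]), or any
#'   data.frame with the grouping column, and a `frames` column; a named
#'   numeric vector of per-variant counts is also accepted when grouping by
#'   class, in which case classes are derived with [collapse_runs()].
#' @param by `"class"` or `"variant"`.
#' @return data.frame with the group, `count` and `frames` (when available).
#' @export
aggregate_pattern_counts <- function(occurrences, by = c("class", "variant")) {
  by <- match.arg(by)
  if (!is.data.frame(occurrences)) {
    counts <- occurrences
    if (is.null(names(counts))) stop("counts vector must be named by variant")
    cls <- vapply(names(counts), collapse_runs, character(1L))
    agg <- tapply(as.numeric(counts), cls, sum)
    return(data.frame(class = names(agg), count = as.numeric(agg),
                      row.names = NULL, stringsAsFactors = FALSE))
  }
  if (!nrow(occurrences)) {
    out <- data.frame(g = character(0), count = integer(0),
                      frames = integer(0), stringsAsFactors = FALSE)
    names(out)[1L] <- by
    return(out)
  }
  agg <- stats::aggregate(
    list(count = rep(1L, nrow(occurrences)), frames = occurrences$frames),
    by = stats::setNames(list(occurrences[[by]]), by), FUN = sum)
  agg[order(-agg$count, agg[[by]]), , drop = FALSE]
}

#' Collapse successive state repetitions of a pattern string
#'
#' `"8806"` collapses to `"806"`: the canonical representative of the
#' pattern's equivalence class.
#'
#' @param variant pattern string over 0-8.
#' @return the run-collapsed class string.
#' @export
collapse_runs <- function(variant) {
  ch <- strsplit(variant, "")[[1L]]
  paste(rle(ch)$values, collapse = "")
}

#' @export
print.pattern_miner <- function(x, ...) {
  cat("Pattern mining:", nrow(x$occurrences), "occurrences,",
      nrow(x$classes), "equivalence classes\n")
  if (nrow(x$classes)) {
    cat("top classes:\n")
    print(utils::head(x$classes, 5L), row.names = FALSE)
  }
  invisible(x)
}

#' Modality action-value profile over a pattern's spanned frames
#'
#' For the frames spanned by the given occurrences, counts each modality's
#' action values (e.g. Sound yes/no). Every modality's counts sum to the
#' same spanned-frame total.
#'
#' @param occurrences occurrence rows ([mine_patterns()] output, typically
#'   filtered to one equivalence class).
#' @param frames_list list of complete-frame data.frames, one per attempt,
#'   indexed by `occurrences$attempt`.
#' @return named list per modality of named count vectors, with attribute
#'   `"n_frames"` (total spanned frames).
#' @export
pattern_modality_profile <- function(occurrences, frames_list) {
  if (is.data.frame(frames_list)) frames_list <- list(frames_list)
  counts <- list(
    Animation = stats::setNames(integer(4L), .ANIMATION_VALUES),
    Sound = stats::setNames(integer(2L), .BINARY_VALUES),
    LEDs = stats::setNames(integer(2L), .BINARY_VALUES),
    Speaking = stats::setNames(integer(2L), .BINARY_VALUES))
  n_frames <- 0L
  for (i in seq_len(nrow(occurrences))) {
    fr <- frames_list[[occurrences$attempt[i]]]
    idx <- occurrences$start[i]:occurrences$end[i]
    if (max(idx) > nrow(fr)) stop("occurrence exceeds the frame series")
    n_frames <- n_frames + length(idx)
    counts$Animation <- counts$Animation +
      table(factor(fr$animation[idx], levels = .ANIMATION_VALUES))
    counts$Sound <- counts$Sound +
      table(factor(fr$sound[idx], levels = .BINARY_VALUES))
    counts$LEDs <- counts$LEDs +
      table(factor(fr$leds[idx], levels = .BINARY_VALUES))
    counts$Speaking <- counts$Speaking +
      table(factor(fr$speaking[idx], levels = .BINARY_VALUES))
  }
  counts <- lapply(counts, function(x) {
    v <- as.integer(x); names(v) <- names(x); v
  })
  structure(counts, n_frames = n_frames)
}
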