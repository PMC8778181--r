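# Synthetic data: pose-dependent landmark generation and scripted session
# logs with known ground truth. The generator emulates (i) stills of a head
# in the nine poses under noise presets mimicking camera-distance/lighting
# conditions, and (ii) 3 Hz session logs in which robot-action outsets bias
# the child's subsequent states toward Front.

# Canonical 3D face template, 68 points in the standard landmark order.
# Arbitrary units: face half-width 1, nose tip protruding toward the camera
# (+z). Fixed constants; documented here and versioned with the package.
face_template_3d <- local({
  ellipse <- function(cx, cy, rx, ry, n, z, t0 = 0) {
    t <- t0 + seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
    cbind(cx + rx * cos(t), cy + ry * sin(t), z)
  }
  t_jaw <- seq(pi, 0, length.out = 17L)
  jaw <- cbind(cos(t_jaw), -0.10 - 1.05 * sin(t_jaw), -0.30)
  brow_x <- seq(-0.75, -0.25, length.out = 5L)
  larch <- 0.55 + 0.08 * sin(seq(0, pi, length.out = 5L))
  left_brow <- cbind(brow_x, larch, 0.10)
  right_brow <- cbind(rev(-brow_x), rev(larch), 0.10)
  bridge <- cbind(0, c(0.45, 0.30, 0.15, 0.02), c(0.10, 0.18, 0.26, 0.35))
  lower_nose <- cbind(seq(-0.16, 0.16, length.out = 5L),
                      -0.08 - c(0, 0.02, 0.03, 0.02, 0),
                      0.18)
  left_eye <- ellipse(-0.45, 0.35, 0.14, 0.06, 6L, 0.05, t0 = pi)
  right_eye <- ellipse(0.45, 0.35, 0.14, 0.06, 6L, 0.05, t0 = pi)
  outer_mouth <- ellipse(0, -0.50, 0.35, 0.15, 12L, 0.12, t0 = pi)
  inner_mouth <- ellipse(0, -0.50, 0.22, 0.07, 8L, 0.12, t0 = pi)
  unname(rbind(jaw, left_brow, right_brow, bridge, lower_nose,
               left_eye, right_eye, outer_mouth, inner_mouth))
})

# yaw/pitch presets (degrees) per pose subclass; left/right and up/down are
# sign-symmetric and Front (proper) is (0, 0)
.POSE_PRESETS <- list(
  FrontLeft = c(-8, 0), FrontProper = c(0, 0), FrontRight = c(8, 0),
  UpperLeft = c(-35, 25), Up = c(0, 25), UpperRight = c(35, 25),
  Right = c(35, 0), LowerRight = c(35, -25), Down = c(0, -25),
  LowerLeft = c(-35, -25), Left = c(-35, 0)
)

# per-landmark jitter scale as a fraction of the inter-ocular distance,
# emulating the ordering of difficulty of the 2x2 camera-distance/lighting
# conditions (near/far x normal/dim)
.NOISE_PRESETS <- c(near_normal = 0.005, far_normal = 0.01,
                    near_dim = 0.02, far_dim = 0.03)

.noise_sigma <- function(noise) {
  if (is.numeric(noise)) {
    if (noise < 0) stop("noise fraction must be nonnegative")
    return(noise)
  }
  if (!noise %in% names(.NOISE_PRESETS))
    stop("unknown noise preset '", noise, "'; use one of ",
         paste(names(.NOISE_PRESETS), collapse = ", "),
         " or a numeric fraction")
  .NOISE_PRESETS[[noise]]
}

# rigid rotation + orthographic projection + jitter, using the current RNG
.pose_landmarks_once <- function(pose, sigma_frac, scale = 100,
                                 center = c(320, 240)) {
  if (!pose %in% names(.POSE_PRESETS))
    stop("unknown pose '", pose, "'")
  ang <- .POSE_PRESETS[[pose]] * pi / 180
  yaw <- ang[1L]; pitch <- ang[2L]
  Ry <- rbind(c(cos(yaw), 0, sin(yaw)), c(0, 1, 0),
              c(-sin(yaw), 0, cos(yaw)))
  Rx <- rbind(c(1, 0, 0), c(0, cos(pitch), -sin(pitch)),
              c(0, sin(pitch), cos(pitch)))
  P3 <- face_template_3d %*% t(Rx %*% Ry)
  xy <- P3[, 1:2, drop = FALSE]
  # image convention: y grows downward
  img <- cbind(center[1L] + scale * xy[, 1L],
               center[2L] - scale * xy[, 2L])
  if (sigma_frac > 0) {
    iod <- sqrt(sum((colMeans(img[37:42, ]) - colMeans(img[43:48, ]))^2))
    img <- img + matrix(stats::rnorm(136L, 0, sigma_frac * iod), 68L, 2L)
  }
  img
}

#' Generate labeled landmark sets for a head pose
#'
#' Rigidly rotates the canonical 3D face template by the pose's yaw/pitch
#' preset, projects orthographically to image coordinates, and adds Gaussian
#' per-landmark jitter scaled by the inter-ocular distance. Deterministic
#' under `seed`.
#'
#' @param pose a pose subclass from [POSE_SUBCLASSES] or one of the nine
#'   pose labels ("Front" uses the FrontProper preset).
#' @param n number of landmark sets (>= 1).
#' @param noise preset name (`"near_normal"`, `"far_normal"`, `"near_dim"`,
#'   `"far_dim"`) or a numeric jitter fraction of the inter-ocular distance.
#' @param seed integer seed.
#' @return list of `n` 68 x 2 landmark matrices with attribute `"pose"`.
#' @export
generate_pose_landmarks <- function(pose, n = 1, noise = "near_normal",
                                    seed = 1) {
  if (pose == "Front") pose <- "FrontProper"
  if (n < 1) stop("n must be >= 1")
  sigma <- .noise_sigma(noise)
  out <- vector("list", n)
  .with_seed(seed, {
    for (i in seq_len(n)) out[[i]] <- .pose_landmarks_once(pose, sigma)
  })
  attr(out, "pose") <- pose
  out
}

#' Generate a labeled synthetic pose corpus
#'
#' `n_per_class` landmark sets for each of the 11 pose subclasses, built as
#' face trees, with subclass labels — the synthetic stand-in for a labeled
#' head-pose training set.
#'
#' @param n_per_class landmark sets per subclass.
#' @param noise noise preset or numeric fraction (see
#'   [generate_pose_landmarks()]).
#' @param seed integer seed.
#' @return list with `trees` (list of `face_tree`) and `labels` (character).
#' @export
generate_pose_corpus <- function(n_per_class = 100, noise = "near_normal",
                                 seed = 1) {
  trees <- list(); labels <- character(0)
  for (i in seq_along(POSE_SUBCLASSES)) {
    pose <- POSE_SUBCLASSES[i]
    lms <- generate_pose_landmarks(pose, n_per_class, noise, seed + i)
    trees <- c(trees, lapply(lms, build_face_tree))
    labels <- c(labels, rep(pose, n_per_class))
  }
  list(trees = trees, labels = labels)
}

#' Define a session script
#'
#' The script fixes the robot-action schedule and the child's state dynamics
#' of a synthetic attempt. States follow either a Markov chain over 0-8 with
#' sticky diagonal whose rows are pulled toward state 0 (Front) for
#' `boost_frames` frames after every robot-action outset (`boost` is the
#' mixing weight of that pull), or an iid draw from `state_probs`
#' (`active_state_probs` while any modality is active) — the latter gives an
#' analytically known conditional state distribution.
#'
#' @param n_frames frames at 3 Hz (default 540, a three-minute attempt).
#' @param state_mode `"markov"` or `"iid"`.
#' @param stay_prob Markov self-transition probability (rest spread
#'   uniformly), default 0.75.
#' @param boost post-event mixing weight toward state 0 in `[0, 1]`.
#' @param boost_frames number of frames the boost persists after an event.
#' @param state_probs baseline state distribution (iid mode), length 9.
#' @param active_state_probs state distribution while a modality is active
#'   (iid mode); defaults to `state_probs`.
#' @param event_rate named per-frame activation probability per modality.
#' @param mean_duration mean frames an activation lasts (geometric).
#' @param schedule optional explicit data.frame with columns `animation`,
#'   `sound`, `leds`, `speaking` overriding the random schedule.
#' @param blank_frac fraction of frames with landmarks blanked (no face
#'   detection).
#' @param noise landmark noise preset or fraction.
#' @param seed integer seed.
#' @param start_time first frame timestamp.
#' @return a `session_script` list.
#' @export
session_script <- function(n_frames = 540, state_mode = c("markov", "iid"),
                           stay_prob = 0.75, boost = 0.5, boost_frames = 6,
                           state_probs = rep(1 / 9, 9),
                           active_state_probs = NULL,
                           event_rate = c(Animation = 0.02, Sound = 0.02,
                                          LEDs = 0.01, Speaking = 0.03),
                           mean_duration = 9, schedule = NULL,
                           blank_frac = 0.1, noise = "near_normal",
                           seed = 1,
                           start_time = "2021-05-10 10:00:00") {
  state_mode <- match.arg(state_mode)
  stopifnot(n_frames >= 1, stay_prob >= 0, stay_prob <= 1,
            boost >= 0, boost <= 1, boost_frames >= 0,
            blank_frac >= 0, blank_frac < 1,
            abs(sum(state_probs) - 1) < 1e-9)
  if (is.null(active_state_probs)) active_state_probs <- state_probs
  structure(list(n_frames = as.integer(n_frames), state_mode = state_mode,
                 stay_prob = stay_prob, boost = boost,
                 boost_frames = as.integer(boost_frames),
                 state_probs = state_probs,
                 active_state_probs = active_state_probs,
                 event_rate = event_rate, mean_duration = mean_duration,
                 schedule = schedule, blank_frac = blank_frac,
                 noise = noise, seed = as.integer(seed),
                 start_time = start_time),
            class = "session_script")
}

# state numeral -> pose subclass used to draw its landmarks
.STATE_POSE <- c("FrontProper", "UpperLeft", "Up", "UpperRight", "Right",
                 "LowerRight", "Down", "LowerLeft", "Left")

#' Generate a synthetic session attempt
#'
#' Emits a 3 Hz frame log in the package's CSV dialect: robot-action columns
#' from the (scripted or simulated) schedule and landmarks drawn from the
#' pose preset of the current ground-truth state; a `blank_frac` fraction of
#' frames has the landmarks blanked (non-complete). Fully deterministic
#' under the script's seed.
#'
#' @param script a [session_script()].
#' @return list with `frames` (frame-log data.frame), `truth` (per-frame
#'   `state`, `complete`, the full `schedule`, event outset indices on both
#'   the full and the complete-frame series, and the script).
#' @export
generate_session <- function(script) {
  stopifnot(inherits(script, "session_script"))
  n <- script$n_frames
  out <- NULL
  .with_seed(script$seed, {
    sched <- script$schedule
    if (is.null(sched)) sched <- .simulate_schedule(script)
    stopifnot(nrow(sched) == n)
    active <- cbind(Animation = sched$animation != "None",
                    Sound = sched$sound == "yes",
                    LEDs = sched$leds == "yes",
                    Speaking = sched$speaking == "yes")
    any_active <- rowSums(active) > 0L
    # outsets over the full frame series (ground truth)
    outset <- rbind(active[1L, , drop = FALSE] & FALSE,
                    active[-1L, , drop = FALSE] &
                      !active[-n, , drop = FALSE])
    event_frame <- which(rowSums(outset) > 0L)

    states <- integer(n)
    if (script$state_mode == "iid") {
      for (t in seq_len(n)) {
        p <- if (any_active[t]) script$active_state_probs else
          script$state_probs
        states[t] <- sample(0:8, 1L, prob = p)
      }
    } else {
      base <- matrix((1 - script$stay_prob) / 8, 9L, 9L)
      diag(base) <- script$stay_prob
      states[1L] <- sample(0:8, 1L)
      last_event <- -Inf
      for (t in 2:n) {
        if (t %in% event_frame) last_event <- t
        row <- base[states[t - 1L] + 1L, ]
        if (t - last_event <= script$boost_frames && script$boost > 0) {
          row <- (1 - script$boost) * row
          row[1L] <- row[1L] + script$boost
        }
        states[t] <- sample(0:8, 1L, prob = row)
      }
    }

    sigma <- .noise_sigma(script$noise)
    lm <- matrix(NA_real_, n, 136L)
    blank <- rep(FALSE, n)
    if (script$blank_frac > 0)
      blank[sample.int(n, round(script$blank_frac * n))] <- TRUE
    for (t in seq_len(n)) {
      if (blank[t]) next
      pts <- .pose_landmarks_once(.STATE_POSE[states[t] + 1L], sigma)
      lm[t, ] <- as.vector(t(pts))  # x0,y0,...,x67,y67
    }

    ts <- format(as.POSIXct(script$start_time, tz = "UTC") +
                   (seq_len(n) - 1L) / 3,
                 "%Y-%m-%d %H:%M:%OS2")
    frames <- data.frame(timestamp = ts, animation = sched$animation,
                         sound = sched$sound, leds = sched$leds,
                         speaking = sched$speaking,
                         stringsAsFactors = FALSE)
    lm_df <- as.data.frame(lm)
    names(lm_df) <- .LANDMARK_COLS
    frames <- cbind(frames, lm_df)

    complete <- !blank
    k_complete <- cumsum(complete)  # full index -> complete-series index
    out <- list(
      frames = frames,
      truth = list(state = states, complete = complete, schedule = sched,
                   event_frame = event_frame,
                   event_k = k_complete[event_frame][complete[event_frame]],
                   script = script))
  })
  out
}

.simulate_schedule <- function(script) {
  n <- script$n_frames
  p_off <- 1 / script$mean_duration
  sim_binary <- function(p_on) {
    x <- logical(n)
    if (n >= 2L) for (t in 2:n) {
      x[t] <- if (x[t - 1L]) stats::runif(1) >= p_off else
        stats::runif(1) < p_on
    }
    x
  }
  rate <- function(m) {
    r <- script$event_rate[[m]]
    if (is.null(r) || is.na(r)) 0 else r
  }
  anim_on <- sim_binary(rate("Animation"))
  anim <- rep("None", n)
  if (any(anim_on)) {
    r <- rle(anim_on)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      anim[starts[j]:ends[j]] <-
        sample(c("Disappointed", "Default", "Stand"), 1L)
    }
  }
  yn <- function(x) ifelse(x, "yes", "no")
  data.frame(animation = anim,
             sound = yn(sim_binary(rate("Sound"))),
             leds = yn(sim_binary(rate("LEDs"))),
             speaking = yn(sim_binary(rate("Speaking"))),
             stringsAsFactors = FALSE)
}

#' Write the ground truth of a synthetic session to JSON
#' @param session output of [generate_session()].
#' @param path output file.
#' @export
session_truth_to_json <- function(session, path) {
  truth <- session$truth
  obj <- list(state = truth$state, complete = truth$complete,
              event_frame = truth$event_frame, event_k = truth$event_k,
              seed = truth$script$seed,
              state_mode = truth$script$state_mode,
              boost = truth$script$boost,
              boost_frames = truth$script$boost_frames,
              blank_frac = truth$script$blank_frac,
              noise = truth$script$noise)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
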