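# Shared fixtures and independent oracles. The oracles re-derive expected
# values from first principles (flat sums, exhaustive scans) and never call
# the code paths they check.

rand_trivial_tree <- function() {
  structure(list(r = stats::runif(59, 0, 2),
                 phi = stats::runif(59, -pi, pi),
                 provenance = NULL),
            class = "face_tree")
}

rand_interval_tree <- function(width = 0.5) {
  r_lo <- stats::runif(59, 0, 2)
  p_lo <- stats::runif(59, -pi, pi)
  interval_tree(r_lo, r_lo + stats::runif(59, 0, width),
                p_lo, p_lo + stats::runif(59, 0, width))
}

rand_params <- function() {
  metric_params(lambda_r = stats::runif(59, 0, 2),
                lambda_phi = stats::runif(59, 0, 2),
                k_r123 = stats::runif(3, 0, 2),
                k_phi123 = stats::runif(3, 0, 2),
                k_r = stats::runif(1, 0.1, 2),
                k_phi = stats::runif(1, 0.1, 2))
}

# Flat weighted-L1 closed form of the hierarchical lattice distance:
# sum over both coordinates and all 59 nodes of
# k_coord * w_i * lambda_i * (|delta lo| + |delta hi|), where w_i is 1 for
# primaries and k_{1,2,3} for secondaries under primaries 1-3.
flat_distance_oracle <- function(ta, tb, params) {
  node_group <- c(rep(0L, 8L), rep(1L, 11L), rep(2L, 11L), rep(3L, 29L))
  ends <- function(tr, coord) {
    if (inherits(tr, "face_tree")) {
      v <- tr[[coord]]
      list(lo = v, hi = v)
    } else if (coord == "r") list(lo = tr$r_lo, hi = tr$r_hi)
    else list(lo = tr$phi_lo, hi = tr$phi_hi)
  }
  total <- 0
  for (coord in c("r", "phi")) {
    lam <- if (coord == "r") params$lambda_r else params$lambda_phi
    ks <- if (coord == "r") params$k_r123 else params$k_phi123
    kc <- if (coord == "r") params$k_r else params$k_phi
    a <- ends(ta, coord); b <- ends(tb, coord)
    for (i in 1:59) {
      w <- if (node_group[i] == 0L) 1 else ks[node_group[i]]
      total <- total + kc * w * lam[i] *
        (abs(a$lo[i] - b$lo[i]) + abs(a$hi[i] - b$hi[i]))
    }
  }
  total
}

# similarity transform of a 68 x 2 landmark matrix
similarity_transform <- function(lm, scale = 1, angle = 0, shift = c(0, 0)) {
  R <- rbind(c(cos(angle), -sin(angle)), c(sin(angle), cos(angle)))
  sweep(scale * (lm %*% t(R)), 2L, shift, "+")
}

max_tree_diff <- function(t1, t2) {
  dphi <- atan2(sin(t1$phi - t2$phi), cos(t1$phi - t2$phi))
  max(abs(t1$r - t2$r), abs(dphi))
}

# exhaustive adjacent-pair scan for modality outsets
brute_events <- function(frames) {
  act <- list(Animation = frames$animation != "None",
              Sound = frames$sound == "yes",
              LEDs = frames$leds == "yes",
              Speaking = frames$speaking == "yes")
  out <- data.frame(k = integer(0), modality = character(0))
  for (k in seq_len(nrow(frames))[-1L]) {
    for (m in names(act)) {
      if (act[[m]][k] && !act[[m]][k - 1L])
        out <- rbind(out, data.frame(k = k, modality = m))
    }
  }
  out
}

# direct per-event recount of transitions
brute_transitions <- function(states, events, lag) {
  mods <- c("Animation", "Sound", "LEDs", "Speaking")
  yes <- stats::setNames(integer(4L), mods)
  no <- yes
  labels <- character(0)
  for (i in seq_len(nrow(events))) {
    k <- events$k[i]; m <- events$modality[i]
    if (k - 1L < 1L || k + lag > length(states)) next
    a <- states[k - 1L]; b <- states[k + lag]
    if (a != b) {
      yes[m] <- yes[m] + 1L
      labels <- c(labels, paste0(a, b))
    } else no[m] <- no[m] + 1L
  }
  list(yes = yes, no = no, labels = sort(labels))
}

# tests every substring of a state vector against the pattern definition:
# spans exactly n_runs maximal runs of the full series, all run lengths
# <= max_run, at least min_distinct distinct states
brute_patterns <- function(s, min_distinct = 3, max_run = 3, n_runs = 3) {
  n <- length(s)
  rows <- list()
  for (i in seq_len(n)) for (j in i:n) {
    if (i > 1L && s[i - 1L] == s[i]) next       # must start a maximal run
    if (j < n && s[j + 1L] == s[j]) next        # must end a maximal run
    r <- rle(s[i:j])
    if (length(r$values) != n_runs) next
    if (length(unique(r$values)) < min_distinct) next
    if (any(r$lengths > max_run)) next
    rows[[length(rows) + 1L]] <- data.frame(
      start = i, end = j,
      variant = paste(s[i:j], collapse = ""),
      class = paste(r$values, collapse = ""), stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(0), end = integer(0),
               variant = character(0), class = character(0),
               stringsAsFactors = FALSE)
}

# frame data.frame skeleton: fixed valid landmarks on complete rows, NA
# landmarks on the others; action columns default to inactive
make_frames <- function(n, complete = rep(TRUE, n),
                        animation = rep("None", n),
                        sound = rep("no", n), leds = rep("no", n),
                        speaking = rep("no", n), state = NULL) {
  base_lm <- generate_pose_landmarks("FrontProper", 1, noise = 0, seed = 1)[[1]]
  lm <- matrix(rep(as.vector(t(base_lm)), n), nrow = n, byrow = TRUE)
  lm[!complete, ] <- NA_real_
  lm_df <- as.data.frame(lm)
  names(lm_df) <- as.vector(rbind(paste0("x", 0:67), paste0("y", 0:67)))
  df <- data.frame(
    timestamp = format(as.POSIXct("2021-05-10 10:00:00", tz = "UTC") +
                         (seq_len(n) - 1) / 3, "%Y-%m-%d %H:%M:%OS2"),
    animation = animation, sound = sound, leds = leds, speaking = speaking,
    stringsAsFactors = FALSE)
  df <- cbind(df, lm_df)
  if (!is.null(state)) df$state <- state
  df
}

# small labeled pose corpus memoised across tests (built once per run)
.pose_corpus_cache <- new.env(parent = emptyenv())
cached_pose_corpus <- function(n_per_class = 12, noise = "near_normal",
                               seed = 42) {
  key <- paste(n_per_class, noise, seed)
  if (is.null(.pose_corpus_cache[[key]]))
    .pose_corpus_cache[[key]] <- generate_pose_corpus(n_per_class, noise, seed)
  .pose_corpus_cache[[key]]
}
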