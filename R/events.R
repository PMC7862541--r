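## Detection of orientation-flip and unbinding events in equilibrium
## repeats. Repeats where the guest flips to the opposite pose or leaves the
## host are excluded from the free energy analysis; the per-frame labels
## also feed the FES stage (unbound/surface states are masked out there).

#' Label frames and classify a repeat by pose-flip / unbinding events
#'
#' Frames are labelled `primary`, `secondary` or `unbound` from the
#' orientation cosine and the host-guest COM distance. A state change is
#' accepted only with hysteresis: the new state's observable must exceed the
#' band (|cos| > `flip_hysteresis` for poses, distance > `unbind_distance`
#' for unbinding) for at least `min_persistence` consecutive frames.
#' Frames inside the hysteresis band inherit the current state.
#'
#' The repeat verdict is `clean` if the trajectory stays in its starting
#' pose, `flipped` (with the first frame of the accepted opposite-pose run)
#' if the orientation reverses, or `unbound` (with the first frame of the
#' accepted unbound run). Unbinding takes precedence over flipping when both
#' occur; the earlier event wins.
#'
#' @param series A [geometry_series()].
#' @param flip_hysteresis Cosine band half-width; |cos| must exceed this for
#'   a pose state to be asserted (default 0.2).
#' @param unbind_distance COM distance above which the guest counts as
#'   unbound, nm (default 1.5).
#' @param min_persistence Minimum consecutive frames for a state change
#'   (default 50).
#' @return List with `labels` (per-frame factor), `verdict` ("clean",
#'   "flipped", "unbound"), `event_frame` (0-based, NA for clean),
#'   `low_confidence` (TRUE when < 50% of frames assert any state).
#' @export
filter_events <- function(series, flip_hysteresis = 0.2,
                          unbind_distance = 1.5, min_persistence = 50L) {
  if (nrow(series) < 1L) stop("series is empty")
  if (flip_hysteresis < 0 || flip_hysteresis >= 1)
    stop("flip_hysteresis must be in [0, 1)")
  n <- nrow(series)
  cosv <- series$orientation_cos
  dist <- series$com_distance
  min_persistence <- max(1L, as.integer(min_persistence))

  ## raw per-frame state assertions: 1 primary, -1 secondary, 2 unbound,
  ## 0 no assertion (inside hysteresis band)
  raw <- integer(n)
  raw[cosv > flip_hysteresis] <- 1L
  raw[cosv < -flip_hysteresis] <- -1L
  raw[dist > unbind_distance] <- 2L

  ## run-length filter: a state is accepted once asserted for
  ## min_persistence consecutive frames; until then the previous accepted
  ## state persists
  r <- rle(raw)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  state <- integer(n)
  cur <- 0L
  accepted <- list()  # (state, start) of each accepted run
  for (k in seq_along(r$values)) {
    v <- r$values[k]
    if (v != 0L && v != cur && r$lengths[k] >= min_persistence) {
      cur <- v
      accepted[[length(accepted) + 1L]] <- c(v, starts[k])
    }
    state[starts[k]:ends[k]] <- cur
  }
  ## frames before the first accepted state inherit it retroactively
  if (cur != 0L && any(state == 0L)) {
    first_acc <- accepted[[1L]]
    state[seq_len(first_acc[2] - 1L)][
      state[seq_len(first_acc[2] - 1L)] == 0L] <- first_acc[1]
  }

  lab <- factor(ifelse(state == 2L, "unbound",
                ifelse(state == -1L, "secondary",
                ifelse(state == 1L, "primary", "undetermined"))),
                levels = c("primary", "secondary", "unbound", "undetermined"))

  verdict <- "clean"; event_frame <- NA_integer_
  if (length(accepted) >= 1L) {
    start_state <- accepted[[1L]][1]
    for (a in accepted[-1L]) {
      if (a[1] == 2L) {
        verdict <- "unbound"
        event_frame <- series$frame_index[a[2]]
        break
      }
      if (a[1] == -start_state && a[1] %in% c(-1L, 1L)) {
        verdict <- "flipped"
        event_frame <- series$frame_index[a[2]]
        break
      }
    }
  }
  low_confidence <- mean(raw != 0L) < 0.5
  list(labels = lab, verdict = verdict, event_frame = event_frame,
       low_confidence = low_confidence)
}
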