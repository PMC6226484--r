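#' Viterbi state assignment of a photon trajectory
#'
#' Computes the most probable per-photon hidden state sequence under a
#' kinetic model, maximizing
#' `p_eq(s_1) F(c_1)_{s_1} prod_i [exp(K tau_i)]_{s_i, s_{i-1}} F(c_i)_{s_i}`
#' by max-product dynamic programming in log space. Ties are broken toward
#' the lower state index (bound first in the canonical ordering).
#'
#' @param traj A [photon_trajectory()].
#' @param model A [kinetic_model()] (normally the two-state model).
#' @return A `state_path`: list with `states` (integer per photon),
#'   `transitions` (data frame with the photon indices `i_before`/`i_after`
#'   bracketing each state change, the interval midpoint `time`, and
#'   `from`/`to` state indices), and the source trajectory `id`.
#' @export
viterbi_path <- function(traj, model) {
  stopifnot(inherits(model, "kinetic_model"))
  tc <- photon_records(traj)
  if (!length(tc$times)) stop("empty trajectory")
  states <- .viterbi_cpp(diff(tc$times), tc$colors, model$K, model$E_diag,
                         model$p_eq)
  ch <- which(diff(states) != 0)
  transitions <- data.frame(
    i_before = ch, i_after = ch + 1L,
    time = (tc$times[ch] + tc$times[ch + 1L]) / 2,
    from = states[ch], to = states[ch + 1L]
  )
  structure(list(states = states, transitions = transitions,
                 times = tc$times,
                 id = if (!is.null(traj$id)) traj$id else "traj"),
            class = "state_path")
}

#' Filter transitions by flanking residence times
#'
#' Retains only state changes whose dwell times on both sides are at least
#' `min_residence`; shorter excursions (typically acceptor-blinking
#' artifacts) are merged into the surrounding state rather than deleted, so
#' photon coverage is preserved. The dwell of a run is measured between the
#' midpoints of its bracketing transition intervals (or the trajectory
#' ends).
#'
#' @param path A `state_path` from [viterbi_path()].
#' @param min_residence Minimum residence time in seconds (default 200 us).
#' @return A data frame of retained transitions: `time` (interval midpoint,
#'   s), `i_before`, `i_after`, `from`, `to`, `direction`
#'   (`"binding"` if the new state has a lower index), `left_dwell_s`,
#'   `right_dwell_s`.
#' @export
find_transitions <- function(path, min_residence = 200e-6) {
  stopifnot(inherits(path, "state_path"))
  times <- path$times
  states <- path$states
  runs <- run_table(states, times)
  # iteratively merge the shortest sub-threshold run into its neighbours
  repeat {
    if (nrow(runs) <= 1) break
    short <- which(runs$dwell < min_residence)
    if (!length(short)) break
    k <- short[which.min(runs$dwell[short])]
    runs$state[k] <- if (k > 1) runs$state[k - 1] else runs$state[k + 1]
    runs <- collapse_runs(runs, times)
  }
  if (nrow(runs) <= 1) return(empty_transitions())
  b <- seq_len(nrow(runs) - 1)
  i_before <- runs$i_end[b]
  i_after <- runs$i_start[b + 1]
  out <- data.frame(
    time = (times[i_before] + times[i_after]) / 2,
    i_before = i_before, i_after = i_after,
    from = runs$state[b], to = runs$state[b + 1],
    direction = ifelse(runs$state[b + 1] < runs$state[b],
                       "binding", "dissociation"),
    left_dwell_s = runs$dwell[b], right_dwell_s = runs$dwell[b + 1]
  )
  out[out$left_dwell_s >= min_residence & out$right_dwell_s >= min_residence, ,
      drop = FALSE]
}

empty_transitions <- function() {
  data.frame(time = numeric(), i_before = integer(), i_after = integer(),
             from = integer(), to = integer(), direction = character(),
             left_dwell_s = numeric(), right_dwell_s = numeric())
}

run_table <- function(states, times) {
  r <- rle(states)
  i_end <- cumsum(r$lengths)
  i_start <- i_end - r$lengths + 1L
  runs <- data.frame(state = r$values, i_start = i_start, i_end = i_end)
  add_dwells(runs, times)
}

add_dwells <- function(runs, times) {
  n <- nrow(runs)
  # run boundaries at the midpoints of the flanking transition intervals
  lo <- c(times[1],
          if (n > 1) (times[runs$i_end[-n]] + times[runs$i_start[-1]]) / 2)
  hi <- c(lo[-1], times[length(times)])
  runs$dwell <- hi - lo
  runs
}

collapse_runs <- function(runs, times) {
  keep <- c(TRUE, runs$state[-1] != runs$state[-nrow(runs)])
  grp <- cumsum(keep)
  out <- data.frame(
    state = runs$state[keep],
    i_start = tapply(runs$i_start, grp, min),
    i_end = tapply(runs$i_end, grp, max)
  )
  rownames(out) <- NULL
  add_dwells(out, times)
}

#' Extract single-transition photon segments
#'
#' Cuts a window around each retained transition for the endpoint-vector
#' likelihood analysis. The window is centred on the transition-interval
#' midpoint, truncated at neighbouring transitions and the trajectory ends,
#' dropped if shorter than `min_window` and capped at `max_window`.
#'
#' @param traj The parent [photon_trajectory()].
#' @param transitions Data frame from [find_transitions()].
#' @param window_total Target total window length in seconds (default 2 ms).
#' @param min_window Minimum acceptable window (default 400 us).
#' @param max_window Maximum window (default 3 ms).
#' @return A list of `transition_segment` objects: photon `times`/`colors`
#'   inside the window, `direction`, transition `midpoint` and `window`
#'   bounds.
#' @export
extract_segments <- function(traj, transitions, window_total = 2e-3,
                             min_window = 400e-6, max_window = 3e-3) {
  tc <- photon_records(traj)
  window_total <- min(window_total, max_window)
  if (!nrow(transitions)) return(list())
  out <- list()
  for (k in seq_len(nrow(transitions))) {
    mid <- transitions$time[k]
    lo <- mid - window_total / 2
    hi <- mid + window_total / 2
    # truncate at the neighbouring transition midpoints and trajectory ends
    if (k > 1) lo <- max(lo, transitions$time[k - 1])
    if (k < nrow(transitions)) hi <- min(hi, transitions$time[k + 1])
    lo <- max(lo, tc$times[1])
    hi <- min(hi, tc$times[length(tc$times)])
    if (hi - lo < min_window) next
    sel <- tc$times >= lo & tc$times <= hi
    if (sum(sel) < 2) next
    out[[length(out) + 1]] <- structure(
      list(traj_id = if (!is.null(traj$id)) traj$id else "traj",
           times = tc$times[sel], colors = tc$colors[sel],
           direction = transitions$direction[k],
           midpoint = mid, window = c(lo, hi)),
      class = "transition_segment")
  }
  out
}

#' @export
print.transition_segment <- function(x, ...) {
  cat(sprintf(
    "transition_segment (%s) from '%s': %d photons in [%.6f, %.6f] s, midpoint %.6f s\n",
    x$direction, x$traj_id, length(x$times), x$window[1], x$window[2],
    x$midpoint))
  invisible(x)
}

#' Keep only the first binding event of each trajectory
#'
#' When the acceptor arrives with the binding partner (barnase/barstar-style
#' labeling) later apparent dissociations cannot be distinguished from
#' acceptor photobleaching, so only the first observed binding transition of
#' each molecule is analysed. A trajectory that starts bound contributes no
#' event.
#'
#' @param transitions Data frame from [find_transitions()], or a list of
#'   such data frames (one per trajectory).
#' @return The filtered transition data frame (or list thereof).
#' @export
first_event_only <- function(transitions) {
  if (is.data.frame(transitions)) {
    bind <- transitions[transitions$direction == "binding", , drop = FALSE]
    return(utils::head(bind, 1))
  }
  lapply(transitions, first_event_only)
}
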