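#' Simulation configuration
#'
#' Describes the generative world for the continuous-time Markov photon
#' simulator: binding kinetics, optional transient-complex and blinking
#' parameters, photon count rate, bleaching rates, and bookkeeping.
#'
#' @param two A [two_state_params()].
#' @param tc Optional [tc_params()] (adds the transient complex; note the
#'   simulator uses the *unreduced* binding rates).
#' @param blink Optional [blink_params()]; the dark-state entry rate is tied
#'   to `rate_ms` as `k_d = k_0 * rate_ms / 100`.
#' @param rate_ms Photon count rate in photons/ms (homogeneous Poisson).
#' @param duration Trajectory duration in seconds.
#' @param n_traj Number of trajectories.
#' @param k_bleach Acceptor photobleaching rate (s^-1, 0 disables). With
#'   `bleach_mode = "immobilized"` (acceptor on the immobilized molecule) the
#'   bleach is permanent: the molecule emits at the donor-leak efficiency for
#'   the rest of the trajectory. With `bleach_mode = "partner"` (acceptor
#'   arrives with the binding partner, barnase/barstar style) the bleach only
#'   blinds the current bound period: the molecule enters a hidden
#'   bound-bleached state that emits at the donor-leak level until it
#'   dissociates, and the next binding event carries a fresh acceptor. In
#'   partner mode the bleach hazard applies only while bound.
#' @param bleach_mode `"immobilized"` or `"partner"` (see `k_bleach`).
#' @param k_donor_bleach Donor photobleaching rate (s^-1, 0 disables); a
#'   donor bleach truncates the trajectory.
#' @param E_leak Donor-leak apparent efficiency used after acceptor bleach
#'   (default 0.06).
#' @param seed Optional integer seed recorded in the output metadata.
#' @param condition Condition label recorded in metadata.
#' @return A `sim_config` object.
#' @export
sim_config <- function(two, tc = NULL, blink = NULL, rate_ms = 100,
                       duration = 1, n_traj = 10, k_bleach = 0,
                       bleach_mode = c("immobilized", "partner"),
                       k_donor_bleach = 0, E_leak = 0.06, seed = NULL,
                       condition = "sim") {
  bleach_mode <- match.arg(bleach_mode)
  stopifnot(inherits(two, "two_state_params"), rate_ms >= 0, duration > 0,
            n_traj >= 1, k_bleach >= 0, k_donor_bleach >= 0)
  if (bleach_mode == "partner" && (!is.null(tc) || !is.null(blink)))
    stop("partner-style bleaching is implemented for the plain two-state model")
  structure(list(two = two, tc = tc, blink = blink, rate_ms = rate_ms,
                 duration = duration, n_traj = n_traj, k_bleach = k_bleach,
                 bleach_mode = bleach_mode,
                 k_donor_bleach = k_donor_bleach, E_leak = E_leak,
                 seed = seed, condition = condition),
            class = "sim_config")
}

# kinetic state space for the simulator: unreduced binding rates, optional
# TC state, optionally crossed with the blinking chain
sim_model <- function(cfg) {
  two <- cfg$two
  if (is.null(cfg$tc)) {
    base <- make_two_state(two)
  } else {
    tc_full <- tc_params(k_TC = cfg$tc$k_TC, E_TC = cfg$tc$E_TC,
                         rate_reduction = 1)  # simulator uses true rates
    base <- make_three_state_tc(two, tc_full)
  }
  if (is.null(cfg$blink)) return(base)
  if (is.null(cfg$tc)) make_four_state(two, cfg$blink, n = cfg$rate_ms)
  else make_six_state_tc(two, tc_params(k_TC = cfg$tc$k_TC,
                                        E_TC = cfg$tc$E_TC,
                                        rate_reduction = 1),
                         cfg$blink, n = cfg$rate_ms)
}

# partner-carried acceptor with photobleaching: states (B, U, B*) where B*
# is bound with a bleached acceptor (emits at the donor-leak level); the
# bleach hazard k_bleach acts only while bound, dissociation from B* restores
# the normal cycle (the next partner carries a fresh acceptor).  Illumination
# starts at t = 0, so the start distribution is the unbleached equilibrium.
partner_bleach_model <- function(cfg) {
  kA <- cfg$two$k_A_app; kD <- cfg$two$k_D; kb <- cfg$k_bleach
  K <- matrix(c(
    -kD - kb, kD,        kb,
    kA,       -kA,       0,
    0,        kD,        -kD
  ), 3, 3)
  pB <- kA / (kA + kD)
  list(K = K, E_diag = c(cfg$two$E_B, cfg$two$E_U, cfg$E_leak),
       p_eq_start = c(pB, 1 - pB, 0))
}

# Gillespie simulation of one state path; returns step function (times,
# states) with switch times in (0, duration)
gillespie_path <- function(K, p_eq, duration) {
  n <- nrow(K)
  exit <- -diag(K)
  jump <- lapply(seq_len(n), function(j) {
    r <- K[, j]; r[j] <- 0
    if (sum(r) > 0) r / sum(r) else r
  })
  s <- sample.int(n, 1, prob = p_eq)
  t <- 0
  times <- numeric(0); states <- s
  while (TRUE) {
    rate <- exit[s]
    if (rate <= 0) break
    t <- t + stats::rexp(1, rate)
    if (t >= duration) break
    s <- sample.int(n, 1, prob = jump[[s]])
    times <- c(times, t); states <- c(states, s)
  }
  list(switch_times = times, states = states)
}

state_at <- function(path, t) {
  path$states[findInterval(t, path$switch_times) + 1L]
}

#' Simulate photon trajectories from a continuous-time Markov model
#'
#' Gillespie simulation of the kinetic state path (binding, optional
#' transient complex, optional acceptor blinking), followed by homogeneous
#' Poisson photon emission at the configured count rate, with each photon
#' colored acceptor with probability equal to the apparent FRET efficiency
#' of the state occupied at its arrival time. Acceptor photobleaching (rate
#' `k_bleach`) irreversibly switches emission to the donor-leak efficiency;
#' donor photobleaching truncates the trajectory. Random numbers are drawn
#' in a fixed documented order (state path, then bleach times, then photon
#' times, then colors) so a seed reproduces trajectories bit-identically.
#'
#' @param cfg A [sim_config()].
#' @return A list of [photon_trajectory()] objects. Each carries the ground
#'   truth and seed in its metadata.
#' @export
simulate_ctmc_photons <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (cfg$rate_ms == 0) {
    warning("zero count rate: returning empty trajectories")
    return(lapply(seq_len(cfg$n_traj), function(i)
      photon_trajectory(numeric(0), integer(0), id = paste0("sim", i))))
  }
  partner <- !is.null(cfg$bleach_mode) && cfg$bleach_mode == "partner" &&
    cfg$k_bleach > 0
  model <- if (partner) partner_bleach_model(cfg) else sim_model(cfg)
  rate_s <- cfg$rate_ms * 1000
  meta <- list(condition = cfg$condition, seed = cfg$seed,
               truth = cfg)
  lapply(seq_len(cfg$n_traj), function(i) {
    p0 <- if (partner) c(model$p_eq_start) else model$p_eq
    path <- gillespie_path(model$K, p0, cfg$duration)
    t_able <- if (!partner && cfg$k_bleach > 0) stats::rexp(1, cfg$k_bleach)
              else Inf
    t_dble <- if (cfg$k_donor_bleach > 0) stats::rexp(1, cfg$k_donor_bleach)
              else Inf
    dur <- min(cfg$duration, t_dble)
    n_ph <- stats::rpois(1, rate_s * dur)
    times <- sort(stats::runif(n_ph, 0, dur))
    times <- times[!duplicated(times)]
    E <- model$E_diag[state_at(path, times)]
    E[times > t_able] <- cfg$E_leak
    colors <- as.integer(stats::runif(length(times)) < E)
    photon_trajectory(times, colors, id = paste0("sim", i), meta = meta)
  })
}

#' Recolor a photon trajectory around a transition
#'
#' The interval-preserving recoloring simulator: photon arrival times are
#' kept exactly and only the colors are redrawn. A transient-complex region
#' of exponentially distributed duration (mean `t_TC`) is centred on the
#' midpoint of the identified transition interval (split symmetrically,
#' truncated at the window edges); the flanking regions are assigned unbound
#' and bound according to `direction`. Photons are recolored acceptor with
#' probability `E_U`, `E_TC` or `E_B` by region. If blinking parameters are
#' given, alternating bright/dark intervals are then drawn from the blinking
#' kinetics (dark entry rate tied to the trajectory count rate) and photons
#' inside dark intervals are recolored with the donor-leak efficiency 0.06.
#'
#' @param traj A [photon_trajectory()] (or transition segment).
#' @param transition_time Midpoint of the transition interval in seconds; if
#'   `NULL` and `traj` is a `transition_segment`, its recorded midpoint.
#' @param t_TC Mean transient-complex duration in seconds (0 for an
#'   instantaneous transition).
#' @param E_B,E_TC,E_U Apparent efficiencies of the three regions.
#' @param direction `"binding"` (unbound before, bound after) or
#'   `"dissociation"`.
#' @param blink Optional [blink_params()].
#' @param E_leak Dark-state recoloring efficiency (default 0.06).
#' @return A trajectory/segment of the same class with identical times and
#'   new colors; attributes `tc_drawn` and `tc_effective` record the drawn
#'   and window-truncated TC durations.
#' @export
recolor_trajectory <- function(traj, transition_time = NULL, t_TC, E_B, E_TC,
                               E_U, direction = c("binding", "dissociation"),
                               blink = NULL, E_leak = 0.06) {
  direction <- match.arg(direction)
  tc <- photon_records(traj)
  if (is.null(transition_time)) {
    if (!is.null(traj$midpoint)) transition_time <- traj$midpoint
    else stop("transition_time missing and trajectory carries no midpoint")
  }
  times <- tc$times
  if (!length(times)) stop("empty trajectory")
  w_lo <- if (!is.null(traj$window)) traj$window[1] else times[1]
  w_hi <- if (!is.null(traj$window)) traj$window[2] else times[length(times)]

  drawn <- if (t_TC > 0) stats::rexp(1, 1 / t_TC) else 0
  lo <- max(transition_time - drawn / 2, w_lo)
  hi <- min(transition_time + drawn / 2, w_hi)

  E_pre <- if (direction == "binding") E_U else E_B
  E_post <- if (direction == "binding") E_B else E_U
  E <- ifelse(times < lo, E_pre, ifelse(times <= hi & drawn > 0, E_TC, E_post))

  if (!is.null(blink)) {
    n_ms <- length(times) / ((w_hi - w_lo) * 1000)
    k_d <- blink$k_0 * n_ms / blink$n_0
    dark <- blink_intervals(w_lo, w_hi, k_d, blink$k_b)
    if (nrow(dark)) {
      in_dark <- vapply(times, function(tt)
        any(tt >= dark$lo & tt < dark$hi), TRUE)
      E[in_dark] <- E_leak
    }
  }
  colors <- as.integer(stats::runif(length(times)) < E)
  out <- traj
  out$colors <- colors
  attr(out, "tc_drawn") <- drawn
  attr(out, "tc_effective") <- max(hi - lo, 0)
  out
}

# alternating bright/dark renewal process over [lo, hi]; returns dark spans
blink_intervals <- function(lo, hi, k_d, k_b) {
  p_b <- k_b / (k_b + k_d)
  bright <- stats::runif(1) < p_b
  t <- lo
  dark_lo <- numeric(0); dark_hi <- numeric(0)
  while (t < hi) {
    dwell <- stats::rexp(1, if (bright) k_d else k_b)
    t2 <- min(t + dwell, hi)
    if (!bright) { dark_lo <- c(dark_lo, t); dark_hi <- c(dark_hi, t2) }
    t <- t2
    bright <- !bright
  }
  data.frame(lo = dark_lo, hi = dark_hi)
}

#' Simulate single-transition photon segments
#'
#' Generates ready-to-analyse transition segments the way the recoloring
#' protocol does: homogeneous Poisson photon times over the window, the
#' transition interval at the window centre, and colors drawn with a
#' transient-complex region of mean duration `t_TC` (possibly 0) centred on
#' it. Binding and dissociation segments alternate.
#'
#' @param n_segments Number of segments.
#' @param t_TC Mean transient-complex duration (s); 0 for instantaneous.
#' @param E_B,E_TC,E_U Apparent efficiencies.
#' @param rate_ms Photon count rate in photons/ms.
#' @param window Total window length in seconds (default 2 ms).
#' @param blink Optional [blink_params()].
#' @return A list of `transition_segment` objects.
#' @export
simulate_transition_segments <- function(n_segments, t_TC, E_B, E_TC, E_U,
                                         rate_ms = 500, window = 2e-3,
                                         blink = NULL) {
  lapply(seq_len(n_segments), function(i) {
    repeat {
      n_ph <- stats::rpois(1, rate_ms * 1000 * window)
      if (n_ph >= 10) break
    }
    times <- sort(stats::runif(n_ph, 0, window))
    times <- times[!duplicated(times)]
    dirn <- if (i %% 2 == 1) "binding" else "dissociation"
    seg <- structure(
      list(traj_id = sprintf("seg%03d", i), times = times,
           colors = integer(length(times)), direction = dirn,
           midpoint = window / 2, window = c(0, window)),
      class = "transition_segment")
    recolor_trajectory(seg, transition_time = window / 2, t_TC = t_TC,
                       E_B = E_B, E_TC = E_TC, E_U = E_U,
                       direction = dirn, blink = blink)
  })
}

#' Generate a monotone condition series with ground-truth manifest
#'
#' Emulates an ionic-strength titration: per condition the generator
#' parameters are interpolated between the endpoints of `series` (e.g. `E_U`
#' rising, `k_D` and `k_A_app` rising), one simulated dataset per condition,
#' with the ground truth recorded in a manifest for recovery tests.
#'
#' @param base_cfg A [sim_config()] providing every non-varying setting.
#' @param series Named list of length-2 numeric vectors `c(from, to)` for any
#'   of `E_U`, `E_B`, `k_A_app`, `k_D`; values are interpolated linearly
#'   across conditions.
#' @param n_conditions Number of conditions.
#' @param labels Optional condition labels (default `cond1..condN`).
#' @return A list with `datasets` (list of trajectory lists) and `manifest`
#'   (data frame of ground-truth parameters per condition).
#' @export
generate_condition_series <- function(base_cfg, series, n_conditions = 4,
                                      labels = NULL) {
  stopifnot(inherits(base_cfg, "sim_config"), length(series) >= 1)
  if (is.null(labels)) labels <- paste0("cond", seq_len(n_conditions))
  f <- seq(0, 1, length.out = n_conditions)
  par0 <- base_cfg$two
  manifest <- data.frame(condition = labels,
                         E_B = par0$E_B, E_U = par0$E_U,
                         k_A_app = par0$k_A_app, k_D = par0$k_D)
  for (nm in names(series)) {
    rng <- series[[nm]]
    manifest[[nm]] <- rng[1] + f * (rng[2] - rng[1])
  }
  datasets <- lapply(seq_len(n_conditions), function(i) {
    cfg <- base_cfg
    cfg$two <- two_state_params(manifest$E_B[i], manifest$E_U[i],
                                manifest$k_A_app[i], manifest$k_D[i])
    cfg$condition <- labels[i]
    cfg$seed <- NULL  # caller controls the RNG stream
    simulate_ctmc_photons(cfg)
  })
  list(datasets = datasets, manifest = manifest)
}
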