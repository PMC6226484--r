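#' Photon-by-photon log-likelihood under equilibrium initial conditions
#'
#' Evaluates `ln L = ln( 1^T prod_i [F(c_i) exp(K tau_i)] F(c_1) p_eq )`,
#' where `F(acceptor) = diag(E)`, `F(donor) = I - diag(E)` and `tau_i` is the
#' interval between consecutive photons. The product is evaluated through the
#' eigendecomposition of `K`, renormalizing the propagated vector after every
#' photon so trajectories of >1e6 photons are numerically stable.
#'
#' @param traj A [photon_trajectory()] (or a transition segment).
#' @param model A [kinetic_model()].
#' @return The log-likelihood; `-Inf` for a zero-probability trajectory
#'   (e.g. an acceptor photon when every state has `E = 0`).
#' @examples
#' m <- make_two_state(two_state_params(0.6, 0.25, 300, 100))
#' tr <- photon_trajectory(c(0, 1e-3, 2e-3), c(1L, 1L, 0L))
#' log_likelihood_eq(tr, m)
#' @export
log_likelihood_eq <- function(traj, model) {
  stopifnot(inherits(model, "kinetic_model"))
  tc <- photon_records(traj)
  n <- length(model$p_eq)
  .photon_loglik_cpp(diff(tc$times), tc$colors, model$K, model$E_diag,
                     model$p_eq, rep(1, n))
}

#' Photon log-likelihood with fixed endpoint state vectors
#'
#' Evaluates `ln( v_fin^T prod_i [F(c_i) exp(K tau_i)] F(c_1) v_ini )` for a
#' photon segment known to contain a single transition, with occupancy
#' vectors pinning the states at the segment start and end.
#'
#' @param seg A [photon_trajectory()] or transition segment.
#' @param model A [kinetic_model()].
#' @param ends A list with numeric vectors `v_ini` and `v_fin` (see
#'   [endpoint_vectors()]).
#' @return The log-likelihood (`-Inf` if the segment has zero probability).
#' @export
log_likelihood_endpoint <- function(seg, model, ends) {
  stopifnot(inherits(model, "kinetic_model"))
  tc <- photon_records(seg)
  .photon_loglik_cpp(diff(tc$times), tc$colors, model$K, model$E_diag,
                     as.numeric(ends$v_ini), as.numeric(ends$v_fin))
}

photon_records <- function(x) {
  if (inherits(x, "photon_trajectory") || inherits(x, "transition_segment"))
    return(list(times = x$times, colors = x$colors))
  if (is.list(x) && !is.null(x$times) && !is.null(x$colors))
    return(list(times = as.numeric(x$times), colors = encode_colors(x$colors)))
  stop("expected a photon_trajectory or transition_segment")
}

#' Endpoint state vectors for a single-transition segment
#'
#' For a binding segment the molecule starts unbound and ends bound (and vice
#' versa for dissociation). With acceptor blinking the initial occupancy is
#' split between the bright and dark manifolds by the bright-state population
#' `p_b`, while the final vector sums over both manifolds, e.g.
#' `v_ini = (0, 0, p_b, 0, 0, 1 - p_b)` and `v_fin = (1, 0, 0, 1, 0, 0)` for
#' a six-state binding transition.
#'
#' @param model A [kinetic_model()] with 2, 3, 4 or 6 states in the canonical
#'   ordering.
#' @param direction `"binding"` or `"dissociation"`.
#' @param p_b Acceptor bright-state population (used for 4/6-state models).
#' @return A list with `v_ini` and `v_fin`.
#' @export
endpoint_vectors <- function(model, direction = c("binding", "dissociation"),
                             p_b = 1) {
  direction <- match.arg(direction)
  n <- length(model$p_eq)
  if (n == 2) {
    vi <- c(0, 1); vf <- c(1, 0)
  } else if (n == 3) {
    vi <- c(0, 0, 1); vf <- c(1, 0, 0)
  } else if (n == 4) {
    vi <- c(0, p_b, 0, 1 - p_b); vf <- c(1, 0, 1, 0)
  } else if (n == 6) {
    vi <- c(0, 0, p_b, 0, 0, 1 - p_b); vf <- c(1, 0, 0, 1, 0, 0)
  } else stop("endpoint vectors defined for 2/3/4/6-state models only")
  if (direction == "binding") list(v_ini = vi, v_fin = vf)
  else list(v_ini = swap_BU(vi, n), v_fin = swap_BU(vf, n))
}

# exchange the roles of B and U (a dissociation is a state-mirrored binding)
swap_BU <- function(v, n) {
  if (n == 2) v[c(2, 1)]
  else if (n == 3) v[c(3, 2, 1)]
  else if (n == 4) v[c(2, 1, 4, 3)]
  else v[c(3, 2, 1, 6, 5, 4)]
}

#' Total log-likelihood of a trajectory set
#'
#' Sums [log_likelihood_eq()] over trajectories (likelihoods are independent
#' across molecules).
#' @param trajs List of [photon_trajectory()] objects.
#' @param model A [kinetic_model()].
#' @return Total log-likelihood.
#' @export
total_log_likelihood <- function(trajs, model) {
  sum(vapply(as_trajectory_list(trajs), log_likelihood_eq, 0, model = model))
}

## ---- fitting machinery ----------------------------------------------------

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

# transform a named natural parameter vector to the unconstrained scale:
# rates -> log, efficiencies/probabilities -> logit
to_trans <- function(par, eff_names) {
  out <- ifelse(names(par) %in% eff_names,
                logit(pmin(pmax(par, 1e-6), 1 - 1e-6)), log(par))
  names(out) <- names(par)
  out
}
from_trans <- function(theta, eff_names) {
  out <- ifelse(names(theta) %in% eff_names, inv_logit(theta), exp(theta))
  names(out) <- names(theta)
  out
}
# |d natural / d transformed| for the delta method
trans_jac <- function(par, eff_names) {
  ifelse(names(par) %in% eff_names, par * (1 - par), par)
}

#' @keywords internal
ml_maximize <- function(negll_trans, start_nat, eff_names, n_starts = 1,
                        maxit = 300) {
  theta0 <- to_trans(start_nat, eff_names)
  # guard: parameter excursions (rate overflow, invalid model) score as a
  # large finite penalty instead of aborting the optimizer
  raw_fn <- negll_trans
  negll_trans <- function(th) {
    v <- tryCatch(raw_fn(th), error = function(e) 1e10)
    if (!is.finite(v)) 1e10 else v
  }
  starts <- list(theta0)
  if (n_starts > 1) {
    for (s in seq_len(n_starts - 1))
      starts[[s + 1]] <- theta0 + stats::runif(length(theta0), -0.7, 0.7)
  }
  best <- NULL
  for (th in starts) {
    fit <- tryCatch(
      stats::optim(th, negll_trans, method = "BFGS",
                   control = list(maxit = maxit, reltol = 1e-8)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("optimization failed from every start")
  se_trans <- rep(NA_real_, length(best$par))
  for (nd in c(1e-4, 1e-3)) {  # coarser retry if the Hessian is indefinite
    H <- tryCatch(
      stats::optimHess(best$par, negll_trans,
                       control = list(ndeps = rep(nd, length(best$par)))),
      error = function(e) NULL)
    if (is.null(H)) next
    cov <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(cov)) next
    d <- diag(cov)
    se_trans <- ifelse(is.finite(d) & d > 0, sqrt(abs(d)), NA_real_)
    if (all(is.finite(se_trans))) break
  }
  par_nat <- from_trans(best$par, eff_names)
  se_nat <- se_trans * trans_jac(par_nat, eff_names)
  names(se_nat) <- names(par_nat)
  list(params = par_nat, stderr = se_nat, lnL = -best$value,
       convergence = best$convergence)
}

new_ml_fit <- function(res, fixed = list(), model_type = "") {
  structure(list(params = res$params, lnL = res$lnL, stderr = res$stderr,
                 convergence = res$convergence, fixed = fixed,
                 model_type = model_type),
            class = "ml_fit")
}

#' @export
print.ml_fit <- function(x, ...) {
  cat(sprintf("%s maximum-likelihood fit (lnL = %.2f, convergence %d)\n",
              x$model_type, x$lnL, x$convergence))
  tab <- data.frame(estimate = signif(x$params, 4),
                    stderr = signif(x$stderr, 3))
  print(tab)
  if (length(x$fixed))
    cat("fixed:", paste(names(x$fixed), unlist(x$fixed), sep = "=",
                        collapse = ", "), "\n")
  invisible(x)
}

#' Maximum-likelihood fit of the two-state binding model
#'
#' Maximizes the summed photon likelihood over
#' `(E_B, E_U, k_A_app, k_D)`. With `fix_pB` supplied (the photobleaching
#' correction for donor-only unbound states) the bound fraction is held fixed
#' and `k_A_app = p_B k_D / (1 - p_B)` is derived, leaving three free
#' parameters.
#'
#' @param trajs List of [photon_trajectory()] objects.
#' @param init Optional named list/vector of starting values
#'   (`E_B, E_U, k_A_app, k_D`).
#' @param fix_pB Optional bound fraction in (0, 1) to hold fixed.
#' @param n_starts Number of optimizer starts (default 1 when `init` is
#'   supplied, otherwise 5 jittered starts).
#' @return An `ml_fit` with estimates, stderr (inverse numerical Hessian) and
#'   the maximized `lnL`.
#' @export
fit_two_state <- function(trajs, init = NULL, fix_pB = NULL, n_starts = NULL) {
  trajs <- as_trajectory_list(trajs)
  dat <- lapply(trajs, function(tr) list(tau = diff(tr$times),
                                         colors = tr$colors))
  if (is.null(n_starts)) n_starts <- if (is.null(init)) 5 else 1
  init <- init_defaults(init, c(E_B = 0.7, E_U = 0.2, k_A_app = 100, k_D = 100))
  eff <- c("E_B", "E_U")

  if (is.null(fix_pB)) {
    start <- unlist(init[c("E_B", "E_U", "k_A_app", "k_D")])
    negll <- function(theta) {
      p <- from_trans(theta, eff)
      two_state_negll(dat, p["E_B"], p["E_U"], p["k_A_app"], p["k_D"])
    }
    res <- ml_maximize(negll, start, eff, n_starts)
    fit <- new_ml_fit(res, model_type = "two-state")
  } else {
    stopifnot(fix_pB > 0, fix_pB < 1)
    start <- unlist(init[c("E_B", "E_U", "k_D")])
    negll <- function(theta) {
      p <- from_trans(theta, eff)
      kA <- fix_pB * p["k_D"] / (1 - fix_pB)
      two_state_negll(dat, p["E_B"], p["E_U"], kA, p["k_D"])
    }
    res <- ml_maximize(negll, start, eff, n_starts)
    kD <- res$params[["k_D"]]
    kA <- fix_pB * kD / (1 - fix_pB)
    res$params <- c(res$params, k_A_app = kA)
    res$stderr <- c(res$stderr,
                    k_A_app = res$stderr[["k_D"]] * fix_pB / (1 - fix_pB))
    fit <- new_ml_fit(res, fixed = list(p_B = fix_pB),
                      model_type = "two-state (fixed p_B)")
  }
  fit
}

two_state_negll <- function(dat, E_B, E_U, kA, kD) {
  K <- matrix(c(-kD, kD, kA, -kA), 2, 2)
  pB <- kA / (kA + kD)
  E <- c(E_B, E_U); p_eq <- c(pB, 1 - pB); one <- c(1, 1)
  ll <- 0
  for (d in dat) {
    v <- .photon_loglik_cpp(d$tau, d$colors, K, E, p_eq, one)
    if (!is.finite(v)) return(1e10)
    ll <- ll + v
  }
  -ll
}

init_defaults <- function(init, defaults) {
  init <- as.list(init)
  for (nm in names(defaults))
    if (is.null(init[[nm]])) init[[nm]] <- defaults[[nm]]
  init
}

#' Maximum-likelihood fit of the four-state model (binding + blinking)
#'
#' Maximizes the summed photon likelihood over
#' `(E_B, E_U, k_A_app, k_D, E_d, k_b, k_0)`, with the per-trajectory
#' dark-state entry rate `k_d = k_0 * (n / 100)` tied to each trajectory's
#' mean count rate `n` (photons/ms).
#'
#' @inheritParams fit_two_state
#' @param fix_E_d Optional fixed dark-state efficiency (e.g. the donor-leak
#'   value 0.06); fitted when `NULL`.
#' @return An `ml_fit`.
#' @export
fit_four_state <- function(trajs, init = NULL, fix_E_d = NULL, n_starts = NULL) {
  trajs <- as_trajectory_list(trajs)
  dat <- lapply(trajs, function(tr) list(tau = diff(tr$times),
                                         colors = tr$colors,
                                         n = count_rate_ms(tr)))
  if (is.null(n_starts)) n_starts <- if (is.null(init)) 5 else 1
  init <- init_defaults(init, c(E_B = 0.7, E_U = 0.2, k_A_app = 100,
                                k_D = 100, E_d = 0.06, k_b = 2000, k_0 = 300))
  eff <- c("E_B", "E_U", "E_d")
  free <- c("E_B", "E_U", "k_A_app", "k_D",
            if (is.null(fix_E_d)) "E_d", "k_b", "k_0")
  start <- unlist(init[free])

  negll <- function(theta) {
    p <- from_trans(theta, eff)
    E_d <- if (is.null(fix_E_d)) p[["E_d"]] else fix_E_d
    four_state_negll(dat, p[["E_B"]], p[["E_U"]], p[["k_A_app"]],
                     p[["k_D"]], E_d, p[["k_b"]], p[["k_0"]])
  }
  res <- ml_maximize(negll, start, eff, n_starts)
  fixed <- if (is.null(fix_E_d)) list() else list(E_d = fix_E_d)
  new_ml_fit(res, fixed = fixed, model_type = "four-state")
}

four_state_negll <- function(dat, E_B, E_U, kA, kD, E_d, kb, k0) {
  pB <- kA / (kA + kD)
  E <- c(E_B, E_U, E_d, E_d)
  one <- rep(1, 4)
  ll <- 0
  for (d in dat) {
    kd <- k0 * (d$n / 100)
    K <- matrix(c(
      -kD - kd, kD,       kd,       0,
      kA,       -kA - kd, 0,        kd,
      kb,       0,        -kD - kb, kD,
      0,        kb,       kA,       -kA - kb
    ), 4, 4)
    pb <- kb / (kb + kd)
    p_eq <- c(pB * pb, (1 - pB) * pb, pB * (1 - pb), (1 - pB) * (1 - pb))
    v <- .photon_loglik_cpp(d$tau, d$colors, K, E, p_eq, one)
    if (!is.finite(v)) return(1e10)
    ll <- ll + v
  }
  -ll
}

#' Bound fraction from trajectory start states
#'
#' When acceptor photobleaching is indistinguishable from dissociation
#' (donor-only unbound state), dwell-based estimates of the bound fraction
#' are biased. The start state of each trajectory is unaffected by later
#' bleaching, so `p_B` is estimated as the fraction of trajectories whose
#' initial photons have mean apparent efficiency above the midpoint
#' threshold `(E_B + E_U)/2`.
#'
#' @param trajs List of [photon_trajectory()] objects.
#' @param E_B,E_U Apparent efficiencies used to set the threshold.
#' @param window Initial classification window in seconds (default 0.05).
#' @return Estimated bound fraction.
#' @export
estimate_pB_from_start <- function(trajs, E_B, E_U, window = 0.05) {
  trajs <- as_trajectory_list(trajs)
  if (!length(trajs)) stop("no trajectories supplied")
  thr <- (E_B + E_U) / 2
  starts <- vapply(trajs, function(tr) {
    sel <- tr$times <= tr$times[1] + window
    mean(tr$colors[sel]) > thr
  }, TRUE)
  mean(starts)
}

## ---- transient-complex lifetime scan --------------------------------------

#' Default lifetime grid for the likelihood-difference scan
#'
#' 50 log-spaced candidate lifetimes from 0.5 microseconds to 10 ms.
#' @param n Number of grid points.
#' @param lower,upper Grid bounds in seconds.
#' @return Numeric vector of lifetimes (s).
#' @export
default_t_grid <- function(n = 50, lower = 0.5e-6, upper = 10e-3) {
  exp(seq(log(lower), log(upper), length.out = n))
}

# instantaneous-transition reference: as t_TC -> 0 the transient-complex
# chain converges to the plain binding chain with HALVED reduced rates
# (each TC visit branches 1/2 to each neighbour), so the reference model
# uses k'/2; this makes delta lnL(0) = 0 hold identically.
reference_model <- function(base, blink, n, rate_reduction) {
  two_red <- two_state_params(base$E_B, base$E_U,
                              base$k_A_app / (2 * rate_reduction),
                              base$k_D / (2 * rate_reduction))
  if (is.null(blink)) make_two_state(two_red)
  else make_four_state(two_red, blink, n)
}

scan_model <- function(base, blink, n, t, E_TC, rate_reduction) {
  tc <- tc_params(t_TC = t, E_TC = E_TC, rate_reduction = rate_reduction)
  two <- two_state_params(base$E_B, base$E_U, base$k_A_app, base$k_D)
  if (is.null(blink)) make_three_state_tc(two, tc)
  else make_six_state_tc(two, tc, blink, n)
}

segment_count_rate <- function(seg) {
  w <- seg$window
  dur <- if (!is.null(w)) diff(w) else diff(range(seg$times))
  length(seg$times) / (dur * 1000)
}

#' Likelihood-difference scan over candidate transient-complex lifetimes
#'
#' For each candidate lifetime `t` builds the transient-complex model
#' (three-state, or six-state when blinking parameters are supplied) with
#' `k_TC = 1/(2t)` and reduced binding rates, sums the endpoint-vector
#' log-likelihoods over all single-transition segments, and subtracts the
#' instantaneous-transition reference `ln L(0)` so that
#' `delta lnL(t) -> 0` as `t -> 0`. A peak above +3 log-units (~95%
#' confidence) identifies a measurable lifetime; otherwise the crossing of
#' -3 gives an upper bound.
#'
#' @param segments List of transition segments (see [extract_segments()] or
#'   [simulate_transition_segments()]).
#' @param base A [two_state_params()] holding `E_B`, `E_U` and the unreduced
#'   apparent rates.
#' @param blink Optional [blink_params()]; switches to the six-state model.
#' @param t_grid Candidate lifetimes in seconds (sorted, positive).
#' @param E_TC_mode `"fixed-midpoint"` uses `E_TC = (E_B + E_U)/2`;
#'   `"free"` maximizes over `E_TC` at each grid point.
#' @param rate_reduction Factor dividing the binding rates (default 1000).
#' @return A `lifetime_scan` object with `t_grid`, `delta_lnL`, the excluded
#'   segment count, and a closure `delta_fn` for continuous refinement.
#' @seealso [find_lifetime_or_bound()]
#' @export
delta_lnL_scan <- function(segments, base, blink = NULL,
                           t_grid = default_t_grid(),
                           E_TC_mode = c("fixed-midpoint", "free"),
                           rate_reduction = 1000) {
  E_TC_mode <- match.arg(E_TC_mode)
  stopifnot(length(segments) >= 1, all(diff(t_grid) > 0), all(t_grid > 0))
  segs <- lapply(segments, function(s) {
    list(tau = diff(s$times), colors = s$colors,
         direction = if (!is.null(s$direction)) s$direction else "binding",
         n = segment_count_rate(s))
  })

  ref_ll <- vapply(segs, function(s) {
    m <- reference_model(base, blink, s$n, rate_reduction)
    pb <- if (is.null(blink)) 1 else {
      kd <- blink$k_0 * s$n / blink$n_0
      blink$k_b / (blink$k_b + kd)
    }
    e <- endpoint_vectors(m, s$direction, p_b = pb)
    .photon_loglik_cpp(s$tau, s$colors, m$K, m$E_diag, e$v_ini, e$v_fin)
  }, 0)
  keep <- is.finite(ref_ll)
  n_excluded <- sum(!keep)
  if (n_excluded)
    warning(n_excluded,
            " segment(s) with zero likelihood under the reference excluded")
  segs <- segs[keep]
  ref_total <- sum(ref_ll[keep])
  if (!length(segs)) stop("no usable segments")

  E_mid <- (base$E_B + base$E_U) / 2

  sum_ll <- function(t, E_TC) {
    tot <- 0
    for (s in segs) {
      m <- scan_model(base, blink, s$n, t, E_TC, rate_reduction)
      pb <- if (is.null(blink)) 1 else {
        kd <- blink$k_0 * s$n / blink$n_0
        blink$k_b / (blink$k_b + kd)
      }
      e <- endpoint_vectors(m, s$direction, p_b = pb)
      v <- .photon_loglik_cpp(s$tau, s$colors, m$K, m$E_diag, e$v_ini, e$v_fin)
      if (!is.finite(v)) return(-Inf)
      tot <- tot + v
    }
    tot
  }

  delta_fn <- if (E_TC_mode == "fixed-midpoint") {
    function(t) sum_ll(t, E_mid) - ref_total
  } else {
    function(t) {
      opt <- stats::optimize(function(E) sum_ll(t, E), c(0.01, 0.99),
                             maximum = TRUE, tol = 1e-3)
      opt$objective - ref_total
    }
  }

  delta <- vapply(t_grid, delta_fn, 0)
  structure(list(t_grid = t_grid, delta_lnL = delta, E_TC_mode = E_TC_mode,
                 n_segments = length(segs), n_excluded = n_excluded,
                 delta_fn = delta_fn, E_TC = E_mid),
            class = "lifetime_scan")
}

#' @export
print.lifetime_scan <- function(x, ...) {
  cat(sprintf(
    "lifetime_scan (%s E_TC): %d segments, %d grid points, peak delta lnL = %.2f at %.3g s\n",
    x$E_TC_mode, x$n_segments, length(x$t_grid), max(x$delta_lnL),
    x$t_grid[which.max(x$delta_lnL)]))
  invisible(x)
}

#' Extract the lifetime or its upper bound from a scan
#'
#' If the scan peak exceeds the +`conf` confidence level the lifetime is the
#' location of the maximum, refined by continuous local maximization, with a
#' standard error from the local curvature of `delta lnL`. Otherwise only an
#' upper bound is reported: the lifetime where `delta lnL` crosses -`conf`,
#' located by linear interpolation on `log t`. Both the larger-`t` and (when
#' present) smaller-`t` crossings are stored; the headline upper bound is the
#' larger-`t` crossing, appropriate for a peakless decreasing curve.
#'
#' @param scan A `lifetime_scan` from [delta_lnL_scan()].
#' @param conf Confidence level in log-units (default 3, ~95%).
#' @return A `lifetime_estimate` list: `type` (`"lifetime"`, `"upper_bound"`
#'   or `"unbounded"`), `t_hat`, `stderr`, `upper_bound`, `lower_crossing`,
#'   `peak_delta`.
#' @export
find_lifetime_or_bound <- function(scan, conf = 3) {
  stopifnot(inherits(scan, "lifetime_scan"))
  t <- scan$t_grid; d <- scan$delta_lnL
  i <- which.max(d)  # ties resolve to the smaller lifetime
  peak <- d[i]

  cross <- function(idx_from, idx_to) {
    # first -conf crossing walking from idx_from toward idx_to
    path <- if (idx_to >= idx_from) idx_from:idx_to else idx_from:idx_to
    for (k in seq_along(path)[-1]) {
      a <- path[k - 1]; b <- path[k]
      if (d[a] >= -conf && d[b] < -conf) {
        f <- (-conf - d[a]) / (d[b] - d[a])
        return(exp(log(t[a]) + f * (log(t[b]) - log(t[a]))))
      }
    }
    NA_real_
  }
  upper <- cross(i, length(t))
  lower <- cross(i, 1)

  if (peak > conf) {
    lo <- t[max(i - 1, 1)]; hi <- t[min(i + 1, length(t))]
    opt <- stats::optimize(scan$delta_fn, c(lo, hi), maximum = TRUE,
                           tol = min(lo) * 1e-3)
    t_hat <- opt$maximum
    h <- t_hat * 0.05
    d2 <- (scan$delta_fn(t_hat + h) - 2 * opt$objective +
             scan$delta_fn(t_hat - h)) / h^2
    se <- if (is.finite(d2) && d2 < 0) 1 / sqrt(-d2) else NA_real_
    out <- list(type = "lifetime", t_hat = t_hat, stderr = se,
                upper_bound = upper, lower_crossing = lower,
                peak_delta = opt$objective)
  } else if (!is.na(upper)) {
    out <- list(type = "upper_bound", t_hat = NA_real_, stderr = NA_real_,
                upper_bound = upper, lower_crossing = lower,
                peak_delta = peak)
  } else {
    out <- list(type = "unbounded", t_hat = NA_real_, stderr = NA_real_,
                upper_bound = NA_real_, lower_crossing = lower,
                peak_delta = peak,
                note = "delta lnL never crosses the lower confidence level; widen t_grid")
  }
  structure(out, class = "lifetime_estimate")
}

#' @export
print.lifetime_estimate <- function(x, ...) {
  if (x$type == "lifetime")
    cat(sprintf("t_TC = %.3g s (stderr %.2g s), peak delta lnL = %.2f\n",
                x$t_hat, x$stderr, x$peak_delta))
  else if (x$type == "upper_bound")
    cat(sprintf("no significant peak: upper bound t_TC <= %.3g s\n",
                x$upper_bound))
  else
    cat("unbounded on grid:", x$note, "\n")
  invisible(x)
}

#' Fit blinking and efficiency parameters at the instantaneous limit
#'
#' Maximizes the instantaneous-transition likelihood (the four-state
#' blinking model with halved reduced binding rates, the `t_TC -> 0` limit of
#' the six-state model) over `(E_B, E_U, k_b, p_b)`. These are then held
#' fixed in the fixed-`E_TC` lifetime scan.
#'
#' @param segments List of single-transition segments.
#' @param base A [two_state_params()] with the unreduced apparent rates.
#' @param init Optional named starting values (`E_B, E_U, k_b, p_b`).
#' @param E_d Dark-state efficiency (fixed, default 0.06).
#' @param rate_reduction Binding-rate reduction factor (default 1000).
#' @param n_starts Optimizer starts.
#' @return An `ml_fit` over `(E_B, E_U, k_b, p_b)`.
#' @export
fit_blink_at_instantaneous <- function(segments, base, init = NULL,
                                       E_d = 0.06, rate_reduction = 1000,
                                       n_starts = NULL) {
  segs <- lapply(segments, function(s) {
    list(tau = diff(s$times), colors = s$colors,
         direction = if (!is.null(s$direction)) s$direction else "binding")
  })
  if (is.null(n_starts)) n_starts <- if (is.null(init)) 5 else 1
  init <- init_defaults(init, c(E_B = 0.6, E_U = 0.25, k_b = 3000, p_b = 0.85))
  eff <- c("E_B", "E_U", "p_b")
  kAh <- base$k_A_app / (2 * rate_reduction)
  kDh <- base$k_D / (2 * rate_reduction)
  start <- unlist(init[c("E_B", "E_U", "k_b", "p_b")])

  negll <- function(theta) {
    p <- from_trans(theta, eff)
    kb <- p[["k_b"]]; pb <- p[["p_b"]]
    kd <- kb * (1 - pb) / pb
    E <- c(p[["E_B"]], p[["E_U"]], E_d, E_d)
    K <- matrix(c(
      -kDh - kd, kDh,        kd,        0,
      kAh,       -kAh - kd,  0,         kd,
      kb,        0,          -kDh - kb, kDh,
      0,         kb,         kAh,       -kAh - kb
    ), 4, 4)
    ll <- 0
    for (s in segs) {
      e <- if (s$direction == "binding")
        list(v_ini = c(0, pb, 0, 1 - pb), v_fin = c(1, 0, 1, 0))
      else
        list(v_ini = c(pb, 0, 1 - pb, 0), v_fin = c(0, 1, 0, 1))
      v <- .photon_loglik_cpp(s$tau, s$colors, K, E, e$v_ini, e$v_fin)
      if (!is.finite(v)) return(1e10)
      ll <- ll + v
    }
    -ll
  }
  res <- ml_maximize(negll, start, eff, n_starts)
  new_ml_fit(res, fixed = list(E_d = E_d),
             model_type = "instantaneous-limit blinking")
}

#' Joint maximization over efficiencies, blinking and the lifetime
#'
#' Simultaneously maximizes the summed endpoint likelihood of the six-state
#' transient-complex model over `(E_B, E_U, k_b, p_b, E_TC, t_TC)`. With
#' `blink = FALSE` (segments without acceptor-dark excursions) the
#' three-state model is used and only `(E_B, E_U, E_TC, t_TC)` are fitted;
#' with no dark photons the blinking block of the Hessian is singular, so
#' fitting it would be ill-posed.
#'
#' @param segments List of single-transition segments.
#' @param base A [two_state_params()] with the unreduced apparent rates.
#' @param init Optional named starting values.
#' @param blink Logical: include the acceptor-dark manifold?
#' @param E_d Dark-state efficiency (fixed, default 0.06).
#' @param rate_reduction Binding-rate reduction factor (default 1000).
#' @param n_starts Optimizer starts.
#' @return An `ml_fit`; `params["t_TC"]` is the fitted lifetime in seconds.
#' @export
fit_joint_six <- function(segments, base, init = NULL, blink = TRUE,
                          E_d = 0.06, rate_reduction = 1000, n_starts = NULL) {
  segs <- lapply(segments, function(s) {
    list(tau = diff(s$times), colors = s$colors,
         direction = if (!is.null(s$direction)) s$direction else "binding")
  })
  if (is.null(n_starts)) n_starts <- if (is.null(init)) 5 else 1
  defaults <- c(E_B = 0.6, E_U = 0.25, k_b = 3000, p_b = 0.85,
                E_TC = 0.4, t_TC = 2e-4)
  init <- init_defaults(init, defaults)
  eff <- c("E_B", "E_U", "p_b", "E_TC")
  free <- if (blink) c("E_B", "E_U", "k_b", "p_b", "E_TC", "t_TC")
          else c("E_B", "E_U", "E_TC", "t_TC")
  start <- unlist(init[free])

  negll <- function(theta) {
    p <- from_trans(theta, eff)
    twoi <- tryCatch(
      two_state_params(p[["E_B"]], p[["E_U"]], base$k_A_app, base$k_D),
      error = function(e) NULL)
    if (is.null(twoi)) return(1e10)
    tc <- tc_params(t_TC = p[["t_TC"]], E_TC = p[["E_TC"]],
                    rate_reduction = rate_reduction)
    if (blink) {
      kb <- p[["k_b"]]; pb <- p[["p_b"]]
      kd <- kb * (1 - pb) / pb
      bl <- blink_params(k_b = kb, k_0 = kd, E_d = E_d)  # n = n_0 => k_d = k_0
      m <- make_six_state_tc(twoi, tc, bl, n = 100)
    } else {
      pb <- 1
      m <- make_three_state_tc(twoi, tc)
    }
    ll <- 0
    for (s in segs) {
      e <- endpoint_vectors(m, s$direction, p_b = pb)
      v <- .photon_loglik_cpp(s$tau, s$colors, m$K, m$E_diag, e$v_ini, e$v_fin)
      if (!is.finite(v)) return(1e10)
      ll <- ll + v
    }
    -ll
  }
  res <- ml_maximize(negll, start, eff, n_starts)
  new_ml_fit(res, fixed = list(E_d = if (blink) E_d else NA),
             model_type = if (blink) "joint six-state" else "joint three-state")
}
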