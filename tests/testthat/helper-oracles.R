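# Independent oracles and small generators shared across the test files.
#
# The brute-force likelihood multiplies the per-interval propagators
# explicitly using Matrix::expm (scaling-and-squaring), entirely independent
# of the package's eigendecomposition/renormalization path. The Viterbi
# oracle enumerates every state sequence. Both are only usable on tiny
# trajectories, which is the point.

brute_loglik <- function(times, colors, K, E, v_ini, v_fin) {
  Fm <- function(c) if (c == 1) diag(E, nrow = length(E))
                    else diag(1 - E, nrow = length(E))
  v <- Fm(colors[1]) %*% v_ini
  if (length(times) > 1) {
    for (i in 2:length(times)) {
      P <- as.matrix(Matrix::expm(K * (times[i] - times[i - 1])))
      v <- Fm(colors[i]) %*% (P %*% v)
    }
  }
  log(sum(v_fin * v))
}

enum_viterbi <- function(times, colors, K, E, p_eq) {
  n <- length(p_eq)
  N <- length(times)
  Ps <- if (N > 1) lapply(2:N, function(i)
    as.matrix(Matrix::expm(K * (times[i] - times[i - 1])))) else list()
  emis <- function(s, c) if (c == 1) E[s] else 1 - E[s]
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), N)))
  best <- -Inf; best_path <- NULL
  for (r in seq_len(nrow(grid))) {
    path <- grid[r, ]
    lp <- log(p_eq[path[1]]) + log(emis(path[1], colors[1]))
    if (N > 1) for (i in 2:N)
      lp <- lp + log(Ps[[i - 1]][path[i], path[i - 1]]) +
        log(emis(path[i], colors[i]))
    if (lp > best + 1e-12) { best <- lp; best_path <- path }
  }
  best_path
}

rand_two <- function() {
  two_state_params(E_B = runif(1, 0.4, 0.9), E_U = runif(1, 0.05, 0.35),
                   k_A_app = exp(runif(1, log(20), log(2000))),
                   k_D = exp(runif(1, log(20), log(2000))))
}

rand_blink <- function() {
  blink_params(k_b = exp(runif(1, log(500), log(8000))),
               k_0 = exp(runif(1, log(100), log(1500))),
               E_d = runif(1, 0.02, 0.12))
}

rand_tc <- function() {
  tc_params(t_TC = exp(runif(1, log(5e-6), log(2e-3))),
            E_TC = runif(1, 0.2, 0.6))
}

rand_model <- function(kind) {
  switch(kind,
    two = make_two_state(rand_two()),
    three = make_three_state_tc(rand_two(), rand_tc()),
    four = make_four_state(rand_two(), rand_blink(), n = runif(1, 50, 600)),
    six = make_six_state_tc(rand_two(), rand_tc(), rand_blink(),
                            n = runif(1, 50, 600)))
}

rand_traj <- function(n_photons, mean_gap = 1e-3) {
  photon_trajectory(cumsum(rexp(n_photons, 1 / mean_gap)),
                    rbinom(n_photons, 1, 0.5))
}

# photon trajectory from an explicit state path (known ground truth)
traj_from_path <- function(switch_times, states, duration, rate_ms, E_diag) {
  times <- sort(runif(rpois(1, rate_ms * 1000 * duration), 0, duration))
  times <- times[!duplicated(times)]
  s <- states[findInterval(times, switch_times) + 1L]
  colors <- as.integer(runif(length(times)) < E_diag[s])
  list(traj = photon_trajectory(times, colors), states = s)
}
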