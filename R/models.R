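#' Two-state binding parameters
#'
#' The minimal kinetic description of reversible binding observed by FRET:
#' a bound state B with apparent efficiency `E_B` and an unbound state U with
#' apparent efficiency `E_U`, exchanging with apparent (pseudo-first-order)
#' association rate `k_A_app` and dissociation rate `k_D`.
#'
#' Efficiencies are apparent (uncorrected) acceptor fractions, so `E_U` may
#' legitimately sit near the donor-leak level (~0.06) for a donor-only
#' unbound state; no ordering of `E_B` and `E_U` is enforced.
#'
#' @param E_B,E_U Apparent FRET efficiencies in `[0, 1]`.
#' @param k_A_app,k_D Strictly positive rates in s^-1.
#' @return An object of class `two_state_params`.
#' @examples
#' two_state_params(E_B = 0.6, E_U = 0.25, k_A_app = 300, k_D = 100)
#' @export
two_state_params <- function(E_B, E_U, k_A_app, k_D) {
  check_efficiency(E_B, "E_B"); check_efficiency(E_U, "E_U")
  check_rate(k_A_app, "k_A_app"); check_rate(k_D, "k_D")
  structure(list(E_B = E_B, E_U = E_U, k_A_app = k_A_app, k_D = k_D),
            class = "two_state_params")
}

#' Acceptor blinking parameters
#'
#' Microsecond-scale acceptor dark-state kinetics. The dark-state entry rate
#' scales linearly with illumination: `k_d = k_0 * (n / n_0)` where `n` is
#' the per-trajectory mean count rate and `n_0 = 100` photons/ms is the fixed
#' reference. The recovery rate `k_b` is intensity-independent. In the dark
#' state both bound and unbound molecules emit at the donor-leak level `E_d`.
#'
#' @param E_d Apparent efficiency of the acceptor dark state (default 0.06,
#'   the donor-leak fraction).
#' @param k_b Dark-to-bright recovery rate (s^-1).
#' @param k_0 Bright-to-dark rate at the reference count rate (s^-1).
#' @return An object of class `blink_params` (with constant `n_0 = 100` ms^-1).
#' @export
blink_params <- function(k_b, k_0, E_d = 0.06) {
  check_efficiency(E_d, "E_d")
  check_rate(k_b, "k_b"); check_rate(k_0, "k_0")
  structure(list(E_d = E_d, k_b = k_b, k_0 = k_0, n_0 = 100),
            class = "blink_params")
}

#' Transient-complex parameters
#'
#' The short-lived intermediate (transient/encounter complex, TC) between the
#' unbound and bound states. Both exit rates from TC are equal to `k_TC`, so
#' the TC lifetime is `t_TC = 1/(2 k_TC)`. In the lifetime analysis the
#' binding/unbinding rates are divided by `rate_reduction` (default 1000) to
#' suppress unresolvable multiple transitions inside a segment.
#'
#' @param k_TC TC exit rate to each neighbouring state (s^-1); alternatively
#'   supply `t_TC` in seconds.
#' @param E_TC Apparent FRET efficiency of the TC.
#' @param rate_reduction Factor (>= 1) applied to `k_D` and `k_A_app`.
#' @param t_TC Optional lifetime in seconds; mapped to `k_TC = 1/(2 t_TC)`.
#' @return An object of class `tc_params`.
#' @examples
#' tc_params(t_TC = 200e-6, E_TC = 0.425)
#' @export
tc_params <- function(k_TC = NULL, E_TC, rate_reduction = 1000, t_TC = NULL) {
  if (is.null(k_TC)) {
    if (is.null(t_TC)) stop("supply k_TC or t_TC")
    check_rate(t_TC, "t_TC")
    k_TC <- 1 / (2 * t_TC)
  }
  check_rate(k_TC, "k_TC")
  check_efficiency(E_TC, "E_TC")
  if (!is.numeric(rate_reduction) || rate_reduction < 1)
    stop("rate_reduction must be >= 1")
  structure(list(k_TC = k_TC, E_TC = E_TC, rate_reduction = rate_reduction),
            class = "tc_params")
}

#' Transient-complex lifetime from the exit rate
#'
#' With equal exit rates `k_TC` to both neighbours the mean residence time in
#' the TC is `t_TC = 1/(2 k_TC)`.
#' @param k_TC Exit rate to each neighbour (s^-1).
#' @return Lifetime in seconds.
#' @export
tc_lifetime <- function(k_TC) {
  check_rate(k_TC, "k_TC")
  1 / (2 * k_TC)
}

#' Kinetic scheme of association through the transient complex
#'
#' Association proceeds U + partner -> TC (rate coefficient `k_plus`,
#' M^-1 s^-1), from which the disordered chain either folds into the bound
#' complex (rate `k_f`) or dissociates (rate `k_minus`).
#'
#' @param k_plus TC formation rate coefficient (M^-1 s^-1).
#' @param k_minus TC dissociation rate (s^-1).
#' @param k_f Folding rate within the TC (s^-1).
#' @return An object of class `scheme_params`.
#' @export
scheme_params <- function(k_plus, k_minus, k_f) {
  check_rate(k_plus, "k_plus"); check_rate(k_minus, "k_minus")
  check_rate(k_f, "k_f")
  structure(list(k_plus = k_plus, k_minus = k_minus, k_f = k_f),
            class = "scheme_params")
}

check_rate <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
    stop(name, " must be a single strictly positive finite number")
  invisible(x)
}

check_efficiency <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0 || x > 1)
    stop(name, " must be a single number in [0, 1]")
  invisible(x)
}

#' Construct a kinetic model
#'
#' Bundles a rate matrix `K` (columns sum to zero; column j holds the rates
#' out of state j), the diagonal of the apparent-FRET-efficiency matrix, and
#' the equilibrium population vector. Validates stationarity `K p_eq = 0`.
#'
#' @param state_labels Character vector of state names.
#' @param K n x n rate matrix in s^-1.
#' @param E_diag Length-n vector of apparent FRET efficiencies.
#' @param p_eq Optional equilibrium vector; computed as the normalized null
#'   vector of `K` when omitted.
#' @return An object of class `kinetic_model`.
#' @export
kinetic_model <- function(state_labels, K, E_diag, p_eq = NULL) {
  K <- as.matrix(K)
  n <- nrow(K)
  if (ncol(K) != n) stop("K must be square")
  if (length(state_labels) != n || length(E_diag) != n)
    stop("state_labels and E_diag must match dim(K)")
  if (any(E_diag < 0 | E_diag > 1)) stop("E_diag entries must lie in [0, 1]")
  off <- K; diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal entries of K must be >= 0")
  scale <- max(abs(K), 1e-300)
  if (n > 1 && max(abs(colSums(K))) > 1e-12 * scale)
    stop("columns of K must sum to zero")
  if (is.null(p_eq)) p_eq <- stationary_distribution(K)
  if (any(p_eq < -1e-12) || abs(sum(p_eq) - 1) > 1e-8)
    stop("p_eq must be a probability vector")
  p_eq <- pmax(p_eq, 0); p_eq <- p_eq / sum(p_eq)
  if (n > 1 && max(abs(K %*% p_eq)) > 1e-10 * scale)
    stop("p_eq is not stationary for K")
  structure(list(state_labels = as.character(state_labels), K = K,
                 E_diag = as.numeric(E_diag), p_eq = as.numeric(p_eq)),
            class = "kinetic_model")
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat(sprintf("kinetic_model with %d states: %s\n", length(x$state_labels),
              paste(x$state_labels, collapse = ", ")))
  cat("E_diag:", signif(x$E_diag, 3), "\n")
  cat("p_eq:  ", signif(x$p_eq, 3), "\n")
  invisible(x)
}

#' Stationary distribution of a rate matrix
#'
#' Solves `K p = 0`, `sum(p) = 1` by replacing one balance equation with the
#' normalization constraint.
#' @param K Rate matrix with zero column sums.
#' @return Stationary probability vector.
#' @export
stationary_distribution <- function(K) {
  n <- nrow(K)
  if (n == 1) return(1)
  A <- rbind(K[-n, , drop = FALSE], rep(1, n))
  p <- solve(A, c(rep(0, n - 1), 1))
  p <- pmax(p, 0)
  p / sum(p)
}

#' Two-state binding model
#'
#' States (B, U). The bound fraction is
#' `p_B = k_A_app / (k_A_app + k_D)`.
#'
#' @param params A [two_state_params()].
#' @return A [kinetic_model()].
#' @examples
#' m <- make_two_state(two_state_params(0.6, 0.25, 300, 100))
#' m$p_eq  # (0.75, 0.25)
#' @export
make_two_state <- function(params) {
  stopifnot(inherits(params, "two_state_params"))
  p <- params
  K <- matrix(c(-p$k_D, p$k_D, p$k_A_app, -p$k_A_app), 2, 2)
  pB <- p$k_A_app / (p$k_A_app + p$k_D)
  kinetic_model(c("B", "U"), K, c(p$E_B, p$E_U), c(pB, 1 - pB))
}

#' Four-state binding model with acceptor blinking
#'
#' States (B, U, Bdark, Udark). The blinking chain is independent of the
#' binding chain: the dark-state entry rate is `k_d = k_0 * (n / n_0)` and
#' the equilibrium is the outer product of the binding equilibrium
#' `(p_B, 1 - p_B)` with the bright-state equilibrium
#' `p_b = k_b / (k_b + k_d)`. Dark states emit at `E_d`.
#'
#' @param two A [two_state_params()].
#' @param blink A [blink_params()].
#' @param n Mean photon count rate of the trajectory in photons/ms.
#' @return A [kinetic_model()].
#' @export
make_four_state <- function(two, blink, n) {
  stopifnot(inherits(two, "two_state_params"), inherits(blink, "blink_params"))
  check_rate(n, "n")
  k_d <- blink$k_0 * (n / blink$n_0)
  kA <- two$k_A_app; kD <- two$k_D; kb <- blink$k_b
  K <- matrix(c(
    -kD - k_d, kD,        k_d,      0,
    kA,        -kA - k_d, 0,        k_d,
    kb,        0,         -kD - kb, kD,
    0,         kb,        kA,       -kA - kb
  ), 4, 4)
  pB <- kA / (kA + kD)
  pb <- kb / (kb + k_d)
  p_eq <- c(pB * pb, (1 - pB) * pb, pB * (1 - pb), (1 - pB) * (1 - pb))
  kinetic_model(c("B", "U", "Bdark", "Udark"), K,
                c(two$E_B, two$E_U, blink$E_d, blink$E_d), p_eq)
}

#' Three-state model with a transient complex
#'
#' States (B, TC, U). The TC exits to both neighbours at equal rate `k_TC`
#' (lifetime `t_TC = 1/(2 k_TC)`); the binding/unbinding rates are reduced by
#' `rate_reduction` to `k'_D = k_D / rate_reduction` and
#' `k'_A_app = k_A_app / rate_reduction` so that a segment effectively
#' contains a single resolvable transition.
#'
#' @param two A [two_state_params()].
#' @param tc A [tc_params()].
#' @return A [kinetic_model()].
#' @export
make_three_state_tc <- function(two, tc) {
  stopifnot(inherits(two, "two_state_params"), inherits(tc, "tc_params"))
  kDp <- two$k_D / tc$rate_reduction
  kAp <- two$k_A_app / tc$rate_reduction
  kTC <- tc$k_TC
  K <- matrix(c(
    -kDp, kDp,            0,
    kTC,  -2 * kTC,       kTC,
    0,    kAp,            -kAp
  ), 3, 3)
  kinetic_model(c("B", "TC", "U"), K, c(two$E_B, tc$E_TC, two$E_U))
}

#' Six-state transient-complex model with acceptor blinking
#'
#' States (B, TC, U, Bdark, TCdark, Udark): the three-state
#' transient-complex chain replicated in the acceptor bright and dark
#' manifolds, coupled by the blinking rates `k_d` (bright to dark, count-rate
#' dependent) and `k_b` (dark to bright). Kinetic rates in the dark block
#' equal those in the bright block; dark states emit at `E_d`.
#'
#' @param two A [two_state_params()].
#' @param tc A [tc_params()].
#' @param blink A [blink_params()].
#' @param n Mean photon count rate in photons/ms.
#' @return A [kinetic_model()].
#' @export
make_six_state_tc <- function(two, tc, blink, n) {
  stopifnot(inherits(two, "two_state_params"), inherits(tc, "tc_params"),
            inherits(blink, "blink_params"))
  check_rate(n, "n")
  k_d <- blink$k_0 * (n / blink$n_0)
  kb <- blink$k_b
  kDp <- two$k_D / tc$rate_reduction
  kAp <- two$k_A_app / tc$rate_reduction
  kTC <- tc$k_TC
  block <- function(extra) matrix(c(
    -kDp - extra, kDp,                 0,
    kTC,          -2 * kTC - extra,    kTC,
    0,            kAp,                 -kAp - extra
  ), 3, 3)
  K <- rbind(cbind(block(k_d), kb * diag(3)),
             cbind(k_d * diag(3), block(kb)))
  E <- c(two$E_B, tc$E_TC, two$E_U, rep(blink$E_d, 3))
  kinetic_model(c("B", "TC", "U", "Bdark", "TCdark", "Udark"), K, E)
}

#' Bimolecular association rate coefficient
#'
#' Binding is pseudo-first order (labeled molecule concentration much below
#' the partner concentration), so the bimolecular coefficient is the apparent
#' association rate divided by the partner concentration.
#'
#' @param k_A_app Apparent association rate (s^-1).
#' @param partner_conc Binding-partner concentration (M), strictly positive.
#' @return Association rate coefficient in M^-1 s^-1.
#' @examples
#' association_rate_coefficient(3.8, 1e-9)  # 3.8e9 M^-1 s^-1
#' @export
association_rate_coefficient <- function(k_A_app, partner_conc) {
  if (!is.numeric(partner_conc) || partner_conc <= 0)
    stop("partner_conc must be strictly positive")
  if (!is.numeric(k_A_app) || k_A_app < 0) stop("k_A_app must be >= 0")
  k_A_app / partner_conc
}

#' Overall association rate coefficient of the two-step scheme
#'
#' For association through a transient complex with formation coefficient
#' `k_plus`, back-dissociation `k_minus`, and folding `k_f`, the overall
#' coefficient is `k_A = k_plus * k_f / (k_f + k_minus)`; it approaches the
#' diffusion-limited `k_plus` when folding outruns dissociation.
#'
#' @param scheme A [scheme_params()].
#' @return Overall association rate coefficient (M^-1 s^-1).
#' @export
effective_kA <- function(scheme) {
  stopifnot(inherits(scheme, "scheme_params"))
  scheme$k_plus * scheme$k_f / (scheme$k_f + scheme$k_minus)
}

#' Serialize model parameters to a flat key-value JSON config
#'
#' Writes the union of supplied parameter sets with the canonical key names
#' `E_B, E_U, k_A_app, k_D, E_d, k_b, k_0, E_TC, k_TC, rate_reduction`.
#'
#' @param path Output path; `NULL` returns the JSON string.
#' @param two,blink,tc Optional parameter objects.
#' @return The JSON string, invisibly if written to `path`.
#' @seealso [params_from_config()]
#' @export
params_to_config <- function(path = NULL, two = NULL, blink = NULL, tc = NULL) {
  kv <- list()
  if (!is.null(two)) kv[c("E_B", "E_U", "k_A_app", "k_D")] <-
      two[c("E_B", "E_U", "k_A_app", "k_D")]
  if (!is.null(blink)) kv[c("E_d", "k_b", "k_0")] <- blink[c("E_d", "k_b", "k_0")]
  if (!is.null(tc)) kv[c("E_TC", "k_TC", "rate_reduction")] <-
      tc[c("E_TC", "k_TC", "rate_reduction")]
  js <- jsonlite::toJSON(kv, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(as.character(js))
}

#' Read model parameters from a flat key-value JSON config
#'
#' @param path Path to a JSON file, or a JSON string.
#' @return A list with any of `two` ([two_state_params()]),
#'   `blink` ([blink_params()]) and `tc` ([tc_params()]) that the config
#'   defines.
#' @export
params_from_config <- function(path) {
  kv <- jsonlite::fromJSON(path)
  out <- list()
  if (all(c("E_B", "E_U", "k_A_app", "k_D") %in% names(kv)))
    out$two <- two_state_params(kv$E_B, kv$E_U, kv$k_A_app, kv$k_D)
  if (all(c("k_b", "k_0") %in% names(kv)))
    out$blink <- blink_params(kv$k_b, kv$k_0,
                              E_d = if (!is.null(kv$E_d)) kv$E_d else 0.06)
  if (all(c("E_TC", "k_TC") %in% names(kv)))
    out$tc <- tc_params(k_TC = kv$k_TC, E_TC = kv$E_TC,
                        rate_reduction = if (!is.null(kv$rate_reduction))
                          kv$rate_reduction else 1000)
  out
}
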