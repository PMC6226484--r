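#' Bin a photon trajectory
#'
#' Counts donor and acceptor photons in left-closed right-open bins from the
#' trajectory start and computes the per-bin apparent FRET efficiency
#' `E = N_A / (N_A + N_D)` (NA for empty bins). Binning partitions the
#' photons exactly.
#'
#' @param traj A [photon_trajectory()].
#' @param bin_time Bin width in seconds (e.g. 1e-3 for the standard 1 ms
#'   display binning).
#' @return A `binned_trajectory` data frame with columns `t` (bin start),
#'   `N_D`, `N_A`, `E`.
#' @export
bin_trajectory <- function(traj, bin_time) {
  stopifnot(bin_time > 0)
  tc <- photon_records(traj)
  if (!length(tc$times))
    return(structure(data.frame(t = numeric(), N_D = integer(),
                                N_A = integer(), E = numeric()),
                     class = c("binned_trajectory", "data.frame"),
                     bin_time = bin_time))
  rel <- tc$times - tc$times[1]
  idx <- pmin(floor(rel / bin_time), floor(max(rel) / bin_time))
  nb <- max(idx) + 1
  N_A <- tabulate(idx[tc$colors == 1L] + 1L, nbins = nb)
  N_D <- tabulate(idx[tc$colors == 0L] + 1L, nbins = nb)
  tot <- N_A + N_D
  structure(data.frame(t = tc$times[1] + (seq_len(nb) - 1) * bin_time,
                       N_D = N_D, N_A = N_A,
                       E = ifelse(tot > 0, N_A / tot, NA_real_)),
            class = c("binned_trajectory", "data.frame"),
            bin_time = bin_time)
}

#' FRET efficiency histogram over binned trajectories
#'
#' Pools the per-bin apparent efficiencies of a trajectory set (empty bins
#' excluded, optionally also bins with too few photons) into a histogram on
#' `[0, 1]`.
#'
#' @param trajs A [photon_trajectory()] or list of them.
#' @param bin_time Photon-binning time in seconds.
#' @param n_bins Number of histogram bins over `[0, 1]`.
#' @param min_counts Minimum photons per bin for inclusion (default 1).
#' @return A data frame with `E_mid` (bin centres) and `count`.
#' @export
fret_histogram <- function(trajs, bin_time, n_bins = 40, min_counts = 1) {
  trajs <- as_trajectory_list(trajs)
  Es <- unlist(lapply(trajs, function(tr) {
    b <- bin_trajectory(tr, bin_time)
    b$E[!is.na(b$E) & (b$N_A + b$N_D) >= min_counts]
  }))
  breaks <- seq(0, 1, length.out = n_bins + 1)
  h <- hist(pmin(pmax(Es, 0), 1), breaks = breaks, plot = FALSE)
  data.frame(E_mid = h$mids, count = h$counts)
}

#' Donor-acceptor cross-correlation of binned photon counts
#'
#' For each qualifying trajectory segment computes
#' `C_DA(tau) = <N_D(t + tau) N_A(t)> / (<N_D><N_A>) - 1` at lags that are
#' integer multiples of the bin time, then averages across segments. The
#' relaxation rate of the resulting anticorrelated decay equals the sum of
#' the apparent association and dissociation rates for two-state exchange.
#'
#' @param trajs A [photon_trajectory()] or list of them; each trajectory is
#'   one averaging segment.
#' @param bin_time Bin width in seconds.
#' @param max_lag Largest lag in seconds.
#' @param segment_min Minimum segment length in seconds (default 20 ms);
#'   shorter trajectories are skipped.
#' @return A `correlation_curve` data frame with `lag_s` and `C_DA`, and
#'   attributes recording the settings.
#' @export
cross_correlation <- function(trajs, bin_time, max_lag, segment_min = 20e-3) {
  trajs <- as_trajectory_list(trajs)
  n_lags <- max(1, floor(max_lag / bin_time))
  per_seg <- list()
  for (tr in trajs) {
    if (trajectory_duration(tr) < segment_min) next
    b <- bin_trajectory(tr, bin_time)
    if (nrow(b) <= n_lags + 1) next
    mD <- mean(b$N_D); mA <- mean(b$N_A)
    if (mD == 0 || mA == 0) next
    cc <- vapply(seq_len(n_lags), function(l) {
      m <- nrow(b) - l
      mean(b$N_D[(1 + l):(m + l)] * b$N_A[1:m]) / (mD * mA) - 1
    }, 0)
    per_seg[[length(per_seg) + 1]] <- cc
  }
  if (!length(per_seg))
    stop("no segments longer than segment_min = ", segment_min, " s")
  per_seg <- do.call(cbind, per_seg)
  C <- rowMeans(per_seg)
  structure(data.frame(lag_s = seq_len(n_lags) * bin_time, C_DA = C),
            class = c("correlation_curve", "data.frame"),
            bin_time = bin_time, segment_min = segment_min,
            n_segments = ncol(per_seg), per_segment = per_seg)
}

#' Fit a single-exponential relaxation to a correlation curve
#'
#' Least-squares fit of `A * exp(-lambda * tau) + c`; for two-state binding
#' the fitted `lambda` estimates `k_A_app + k_D` and the amplitude `A` is
#' negative (donor and acceptor counts are anticorrelated).
#'
#' When the curve carries its per-segment components (as curves from
#' [cross_correlation()] do), `rate_stderr` is a leave-one-segment-out
#' jackknife standard error, which accounts for the correlation of
#' residuals across lags that the parametric `nls` error ignores; otherwise
#' the `nls` standard error is reported.
#'
#' @param curve A `correlation_curve` from [cross_correlation()] (>= 5 lag
#'   points).
#' @return A list with `rate`, `rate_stderr`, `amplitude`, `baseline`,
#'   `converged`, and the `nls` fit object.
#' @export
fit_relaxation <- function(curve) {
  stopifnot(nrow(curve) >= 5)
  tau <- curve$lag_s; C <- curve$C_DA
  A0 <- C[1] - C[length(C)]
  lam0 <- 1 / (tau[max(2, floor(length(tau) / 3))])
  fit <- tryCatch(
    stats::nls(C ~ A * exp(-lam * tau) + c0,
               start = list(A = A0, lam = lam0, c0 = C[length(C)]),
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(rate = NA_real_, rate_stderr = NA_real_,
                amplitude = NA_real_, baseline = NA_real_,
                converged = FALSE, fit = NULL))
  co <- summary(fit)$coefficients
  rate <- co["lam", "Estimate"]
  se <- co["lam", "Std. Error"]
  per_seg <- attr(curve, "per_segment")
  if (!is.null(per_seg) && ncol(per_seg) >= 5) {
    start <- as.list(stats::coef(fit))
    m <- ncol(per_seg)
    rates <- rep(NA_real_, m)
    for (j in seq_len(m)) {
      Cj <- rowMeans(per_seg[, -j, drop = FALSE])
      fj <- tryCatch(
        stats::nls(Cj ~ A * exp(-lam * tau) + c0, start = start,
                   control = stats::nls.control(maxiter = 50,
                                                warnOnly = TRUE)),
        error = function(e) NULL)
      if (!is.null(fj)) rates[j] <- stats::coef(fj)[["lam"]]
    }
    rates <- rates[is.finite(rates)]
    if (length(rates) >= 5) {
      n <- length(rates)
      se <- sqrt((n - 1) / n * sum((rates - mean(rates))^2))
    }
  }
  list(rate = rate, rate_stderr = se,
       amplitude = co["A", "Estimate"], baseline = co["c0", "Estimate"],
       converged = fit$convInfo$isConv, fit = fit)
}
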