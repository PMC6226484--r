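#' Pipeline run configuration
#'
#' One object describing an end-to-end run: where the photons come from
#' (files or a simulation spec), which models to fit, and every threshold.
#'
#' @param input Either a character vector of PHOT-TSV paths or a
#'   [sim_config()].
#' @param fit_model `"two-state"` or `"four-state"` for the kinetic fit.
#' @param scan Logical: run the transient-complex lifetime scan?
#' @param scan_blink Logical: six-state (blinking) scan instead of
#'   three-state?
#' @param E_TC_mode `"fixed-midpoint"` or `"free"` for the scan.
#' @param barnase_mode Logical: donor-only unbound state; applies
#'   first-binding-event filtering and the fixed-`p_B` photobleach
#'   correction automatically.
#' @param min_residence Transition residence filter in seconds.
#' @param window_total,min_window,max_window Segment window bounds (s).
#' @param t_grid Lifetime grid for the scan (s).
#' @param conf Confidence level in log-units (default 3).
#' @param concentration_M Optional binding-partner concentration for the
#'   bimolecular rate coefficient.
#' @param init Optional named starting values forwarded to the fits.
#' @param out_dir Optional output directory for result tables.
#' @param seed Integer seed controlling every random draw of the run.
#' @return A `run_config` object.
#' @export
run_config <- function(input, fit_model = c("two-state", "four-state"),
                       scan = TRUE, scan_blink = FALSE,
                       E_TC_mode = "fixed-midpoint", barnase_mode = FALSE,
                       min_residence = 200e-6, window_total = 2e-3,
                       min_window = 400e-6, max_window = 3e-3,
                       t_grid = default_t_grid(), conf = 3,
                       concentration_M = NULL, init = NULL, out_dir = NULL,
                       seed = 1L) {
  fit_model <- match.arg(fit_model)
  stopifnot(min_residence > 0, window_total > 0, min_window > 0,
            max_window > 0, conf > 0, all(t_grid > 0))
  structure(list(input = input, fit_model = fit_model, scan = scan,
                 scan_blink = scan_blink, E_TC_mode = E_TC_mode,
                 barnase_mode = barnase_mode, min_residence = min_residence,
                 window_total = window_total, min_window = min_window,
                 max_window = max_window, t_grid = t_grid, conf = conf,
                 concentration_M = concentration_M, init = init,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(cfg) {
  # stable fingerprint of the configuration (no external digest dependency)
  s <- paste(utils::capture.output(utils::str(cfg, digits.d = 12)),
             collapse = "\n")
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 1e9
}

#' Run the full analysis pipeline
#'
#' simulate/load -> Viterbi segmentation -> transition filtering -> kinetic
#' fit -> lifetime scan -> results table. Deterministic given the seed. In
#' barnase mode the bound fraction is estimated from trajectory start states
#' and held fixed in the fit, and only first binding events enter the scan.
#'
#' @param cfg A [run_config()].
#' @return A list of class `pipeline_result`: `table` (the results data
#'   frame), `fit`, `scan`, `lifetime`, `transitions`, `config_hash`, `seed`.
#'   If `cfg$out_dir` is set, `results.tsv` and `scan.tsv` are written there.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  set.seed(cfg$seed)

  trajs <- if (inherits(cfg$input, "sim_config")) {
    simulate_ctmc_photons(cfg$input)
  } else {
    unlist(lapply(cfg$input, read_photon_tsv), recursive = FALSE)
  }
  condition <- trajs[[1]]$meta$condition
  if (is.null(condition)) condition <- "unlabeled"

  # crude efficiency guesses for segmentation from the pooled color fraction
  guess <- initial_guess(trajs, cfg$init)
  seg_model <- make_two_state(two_state_params(
    guess$E_B, guess$E_U, guess$k_A_app, guess$k_D))

  paths <- lapply(trajs, viterbi_path, model = seg_model)
  trans <- lapply(paths, find_transitions, min_residence = cfg$min_residence)

  # kinetic fit
  if (cfg$barnase_mode) {
    pB <- estimate_pB_from_start(trajs, guess$E_B, guess$E_U)
    pB <- min(max(pB, 0.02), 0.98)
    fit <- fit_two_state(trajs, init = guess, fix_pB = pB)
  } else if (cfg$fit_model == "two-state") {
    fit <- fit_two_state(trajs, init = guess)
  } else {
    fit <- fit_four_state(trajs, init = guess)
  }

  scan <- NULL; lifetime <- NULL
  if (cfg$scan) {
    strans <- if (cfg$barnase_mode) first_event_only(trans) else trans
    segments <- list()
    for (i in seq_along(trajs)) {
      if (!nrow(strans[[i]])) next
      segments <- c(segments, extract_segments(
        trajs[[i]], strans[[i]], window_total = cfg$window_total,
        min_window = cfg$min_window, max_window = cfg$max_window))
    }
    if (length(segments)) {
      base <- two_state_params(fit$params[["E_B"]], fit$params[["E_U"]],
                               fit$params[["k_A_app"]], fit$params[["k_D"]])
      blink <- if (cfg$scan_blink && !is.null(fit$params[["k_b"]]))
        blink_params(fit$params[["k_b"]], fit$params[["k_0"]],
                     E_d = if (!is.null(fit$params[["E_d"]]))
                       fit$params[["E_d"]] else 0.06)
      else NULL
      scan <- delta_lnL_scan(segments, base, blink = blink,
                             t_grid = cfg$t_grid, E_TC_mode = cfg$E_TC_mode)
      lifetime <- find_lifetime_or_bound(scan, conf = cfg$conf)
    }
  }

  table <- results_table(condition, fit, lifetime, cfg)
  res <- structure(list(table = table, fit = fit, scan = scan,
                        lifetime = lifetime, transitions = trans,
                        config_hash = config_hash(cfg), seed = cfg$seed),
                   class = "pipeline_result")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(table, file.path(cfg$out_dir, "results.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(scan))
      utils::write.table(
        data.frame(t_TC_s = scan$t_grid, delta_lnL = scan$delta_lnL),
        file.path(cfg$out_dir, "scan.tsv"),
        sep = "\t", row.names = FALSE, quote = FALSE)
  }
  res
}

initial_guess <- function(trajs, init) {
  g <- list(E_B = 0.7, E_U = 0.2, k_A_app = 100, k_D = 100)
  acc <- unlist(lapply(trajs, function(tr) tr$colors))
  if (length(acc)) {
    m <- mean(acc)
    g$E_B <- min(m + 0.25, 0.95)
    g$E_U <- max(m - 0.25, 0.03)
  }
  for (nm in names(init)) g[[nm]] <- init[[nm]]
  g
}

results_table <- function(condition, fit, lifetime, cfg) {
  rows <- data.frame(condition = condition, model = fit$model_type,
                     parameter = names(fit$params),
                     estimate = as.numeric(fit$params),
                     stderr = as.numeric(fit$stderr), flags = "")
  if (!is.null(cfg$concentration_M)) {
    kA <- association_rate_coefficient(fit$params[["k_A_app"]],
                                       cfg$concentration_M)
    rows <- rbind(rows, data.frame(
      condition = condition, model = fit$model_type, parameter = "k_A",
      estimate = kA,
      stderr = fit$stderr[["k_A_app"]] / cfg$concentration_M, flags = ""))
  }
  if (!is.null(lifetime)) {
    if (lifetime$type == "lifetime") {
      rows <- rbind(rows, data.frame(
        condition = condition, model = paste0("TC scan (", cfg$E_TC_mode, ")"),
        parameter = "t_TC", estimate = lifetime$t_hat,
        stderr = lifetime$stderr, flags = "peak>+3"))
    } else if (lifetime$type == "upper_bound") {
      rows <- rbind(rows, data.frame(
        condition = condition, model = paste0("TC scan (", cfg$E_TC_mode, ")"),
        parameter = "t_TC", estimate = lifetime$upper_bound,
        stderr = NA_real_, flags = "upper_bound"))
    }
  }
  rownames(rows) <- NULL
  rows
}

#' Human-readable summary of pipeline results
#'
#' @param results A `pipeline_result` (or list of them for several
#'   conditions, sorted by their condition labels).
#' @return Character vector of summary lines, invisibly; also printed.
#' @export
report <- function(results) {
  if (inherits(results, "pipeline_result")) results <- list(results)
  labs <- vapply(results, function(r) r$table$condition[1], "")
  results <- results[order(labs)]
  lines <- character(0)
  for (r in results) {
    tb <- r$table
    cond <- tb$condition[1]
    lines <- c(lines, sprintf("condition %s:", cond))
    p <- function(nm) {
      i <- match(nm, tb$parameter)
      if (is.na(i)) NULL else tb[i, ]
    }
    kArow <- p("k_A")
    if (is.null(kArow)) {
      lines <- c(lines,
                 "  k_A omitted: no binding-partner concentration supplied")
    } else {
      lines <- c(lines, sprintf("  k_A = %.3g M^-1 s^-1", kArow$estimate))
    }
    kAapp <- p("k_A_app"); kD <- p("k_D")
    if (!is.null(kAapp) && !is.null(kD))
      lines <- c(lines, sprintf(
        "  k_A_app = %.3g +/- %.2g s^-1, k_D = %.3g +/- %.2g s^-1, p_B = %.3f",
        kAapp$estimate, kAapp$stderr, kD$estimate, kD$stderr,
        kAapp$estimate / (kAapp$estimate + kD$estimate)))
    tTC <- p("t_TC")
    if (!is.null(tTC)) {
      if (identical(tTC$flags, "upper_bound")) {
        lines <- c(lines, sprintf(
          "  no significant likelihood peak: only the upper bound of the TC lifetime can be determined, t_TC <= %.3g us",
          tTC$estimate * 1e6))
      } else {
        lines <- c(lines, sprintf("  t_TC = %.3g +/- %.2g us",
                                  tTC$estimate * 1e6, tTC$stderr * 1e6))
      }
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
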