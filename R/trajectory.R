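#' Photon trajectory objects
#'
#' A `photon_trajectory` is the atomic input of every analysis stage: the
#' ordered arrival times (seconds) and detection channels (donor/acceptor) of
#' all photons recorded from one immobilized molecule, plus free-form
#' metadata (condition label, binding-partner concentration, illumination
#' note).
#'
#' @param times Numeric vector of strictly increasing photon arrival times in
#'   seconds.
#' @param colors Photon channels: integer (0 = donor, 1 = acceptor), logical,
#'   or character `"donor"`/`"acceptor"`.
#' @param id Trajectory identifier (coerced to character).
#' @param meta Named list of metadata. Recognised entries: `condition`,
#'   `concentration_M`, `power_note`.
#'
#' @return An object of class `photon_trajectory` with elements `id`, `times`,
#'   `colors` (integer 0/1) and `meta`.
#' @examples
#' tr <- photon_trajectory(c(0, 1e-4, 3e-4), c(0L, 1L, 1L))
#' count_rate_ms(tr)
#' @export
photon_trajectory <- function(times, colors, id = "traj1", meta = list()) {
  times <- as.numeric(times)
  colors <- encode_colors(colors)
  if (length(times) != length(colors))
    stop("times and colors must have equal length")
  if (length(times) >= 2 && any(diff(times) <= 0))
    stop("photon arrival times must be strictly increasing")
  if (!is.list(meta)) stop("meta must be a list")
  structure(
    list(id = as.character(id), times = times, colors = colors, meta = meta),
    class = "photon_trajectory"
  )
}

encode_colors <- function(colors) {
  if (is.character(colors)) {
    m <- match(colors, c("donor", "acceptor"))
    if (anyNA(m)) stop("colors must be 'donor' or 'acceptor'")
    return(m - 1L)
  }
  colors <- as.integer(colors)
  if (length(colors) && !all(colors %in% c(0L, 1L)))
    stop("integer colors must be 0 (donor) or 1 (acceptor)")
  colors
}

#' @export
print.photon_trajectory <- function(x, ...) {
  dur <- trajectory_duration(x)
  cat(sprintf(
    "photon_trajectory '%s': %d photons, %.4g s, %.3g photons/ms (%.0f%% acceptor)\n",
    x$id, length(x$times), dur, count_rate_ms(x),
    if (length(x$colors)) 100 * mean(x$colors) else 0
  ))
  invisible(x)
}

#' Trajectory duration in seconds
#'
#' Time span from the first to the last photon.
#' @param traj A [photon_trajectory()].
#' @return Duration in seconds (0 for fewer than 2 photons).
#' @export
trajectory_duration <- function(traj) {
  if (length(traj$times) < 2) return(0)
  diff(range(traj$times))
}

#' Mean photon count rate in photons per millisecond
#'
#' The per-trajectory mean count rate `n` drives the intensity-dependent
#' acceptor dark-state entry rate, so it is quoted in the unit the blinking
#' model uses (ms^-1).
#' @param traj A [photon_trajectory()].
#' @return Count rate in photons/ms.
#' @export
count_rate_ms <- function(traj) {
  dur <- trajectory_duration(traj)
  if (dur <= 0) return(NA_real_)
  length(traj$times) / (dur * 1000)
}

#' Read photon trajectories from a PHOT-TSV file
#'
#' PHOT-TSV is the project's plain-text photon format: optional
#' `#`-prefixed `key=value` header lines, then tab-separated columns
#' `time_s` and `channel` (0 = donor, 1 = acceptor), with an optional third
#' column `trajectory_id` for multi-molecule files.
#'
#' @param path File path.
#' @return A list of [photon_trajectory()] objects.
#' @seealso [write_photon_tsv()]
#' @export
read_photon_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- list()
  for (h in sub("^#\\s*", "", lines[hdr])) {
    kv <- strsplit(h, "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) {
      val <- trimws(kv[2])
      num <- suppressWarnings(as.numeric(val))
      meta[[trimws(kv[1])]] <- if (!is.na(num)) num else val
    }
  }
  body <- lines[!hdr & nzchar(lines)]
  if (!length(body)) stop("no photon records in ", path)
  con <- textConnection(body)
  on.exit(close(con))
  df <- utils::read.table(con, sep = "\t", header = FALSE,
                          col.names = c("time_s", "channel", "trajectory_id")[
                            seq_len(length(strsplit(body[1], "\t")[[1]]))],
                          stringsAsFactors = FALSE)
  if (is.null(df$trajectory_id)) df$trajectory_id <- "traj1"
  lapply(split(df, df$trajectory_id), function(d) {
    # the 1 ns file resolution can collapse near-coincident photons
    keep <- c(TRUE, diff(d$time_s) > 0)
    photon_trajectory(d$time_s[keep], d$channel[keep],
                      id = d$trajectory_id[1], meta = meta)
  })
}

#' Write photon trajectories to a PHOT-TSV file
#'
#' @param trajs A [photon_trajectory()] or list of them.
#' @param path Output file path.
#' @param meta Named list written as `# key=value` header lines (defaults to
#'   the first trajectory's metadata).
#' @return `path`, invisibly.
#' @export
write_photon_tsv <- function(trajs, path, meta = NULL) {
  trajs <- as_trajectory_list(trajs)
  if (is.null(meta)) meta <- trajs[[1]]$meta
  hdr <- vapply(names(meta), function(k) sprintf("# %s=%s", k, meta[[k]]), "")
  rows <- do.call(rbind, lapply(trajs, function(tr) {
    data.frame(time_s = sprintf("%.9f", tr$times), channel = tr$colors,
               trajectory_id = tr$id)
  }))
  body <- sprintf("%s\t%s\t%s", rows$time_s, rows$channel, rows$trajectory_id)
  writeLines(c(hdr, body), path)
  invisible(path)
}

as_trajectory_list <- function(trajs) {
  if (inherits(trajs, "photon_trajectory")) return(list(trajs))
  if (!is.list(trajs) || !all(vapply(trajs, inherits, TRUE, "photon_trajectory")))
    stop("expected a photon_trajectory or a list of them")
  trajs
}
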