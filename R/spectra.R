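# Derived spectra. All spectrum objects are tibbles (one row per frequency,
# or per frequency x axis for accelerations) so they compose with dplyr and
# ggplot2; classes tag them for autoplot()/tidy()/find_extrema() dispatch.

new_spectrum <- function(df, class, ...) {
  out <- tibble::as_tibble(df)
  attr(out, "spectrum_meta") <- list(...)
  class(out) <- c(class, "vibro_spectrum", class(out))
  out
}

db_level <- function(z) 20 * log10(Mod(z))
phase_cycles <- function(z) Arg(z) / (2 * pi)

#' Mechanical point impedance spectrum
#'
#' The driving-point impedance `Zm = F / v`: applied force divided by the
#' complex velocity at the drive node projected on the drive direction,
#' `v = 1i * 2 pi f * x_drive`. Levels are `20 log10 |Zm|` in dB re
#' 1 N s/m; phases in cycles. A structural resonance appears as a local
#' minimum of `|Zm|`.
#'
#' Should the drive node sit exactly on a node of vibration (zero
#' velocity), the affected rows are flagged with `ok = FALSE` and infinite
#' level rather than raising an error.
#'
#' @param sol a [solve_sweep()] result.
#' @return an `impedance_spectrum` tibble: `f_hz`, `re`, `im`, `level_db`,
#'   `phase_cycles` (plus `ok` if any point was flagged).
#' @export
point_impedance <- function(sol) {
  stopifnot(inherits(sol, "harmonic_solution"))
  load <- sol$load
  # projection of x on the drive shape; for a unit-direction single-node
  # load this is the displacement component along the drive direction
  wsum <- sum(load$weights^2)
  proj <- as.vector(crossprod(load$weights, sol$X[load$dofs, , drop = FALSE])) / wsum
  v <- 1i * 2 * pi * sol$frequencies * proj
  bad <- Mod(v) == 0
  Z <- ifelse(bad, complex(real = Inf), load$amplitude / v)
  out <- new_spectrum(
    tibble::tibble(f_hz = sol$frequencies, re = Re(Z), im = Im(Z),
                   level_db = db_level(Z), phase_cycles = phase_cycles(Z)),
    "impedance_spectrum")
  if (any(bad)) {
    warning(sum(bad), " frequency point(s) with zero drive-point velocity")
    out$ok <- !bad
  }
  out
}

#' Probe acceleration spectrum
#'
#' Averages the complex displacement over a probe node set per axis (the
#' nodes of a small patch are assumed to move alike), converts to
#' acceleration `a = -(2 pi f)^2 x_bar`, and normalises per newton of
#' drive. Levels in dB re 1 (m/s^2)/N, phases in cycles.
#'
#' @param sol a [solve_sweep()] result.
#' @param probe name of a node set carried by the system, or an integer
#'   vector of node indices.
#' @return an `acceleration_spectrum` tibble in long form: `f_hz`, `axis`
#'   ("x", "y", "z"), `re`, `im`, `level_db`, `phase_cycles`.
#' @export
probe_acceleration <- function(sol, probe) {
  stopifnot(inherits(sol, "harmonic_solution"))
  name <- NULL
  if (is.character(probe)) {
    name <- probe
    if (!probe %in% names(sol$node_sets))
      stop("solution carries no node set '", probe, "'")
    probe <- sol$node_sets[[probe]]
  }
  probe <- as.integer(probe)
  if (!length(probe)) stop("probe node set is empty")
  w2 <- (2 * pi * sol$frequencies)^2
  per_axis <- lapply(1:3, function(a) {
    dofs <- 3L * (probe - 1L) + a
    xbar <- colMeans(sol$X[dofs, , drop = FALSE])
    -w2 * xbar / sol$load$amplitude
  })
  axes <- c("x", "y", "z")
  df <- do.call(rbind, lapply(1:3, function(a) {
    z <- per_axis[[a]]
    data.frame(f_hz = sol$frequencies, axis = axes[a], re = Re(z),
               im = Im(z), level_db = db_level(z),
               phase_cycles = phase_cycles(z))
  }))
  new_spectrum(df[order(df$f_hz, match(df$axis, axes)), ],
               "acceleration_spectrum", probe = name)
}

# map x to (-0.5, 0.5] by subtracting an integer
wrap_half <- function(x) x - ceiling(x - 0.5)

#' Unwrap a phase trace
#'
#' Removes the 1-cycle jumps of a wrapped phase trace: the first point is
#' mapped into `(-0.5, 0.5]` cycles and each subsequent step is wrapped
#' into that interval before accumulating, so the unwrapped trace differs
#' from the raw one by an integer number of cycles at every point. Valid
#' when the grid is dense enough that true inter-point phase changes stay
#' below half a cycle.
#'
#' @param f_hz frequencies in Hz.
#' @param phase wrapped phase in cycles.
#' @return a `phase_trace` tibble: `f_hz`, `phase_cycles` (unwrapped).
#' @export
unwrap_phase <- function(f_hz, phase) {
  if (length(f_hz) != length(phase))
    stop("f_hz and phase must have equal length")
  out <- numeric(length(phase))
  if (length(phase)) {
    out[1L] <- wrap_half(phase[1L])
    if (length(phase) > 1L)
      out[-1L] <- out[1L] + cumsum(wrap_half(diff(phase)))
  }
  new_spectrum(tibble::tibble(f_hz = as.numeric(f_hz), phase_cycles = out),
               "phase_trace")
}

#' Group delay of an unwrapped phase trace
#'
#' `tau_gd = -(1 / 2 pi) d phi / d f` with phi in radians; with phase in
#' cycles this is simply `-d phase / d f`. Central finite differences on
#' interior points, one-sided at the ends.
#'
#' @param trace a [unwrap_phase()] result (or any tibble with `f_hz` and
#'   unwrapped `phase_cycles`).
#' @return the trace with a `group_delay_s` column added.
#' @export
group_delay <- function(trace) {
  f <- trace$f_hz; p <- trace$phase_cycles
  n <- length(f)
  if (n < 3L) stop("need at least 3 points to estimate group delay")
  d <- numeric(n)
  d[1L] <- (p[2L] - p[1L]) / (f[2L] - f[1L])
  d[n] <- (p[n] - p[n - 1L]) / (f[n] - f[n - 1L])
  i <- 2:(n - 1L)
  d[i] <- (p[i + 1L] - p[i - 1L]) / (f[i + 1L] - f[i - 1L])
  trace$group_delay_s <- -d
  trace
}

# Extrema of one level trace in (log10 f, dB) coordinates with parabolic
# refinement. Plateau ties break toward the lower frequency.
trace_extrema <- function(f_hz, level_db) {
  n <- length(f_hz)
  if (n < 3L) stop("need at least 3 grid points")
  x <- log10(f_hz); y <- level_db
  out <- list()
  for (i in 2:(n - 1L)) {
    is_min <- y[i] < y[i - 1L] && y[i] <= y[i + 1L] && y[i] < max(y[i + 1L], y[i - 1L])
    is_max <- y[i] > y[i - 1L] && y[i] >= y[i + 1L] && y[i] > min(y[i + 1L], y[i - 1L])
    if (!is_min && !is_max) next
    d1 <- (y[i] - y[i - 1L]) / (x[i] - x[i - 1L])
    d2 <- (y[i + 1L] - y[i]) / (x[i + 1L] - x[i])
    dd <- (d2 - d1) / (x[i + 1L] - x[i - 1L])
    if (dd != 0) {
      xs <- (x[i - 1L] + x[i]) / 2 - d1 / (2 * dd)
      xs <- min(max(xs, x[i - 1L]), x[i + 1L])
      ys <- y[i - 1L] + d1 * (xs - x[i - 1L]) + dd * (xs - x[i - 1L]) * (xs - x[i])
    } else {
      xs <- x[i]; ys <- y[i]
    }
    out[[length(out) + 1L]] <-
      data.frame(f_hz = 10^xs, level_db = ys,
                 kind = if (is_min) "min" else "max")
  }
  if (!length(out))
    return(data.frame(f_hz = numeric(0), level_db = numeric(0),
                      kind = character(0)))
  do.call(rbind, out)
}

#' Locate resonances and antiresonances in a level trace
#'
#' Local extrema of the dB level versus log frequency, refined by parabolic
#' interpolation through the extremum and its neighbours. For a
#' driving-point impedance spectrum, minima are structural resonances and
#' maxima antiresonances; for a transfer acceleration spectrum the labels
#' invert (a resonance boosts the response).
#'
#' @param spectrum an `impedance_spectrum` or `acceleration_spectrum`.
#' @return tibble with `f_hz`, `level_db`, `type`
#'   ("resonance"/"antiresonance"), and `axis` for acceleration spectra.
#'   Zero rows for a monotone trace.
#' @export
find_extrema <- function(spectrum) {
  if (inherits(spectrum, "acceleration_spectrum")) {
    axes <- unique(spectrum$axis)
    out <- do.call(rbind, lapply(axes, function(a) {
      sub <- spectrum[spectrum$axis == a, ]
      ex <- trace_extrema(sub$f_hz, sub$level_db)
      if (nrow(ex)) ex$axis <- a else ex$axis <- character(0)
      ex
    }))
    out$type <- ifelse(out$kind == "max", "resonance", "antiresonance")
    return(tibble::as_tibble(out[order(out$f_hz),
                                 c("axis", "f_hz", "level_db", "type")]))
  }
  ex <- trace_extrema(spectrum$f_hz, spectrum$level_db)
  ex$type <- ifelse(ex$kind == "min", "resonance", "antiresonance")
  tibble::as_tibble(ex[c("f_hz", "level_db", "type")])
}

#' Write a spectrum as CSV
#'
#' One row per frequency. Impedance spectra and phase traces keep their
#' column order (`f_hz, re, im, level_db, phase_cycles[, group_delay_s]`);
#' acceleration spectra are widened to one group of
#' `re, im, level_db, phase_cycles` columns per axis, prefixed `ax_`,
#' `ay_`, `az_`. Values carry 17 significant digits so identical runs give
#' byte-identical files.
#'
#' @param spectrum a spectrum tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  df <- as.data.frame(spectrum)
  if (inherits(spectrum, "acceleration_spectrum")) {
    axes <- c("x", "y", "z")
    wide <- data.frame(f_hz = unique(df$f_hz))
    for (a in axes) {
      sub <- df[df$axis == a, ]
      for (col in c("re", "im", "level_db", "phase_cycles"))
        wide[[paste0("a", a, "_", col)]] <- sub[[col]]
    }
    df <- wide
  } else df$kind <- NULL
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
  }, character(nrow(df)))
  if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1L, dimnames = list(NULL, names(df)))
  lines <- c(paste(names(df), collapse = ","),
             apply(fmt, 1L, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a spectrum CSV written by [write_spectrum_csv()]
#' @param path CSV path.
#' @return a tibble.
#' @export
read_spectrum_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}

# ---- broom-style and plotting methods --------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method tidy vibro_spectrum
#' @export
tidy.vibro_spectrum <- function(x, ...) {
  out <- x
  class(out) <- c("tbl_df", "tbl", "data.frame")
  attr(out, "spectrum_meta") <- NULL
  out
}

#' @method glance impedance_spectrum
#' @export
glance.impedance_spectrum <- function(x, ...) {
  ex <- find_extrema(x)
  res <- ex[ex$type == "resonance", , drop = FALSE]
  tibble::tibble(
    n_freq = nrow(x),
    f_min = min(x$f_hz), f_max = max(x$f_hz),
    f_resonance = if (nrow(res)) res$f_hz[1L] else NA_real_,
    level_at_resonance_db = if (nrow(res)) res$level_db[1L] else NA_real_,
    n_extrema = nrow(ex))
}

#' @method glance acceleration_spectrum
#' @export
glance.acceleration_spectrum <- function(x, ...) {
  do.call(rbind, lapply(split(x, x$axis), function(sub) {
    tibble::tibble(axis = sub$axis[1L], n_freq = nrow(sub),
                   peak_level_db = max(sub$level_db),
                   f_peak = sub$f_hz[which.max(sub$level_db)])
  }))
}

#' @method autoplot impedance_spectrum
#' @export
autoplot.impedance_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$f_hz, y = .data$level_db)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Frequency (Hz)",
                  y = expression("|" * Z[m] * "| (dB re 1 N s/m)"),
                  title = "Mechanical point impedance")
}

#' @method autoplot acceleration_spectrum
#' @export
autoplot.acceleration_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$f_hz, y = .data$level_db,
                                       colour = .data$axis)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Frequency (Hz)",
                  y = "Acceleration (dB re 1 (m/s²)/N)",
                  colour = "Axis",
                  title = "Cochlear-bone acceleration per unit force")
}

#' @method autoplot phase_trace
#' @export
autoplot.phase_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$f_hz, y = .data$phase_cycles)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Frequency (Hz)", y = "Phase (cycles)",
                  title = "Unwrapped phase")
}

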