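#' Uniformly sampled waveform
#'
#' One physical quantity (pressure, velocity, flow rate or area) sampled at a
#' fixed interval at one site.  All analysis and detection routines operate
#' on this container; the site metadata travels with the samples.
#'
#' @param values Numeric sample vector (finite).
#' @param dt Sampling interval (s).
#' @param t_start Time of the first sample (s).
#' @param quantity One of "pressure", "velocity", "flow", "area".
#' @param units Unit string ("Pa", "m/s", "m^3/s", "m^2").
#' @param site Site label, e.g. "main-proximal@0.02".
#' @param pulse_start Optional known pulse onset time (s).
#' @return Object of class `waveform`.
#' @export
waveform <- function(values, dt, t_start = 0,
                     quantity = c("pressure", "velocity", "flow", "area"),
                     units = NULL, site = "unknown", pulse_start = NULL) {
  quantity <- match.arg(quantity)
  stopifnot(is.numeric(values), length(values) >= 16L, all(is.finite(values)),
            is.numeric(dt), dt > 0)
  if (is.null(units))
    units <- switch(quantity, pressure = "Pa", velocity = "m/s",
                    flow = "m^3/s", area = "m^2")
  structure(list(values = as.numeric(values), dt = dt, t_start = t_start,
                 quantity = quantity, units = units, site = site,
                 pulse_start = pulse_start),
            class = "waveform")
}

#' @export
length.waveform <- function(x) length(x$values)

#' Sample times of a waveform
#' @param w A [waveform()].
#' @return Numeric vector of sample times (s).
#' @export
wf_time <- function(w) w$t_start + (seq_along(w$values) - 1L) * w$dt

#' @export
as.data.frame.waveform <- function(x, ...) {
  data.frame(t_s = wf_time(x), value = x$values)
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %s [%s] at %s: %d samples, dt = %g s, t = [%g, %g] s\n",
              x$quantity, x$units, x$site, length(x$values), x$dt,
              x$t_start, x$t_start + (length(x$values) - 1L) * x$dt))
  invisible(x)
}

# internal: shallow copy with new values, same metadata
wf_with <- function(w, values, quantity = w$quantity, units = w$units) {
  w$values <- values
  w$quantity <- quantity
  w$units <- units
  w
}

#' Write a waveform to CSV
#'
#' Plain-text format with metadata header lines (`# site=`, `# quantity=`,
#' `# units=`, `# dt=`) followed by `t_s,value` columns.  Round-trips
#' losslessly through [read_waveform()].
#'
#' @param w A [waveform()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# site=%s", w$site),
               sprintf("# quantity=%s", w$quantity),
               sprintf("# units=%s", w$units),
               sprintf("# dt=%.17g", w$dt),
               "t_s,value"), con)
  writeLines(sprintf("%.17g,%.17g", wf_time(w), w$values), con)
  invisible(path)
}

#' Read a waveform from CSV
#'
#' @param path File written by [write_waveform()] (or following the same
#'   header contract).
#' @return A [waveform()].
#' @export
read_waveform <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  if (length(hdr_idx) && any(diff(hdr_idx) != 1L))
    stop("read_waveform: header lines must precede the data block")
  hdr <- lines[hdr_idx]
  meta <- list()
  for (i in seq_along(hdr)) {
    m <- regmatches(hdr[i], regexec("^#\\s*([a-zA-Z_]+)=(.*)$", hdr[i]))[[1]]
    if (length(m) != 3L)
      stop(sprintf("read_waveform: malformed header at line %d: '%s'", i, hdr[i]))
    meta[[m[2]]] <- m[3]
  }
  for (key in c("site", "quantity", "units", "dt"))
    if (is.null(meta[[key]]))
      stop(sprintf("read_waveform: missing required header key '%s'", key))
  body <- lines[-seq_len(length(hdr_idx) + 1L)]   # drop headers + column line
  if (lines[length(hdr_idx) + 1L] != "t_s,value")
    stop(sprintf("read_waveform: expected column line 't_s,value' at line %d",
                 length(hdr_idx) + 1L))
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop(sprintf("read_waveform: malformed data row at line %d",
                 length(hdr_idx) + 1L + bad[1]))
  t <- as.numeric(vapply(parts, `[[`, "", 1L))
  v <- as.numeric(vapply(parts, `[[`, "", 2L))
  if (anyNA(t) || anyNA(v))
    stop("read_waveform: non-numeric entry in data block")
  dt <- as.numeric(meta$dt)
  if (length(t) > 1L) {
    steps <- diff(t)
    if (any(abs(steps - dt) > 1e-9 * max(dt, 1)))
      stop(sprintf("read_waveform: non-uniform sampling at line %d",
                   length(hdr_idx) + 1L + which(abs(steps - dt) > 1e-9 * max(dt, 1))[1] + 1L))
  }
  waveform(v, dt = dt, t_start = t[1], quantity = meta$quantity,
           units = meta$units, site = meta$site)
}
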