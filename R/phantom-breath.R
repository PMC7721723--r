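#' Specification of a synthetic breathing trace
#'
#' Parameters map onto the seven whole-body plethysmography outputs: tidal
#' volume, respiratory rate, minute volume (their product), inspiratory and
#' expiratory times (via `ti_fraction`), and peak inspiratory/expiratory flows
#' (analytic for half-sine lobes: `PIF = pi * TV / (2 * Ti)` and
#' `PEF = pi * TV / (2 * Te)`).
#'
#' @param tidal_volume_ml tidal volume per breath, ml (> 0).
#' @param rate_bpm respiratory rate, breaths per minute (> 0).
#' @param ti_fraction fraction of each cycle spent in inspiration (0 < f < 1).
#' @param duration_s trace duration, s.
#' @param noise_sd Gaussian flow noise SD, ml/s.
#' @param movement_epochs list of `c(start_s, end_s)` intervals during which
#'   the movement channel is 1 (animal active).
#' @param sampling_hz sampling rate; must be at least 20x the breathing
#'   frequency. Default 1000 Hz.
#' @param seed integer seed; identical seeds give bit-identical traces.
#' @return a `breath_spec` list.
#' @export
breath_spec <- function(tidal_volume_ml = 0.15, rate_bpm = 150, ti_fraction = 0.5,
                        duration_s = 60, noise_sd = 0, movement_epochs = list(),
                        sampling_hz = 1000, seed = 1L) {
  stopifnot(tidal_volume_ml > 0, rate_bpm > 0,
            ti_fraction > 0, ti_fraction < 1,
            duration_s > 0, noise_sd >= 0)
  if (sampling_hz < 20 * rate_bpm / 60) {
    stop("`sampling_hz` must be at least 20x the breathing frequency", call. = FALSE)
  }
  structure(
    list(tidal_volume_ml = tidal_volume_ml, rate_bpm = rate_bpm,
         ti_fraction = ti_fraction, duration_s = duration_s,
         noise_sd = noise_sd, movement_epochs = movement_epochs,
         sampling_hz = sampling_hz, seed = as.integer(seed)),
    class = "breath_spec"
  )
}

cumtrapz_vec <- function(t, y) {
  n <- length(y)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(t)))
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic breathing trace
#'
#' Flow is a half-sine inspiration (positive by convention) followed by a
#' half-sine expiration scaled so each breath returns volume to baseline;
#' volume is the cumulative trapezoid integral of flow; the movement channel
#' is 1 inside the configured movement epochs and 0 elsewhere. Pure function
#' of the spec (including its seed).
#'
#' @param spec a [breath_spec()].
#' @return a `breath_trace` tibble with columns `time_s`, `flow_ml_s`,
#'   `volume_ml`, `movement`, carrying the spec as attribute `"spec"`.
#' @examples
#' tr <- make_breath_trace(breath_spec(duration_s = 5))
#' head(tr)
#' @export
make_breath_trace <- function(spec = breath_spec()) {
  stopifnot(inherits(spec, "breath_spec"))
  dt <- 1 / spec$sampling_hz
  t <- seq(0, spec$duration_s, by = dt)
  period <- 60 / spec$rate_bpm
  ti <- spec$ti_fraction * period
  te <- period - ti
  phase <- t %% period
  pif <- pi * spec$tidal_volume_ml / (2 * ti)
  pef <- pi * spec$tidal_volume_ml / (2 * te)
  flow <- ifelse(phase < ti,
                 pif * sin(pi * phase / ti),
                 -pef * sin(pi * (phase - ti) / te))
  if (spec$noise_sd > 0) {
    flow <- flow + with_seed(spec$seed, rnorm(length(flow), 0, spec$noise_sd))
  }
  movement <- rep(FALSE, length(t))
  for (ep in spec$movement_epochs) {
    movement[t >= ep[1] & t <= ep[2]] <- TRUE
  }
  out <- tibble::tibble(
    time_s = t,
    flow_ml_s = flow,
    volume_ml = cumtrapz_vec(t, flow),
    movement = movement
  )
  attr(out, "spec") <- spec
  class(out) <- c("breath_trace", class(out))
  out
}

#' Read / write breathing traces as CSV
#'
#' Column layout: `time_s, flow_ml_s, volume_ml, movement` (movement as 0/1).
#'
#' @param trace a breath-trace data frame.
#' @param path CSV path.
#' @return `read_breath_trace()` returns a `breath_trace` tibble;
#'   `write_breath_trace()` returns `path` invisibly.
#' @export
write_breath_trace <- function(trace, path) {
  df <- as.data.frame(trace)
  df$movement <- as.integer(df$movement)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_breath_trace
#' @export
read_breath_trace <- function(path) {
  df <- read.csv(path)
  req <- c("time_s", "flow_ml_s", "volume_ml", "movement")
  if (!all(req %in% names(df))) {
    stop("trace CSV must have columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(df[req])
  out$movement <- as.logical(out$movement)
  class(out) <- c("breath_trace", class(out))
  out
}
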