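# Breath detection and the seven respiratory parameters from whole-body
# plethysmography traces: tidal volume, respiratory rate, minute volume,
# inspiratory/expiratory times, peak inspiratory/expiratory flows.

#' Quiet (movement-free) epoch selection
#'
#' Wakeful baseline breathing is scored only during quiet epochs: maximal
#' intervals of the movement channel at 0 lasting at least `min_duration_s`
#' (inclusive threshold, so an epoch of exactly the minimum duration counts).
#'
#' @param trace a breath-trace data frame (`time_s`, `flow_ml_s`,
#'   `volume_ml`, `movement`).
#' @param min_duration_s minimum quiet duration, s (default 5).
#' @return tibble with `epoch_id`, `start_s`, `end_s`, `duration_s`
#'   (possibly zero rows).
#' @export
select_quiet_epochs <- function(trace, min_duration_s = 5) {
  stopifnot(all(c("time_s", "movement") %in% names(trace)))
  quiet <- !trace$movement
  if (!any(quiet)) {
    return(tibble::tibble(epoch_id = integer(), start_s = numeric(),
                          end_s = numeric(), duration_s = numeric()))
  }
  r <- rle(quiet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  out <- tibble::tibble(
    start_s = trace$time_s[starts[keep]],
    end_s = trace$time_s[ends[keep]]
  )
  out$duration_s <- out$end_s - out$start_s
  out <- out[out$duration_s >= min_duration_s - 1e-9, , drop = FALSE]
  out$epoch_id <- seq_len(nrow(out))
  out[, c("epoch_id", "start_s", "end_s", "duration_s")]
}

#' Detect breaths within quiet epochs
#'
#' A breath is one positive-flow (inspiratory) lobe followed by its
#' expiratory lobe, delimited by hysteresis-guarded zero crossings of the
#' flow signal: a crossing only counts once flow has exceeded a guard band
#' (default 5% of the robust flow amplitude), which prevents noise from
#' splitting breaths. Crossing times are refined by linear interpolation.
#' Breaths that are not entirely inside one quiet epoch are discarded whole.
#'
#' @param trace a breath-trace data frame (inspiration positive).
#' @param epochs quiet epochs from [select_quiet_epochs()]; defaults to
#'   computing them from the trace's movement channel.
#' @param hysteresis_frac guard band as a fraction of the robust (95th
#'   percentile) flow amplitude.
#' @return a `breath_table` tibble: `onset_s`, `tidal_volume_ml`, `ti_ms`,
#'   `te_ms`, `pif_ml_s`, `pef_ml_s`, `epoch_id`.
#' @export
detect_breaths <- function(trace, epochs = select_quiet_epochs(trace),
                           hysteresis_frac = 0.05) {
  t <- trace$time_s
  f <- trace$flow_ml_s
  n <- length(t)
  empty <- tibble::tibble(
    onset_s = numeric(), tidal_volume_ml = numeric(), ti_ms = numeric(),
    te_ms = numeric(), pif_ml_s = numeric(), pef_ml_s = numeric(),
    epoch_id = integer()
  )
  class(empty) <- c("breath_table", class(empty))
  if (n < 3 || nrow(epochs) == 0) return(empty)

  amp <- as.numeric(quantile(abs(f), 0.95))
  if (amp <= 0) return(empty)
  band <- hysteresis_frac * amp

  # undersampling check: dominant frequency from guarded sign changes
  dt <- diff(t)
  fs <- 1 / stats::median(dt)
  state <- sign(f) * (abs(f) > band)
  st <- state[state != 0]
  n_half <- sum(diff(st) != 0)
  if (n_half > 2) {
    span <- t[n] - t[1]
    f_dom <- (n_half / 2) / span
    if (fs < 10 * f_dom) {
      warning(sprintf(
        "sampling rate %.1f Hz is below 10x the dominant breathing frequency %.2f Hz",
        fs, f_dom), call. = FALSE)
    }
  }

  # hysteresis state: +1 after exceeding +band, -1 after falling below -band
  hstate <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (f[i] > band) cur <- 1L else if (f[i] < -band) cur <- -1L
    hstate[i] <- cur
  }
  up <- which(diff(hstate == 1L) == 1L) + 1L   # first index in the +1 run
  down <- which(diff(hstate == -1L) == 1L) + 1L

  zero_before <- function(i) {
    # refine to the zero crossing at or before index i
    j <- i
    while (j > 1 && (f[j - 1] > 0) == (f[i] > 0) && f[j - 1] != 0) j <- j - 1
    if (j == 1) return(t[1])
    if (f[j] == 0) return(t[j])
    # linear interpolation between j-1 and j
    t[j - 1] + (0 - f[j - 1]) * (t[j] - t[j - 1]) / (f[j] - f[j - 1])
  }

  if (length(up) < 2) return(empty)
  rows <- list()
  for (b in seq_len(length(up) - 1)) {
    i0 <- up[b]
    i1 <- up[b + 1]
    dn <- down[down > i0 & down < i1]
    if (length(dn) == 0) next
    t_on <- zero_before(i0)
    t_exp <- zero_before(dn[1])
    t_end <- zero_before(i1)
    if (t_exp <= t_on || t_end <= t_exp) next
    ep <- which(epochs$start_s - 1e-9 <= t_on & epochs$end_s + 1e-9 >= t_end)
    if (length(ep) == 0) next
    insp <- which(t >= t_on & t <= t_exp)
    expn <- which(t >= t_exp & t <= t_end)
    tv <- sum(diff(t[insp]) * (head(f[insp], -1) + tail(f[insp], -1)) / 2)
    rows[[length(rows) + 1]] <- tibble::tibble(
      onset_s = t_on,
      tidal_volume_ml = tv,
      ti_ms = (t_exp - t_on) * 1e3,
      te_ms = (t_end - t_exp) * 1e3,
      pif_ml_s = max(f[insp]),
      pef_ml_s = abs(min(f[expn])),
      epoch_id = epochs$epoch_id[ep[1]]
    )
  }
  if (length(rows) == 0) return(empty)
  out <- dplyr::bind_rows(rows)
  class(out) <- c("breath_table", class(out))
  out
}

#' Tidal-volume plausibility filter
#'
#' Removes baseline drift and environmental-noise episodes: breaths are
#' excluded when the calculated tidal volume is less than `min_ml` or
#' greater than `max_ml` (strict inequalities — breaths exactly at a bound
#' are retained). Idempotent.
#'
#' @param table a `breath_table` from [detect_breaths()].
#' @param min_ml,max_ml retention bounds, ml (defaults 0.05 and 2.0).
#' @return the filtered `breath_table`.
#' @export
filter_breaths <- function(table, min_ml = 0.05, max_ml = 2.0) {
  out <- table[!(table$tidal_volume_ml < min_ml | table$tidal_volume_ml > max_ml), ,
               drop = FALSE]
  if (!inherits(out, "breath_table")) class(out) <- c("breath_table", class(out))
  out
}

#' Summarise respiration over retained breaths
#'
#' Respiratory rate is the number of breaths divided by the extracted time
#' (per minute); minute volume is mean tidal volume times respiratory rate
#' (exact by construction); the remaining parameters are means over the
#' retained breaths.
#'
#' @param table a (filtered) `breath_table`.
#' @param extracted_time_s duration of trace actually analysed, s. Defaults
#'   to the summed durations of the retained breaths, which makes the rate
#'   insensitive to incomplete breaths at epoch borders.
#' @return a `respiratory_summary` tibble (one row): `tidal_volume_ml`,
#'   `rr_per_min`, `minute_volume_ml_min`, `ti_ms`, `te_ms`, `pif_ml_s`,
#'   `pef_ml_s`, `extracted_time_s`, `n_breaths`.
#' @export
summarize_respiration <- function(table,
                                  extracted_time_s = sum(table$ti_ms + table$te_ms) / 1e3) {
  if (nrow(table) == 0 || extracted_time_s <= 0) {
    stop("empty-summary error: no retained breaths to summarise", call. = FALSE)
  }
  tv <- mean(table$tidal_volume_ml)
  rr <- nrow(table) / extracted_time_s * 60
  out <- tibble::tibble(
    tidal_volume_ml = tv,
    rr_per_min = rr,
    minute_volume_ml_min = tv * rr,
    ti_ms = mean(table$ti_ms),
    te_ms = mean(table$te_ms),
    pif_ml_s = mean(table$pif_ml_s),
    pef_ml_s = mean(table$pef_ml_s),
    extracted_time_s = extracted_time_s,
    n_breaths = nrow(table)
  )
  class(out) <- c("respiratory_summary", class(out))
  out
}

#' End-to-end respiratory analysis of one trace
#'
#' Quiet-epoch selection, breath detection, tidal-volume filtering and
#' summary in one call.
#'
#' @param trace a breath-trace data frame.
#' @param min_quiet_s minimum quiet-epoch duration, s.
#' @param min_tv_ml,max_tv_ml tidal-volume retention bounds, ml.
#' @return a `respiratory_summary` tibble.
#' @examples
#' tr <- make_breath_trace(breath_spec(duration_s = 20))
#' analyze_respiration(tr)
#' @export
analyze_respiration <- function(trace, min_quiet_s = 5,
                                min_tv_ml = 0.05, max_tv_ml = 2.0) {
  epochs <- select_quiet_epochs(trace, min_duration_s = min_quiet_s)
  breaths <- detect_breaths(trace, epochs)
  breaths <- filter_breaths(breaths, min_tv_ml, max_tv_ml)
  summarize_respiration(breaths)
}

#' @importFrom stats quantile median
NULL
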