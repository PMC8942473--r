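#' Detect action potentials in a voltage trace
#'
#' An action potential is a maximal run of samples strictly above the
#' amplitude criterion (default 0 mV; a sample exactly at the criterion is
#' subthreshold). Each suprathreshold excursion yields one event at the
#' time of its local maximum; events closer than `dead_time` to the
#' previous accepted event are merged into it.
#'
#' @param trace A voltage [trace()].
#' @param criterion Amplitude criterion in mV; default 0.
#' @param dead_time Minimum separation between events in ms; default 1.
#' @return A [spike_train()] spanning the trace.
#' @export
detect_spikes <- function(trace, criterion = 0, dead_time = 1) {
  if (!inherits(trace, "trace")) stop("expected a trace", call. = FALSE)
  if (trace$kind != "voltage")
    stop("detect_spikes requires a voltage trace, got ", trace$kind,
         call. = FALSE)
  v <- trace$samples
  above <- v > criterion
  times <- numeric(0)
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    tt <- trace_times(trace)
    peak_times <- vapply(runs, function(k) {
      idx <- starts[k]:ends[k]
      tt[idx[which.max(v[idx])]]
    }, numeric(1))
    # merge events closer than dead_time into the earlier accepted event
    keep <- numeric(0)
    for (p in peak_times) {
      if (length(keep) == 0L || p - keep[length(keep)] >= dead_time)
        keep <- c(keep, p)
    }
    times <- keep
  }
  end_t <- trace$t0 + trace$dt * (length(v) - 1L)
  spike_train(times - trace$t0, record_duration = end_t - trace$t0)
}

#' Mean firing rate over a window
#'
#' @param train A [spike_train()].
#' @param window Length-2 numeric `(start, end)` in ms, within the record.
#' @return Rate in spikes/s.
#' @export
firing_rate <- function(train, window = c(0, train$record_duration)) {
  stopifnot(inherits(train, "spike_train"))
  if (length(window) != 2L || !(window[2L] > window[1L]))
    stop("window must be (start, end) with end > start", call. = FALSE)
  if (window[1L] < 0 || window[2L] > train$record_duration)
    stop("window outside record", call. = FALSE)
  n <- sum(train$times >= window[1L] & train$times < window[2L])
  1000 * n / (window[2L] - window[1L])
}

#' First-spike latency relative to a stimulus onset
#'
#' @param train A [spike_train()].
#' @param stim_onset Stimulus onset in ms; defaults to the onset of the
#'   attached stimulus if present, else 0.
#' @return Object of class `latency_result` with fields `latency` (ms) and
#'   `spike_found`.
#' @export
first_spike_latency <- function(train, stim_onset = NULL) {
  stopifnot(inherits(train, "spike_train"))
  if (is.null(stim_onset))
    stim_onset <- if (!is.null(train$stimulus)) train$stimulus$onset else 0
  after <- train$times[train$times >= stim_onset]
  if (length(after) == 0L)
    return(structure(list(latency = NA_real_, spike_found = FALSE),
                     class = "latency_result"))
  structure(list(latency = after[1L] - stim_onset, spike_found = TRUE),
            class = "latency_result")
}
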