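# Extraction of per-terminal measurements from A-scan traces: the first
# peak (primary pulse: delivered voltage + propagation time) and the full
# echo train of reflection arrivals.

# Plateau-aware local maxima of a non-negative series. A "peak" is a run of
# equal values strictly greater than both neighbouring runs (trace edges
# count as -Inf). Returns the index of the first sample of each peak run.
local_maxima_runs <- function(a) {
  r <- rle(a)
  vals <- r$values
  n <- length(vals)
  if (n == 0L) return(integer(0))
  prev <- c(-Inf, vals[-n])
  nxt <- c(vals[-1L], -Inf)
  is_peak <- vals > prev & vals > nxt
  starts <- cumsum(c(1L, r$lengths[-n]))
  starts[is_peak]
}

no_arrival <- function(trace) {
  structure(list(node = trace$node, label = trace$label,
                 detected = FALSE, arrival_time = NA_real_,
                 amplitude = NA_real_, peak_index = NA_integer_),
            class = "peak_measurement")
}

#' First-peak measurement of an A-scan trace
#'
#' Locates the primary pulse: the first local maximum of `|voltage|`
#' exceeding the noise floor. A peak is a sample-level local maximum; a
#' flat-topped (rectangular) pulse counts once, and the reported arrival
#' time is the time of its first sample — the onset of the plateau. The
#' amplitude is the signed voltage at that sample (detection uses the
#' absolute value).
#'
#' If no sample exceeds the noise floor the result is an explicit
#' "no arrival" measurement (`detected = FALSE`), not an error.
#'
#' @param trace An [ascan_trace()].
#' @param noise_floor Detection threshold in volts (`>= 0`). A common
#'   choice is `1e-6 *` source amplitude.
#' @return An object of class `peak_measurement` with fields `detected`,
#'   `arrival_time` (s), `amplitude` (V, signed), `peak_index`.
#' @export
first_peak <- function(trace, noise_floor = 0) {
  stopifnot(inherits(trace, "ascan_trace"))
  if (!is.numeric(noise_floor) || length(noise_floor) != 1L ||
      !is.finite(noise_floor) || noise_floor < 0) {
    stop("`noise_floor` must be a single number >= 0", call. = FALSE)
  }
  a <- abs(trace$voltages)
  peaks <- local_maxima_runs(a)
  peaks <- peaks[a[peaks] > noise_floor]
  if (!length(peaks)) return(no_arrival(trace))
  i <- peaks[1L]
  structure(list(node = trace$node, label = trace$label, detected = TRUE,
                 arrival_time = trace$times[i],
                 amplitude = trace$voltages[i], peak_index = i),
            class = "peak_measurement")
}

#' @export
print.peak_measurement <- function(x, ...) {
  if (!x$detected) {
    cat(sprintf("<peak_measurement> %s: no arrival above noise floor\n",
                x$label))
  } else {
    cat(sprintf("<peak_measurement> %s: t = %.4f us, v = %.4g mV\n",
                x$label, x$arrival_time * 1e6, x$amplitude * 1e3))
  }
  invisible(x)
}

#' Echo train of an A-scan trace
#'
#' All local maxima of `|voltage|` above the noise floor, in time order,
#' thinned so consecutive reported peaks are separated by at least
#' `min_separation` (earlier peaks win; a sensible separation is the pulse
#' width). The first element equals [first_peak()] of the same trace.
#'
#' @inheritParams first_peak
#' @param min_separation Minimum time between reported peaks (seconds); at
#'   least the trace's sampling step.
#' @return An object of class `echo_train`: a data.frame with columns
#'   `arrival_time`, `amplitude`, `peak_index` sorted by strictly
#'   increasing arrival time (zero rows if nothing exceeds the floor).
#' @export
echo_train <- function(trace, noise_floor = 0, min_separation = NULL) {
  stopifnot(inherits(trace, "ascan_trace"))
  dt <- trace$times[2] - trace$times[1]
  if (is.null(min_separation)) min_separation <- dt
  if (min_separation < dt) {
    stop("`min_separation` must be at least the trace time step",
         call. = FALSE)
  }
  a <- abs(trace$voltages)
  peaks <- local_maxima_runs(a)
  peaks <- peaks[a[peaks] > noise_floor]
  keep <- integer(0)
  last_t <- -Inf
  for (i in peaks) {
    t_i <- trace$times[i]
    if (t_i - last_t >= min_separation) {
      keep <- c(keep, i)
      last_t <- t_i
    }
  }
  out <- data.frame(arrival_time = trace$times[keep],
                    amplitude = trace$voltages[keep],
                    peak_index = keep)
  attr(out, "node") <- trace$node
  attr(out, "label") <- trace$label
  class(out) <- c("echo_train", class(out))
  out
}
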