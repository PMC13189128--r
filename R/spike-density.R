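## Spike-density estimation with the forward ("EPSP") kernel
##   K(t) = A (1 - exp(-t/growth)) exp(-t/decay), t >= 0;  A: unit area.
## Each spike influences only forward in time; convolution conserves spike
## count. All rate analyses read from this front end.

#' Kernel parameters
#'
#' @param growth_tau Growth time constant (ms), default 1.
#' @param decay_tau Decay time constant (ms), default 20.
#' @return List of class `"kernel_params"`.
#' @export
kernel_params <- function(growth_tau = 1, decay_tau = 20) {
  if (!is.numeric(growth_tau) || growth_tau <= 0 ||
      !is.numeric(decay_tau) || decay_tau <= 0)
    stop("kernel time constants must be positive", call. = FALSE)
  structure(list(growth_tau = growth_tau, decay_tau = decay_tau),
            class = "kernel_params")
}

# unit-area normalization constant: integral of the unnormalized kernel
.kernel_area <- function(p) {
  g <- p$growth_tau; d <- p$decay_tau
  d - g * d / (g + d)
}

#' Evaluate the EPSP kernel on a time grid
#'
#' @param params [kernel_params()].
#' @param t_grid Times (ms); the kernel is zero for negative times.
#' @return Kernel values normalized to unit area (per ms).
#' @export
epsp_kernel <- function(params = kernel_params(), t_grid) {
  g <- params$growth_tau; d <- params$decay_tau
  k <- ifelse(t_grid < 0, 0, (1 - exp(-t_grid / g)) * exp(-t_grid / d))
  k / .kernel_area(params)
}

# cumulative kernel integral from 0 to x (vectorized, exact); C(Inf) = 1
.kernel_cumint <- function(params, x) {
  g <- params$growth_tau; d <- params$decay_tau
  gd <- g * d / (g + d)
  x <- pmax(x, 0)
  (d * (1 - exp(-x / d)) - gd * (1 - exp(-x * (1 / gd)))) / .kernel_area(params)
}

#' Spike-density function on a 1-ms grid
#'
#' `rate(t) = sum_spikes K(t - t_spike) * 1000` in spikes/s. The default
#' `"direct"` method evaluates the kernel at every (grid, spike) shift
#' exactly; the `"fft"` method computes the same lattice convolution via the
#' FFT and requires (or quantizes to) grid-aligned spike times.
#'
#' @param spikes Sorted numeric spike times (ms).
#' @param window `c(t0, t1)` evaluation window (ms). Spikes before `t0`
#'   still contribute causally.
#' @param params [kernel_params()].
#' @param step Grid step (ms), default 1.
#' @param method `"direct"` or `"fft"`.
#' @return Object of class `"rate_trace"`: list with `times`, `rate`
#'   (spikes/s), `normalized = FALSE`.
#' @export
convolve_density <- function(spikes, window, params = kernel_params(),
                             step = 1, method = c("direct", "fft")) {
  method <- match.arg(method)
  if (is.unsorted(spikes)) stop("spikes must be sorted", call. = FALSE)
  times <- seq(window[1], window[2], by = step)
  if (length(spikes) == 0)
    return(structure(list(times = times, rate = numeric(length(times)),
                          normalized = FALSE), class = "rate_trace"))
  if (method == "direct") {
    rate <- numeric(length(times))
    # block over spikes to bound memory on long trains
    idx <- split(seq_along(spikes), ceiling(seq_along(spikes) / 2000))
    for (ii in idx) {
      dt <- outer(times, spikes[ii], "-")
      rate <- rate + rowSums(matrix(epsp_kernel(params, dt), nrow = length(times)))
    }
    rate <- rate * 1000
  } else {
    snapped <- round((spikes - window[1]) / step) * step + window[1]
    if (max(abs(snapped - spikes)) > 1e-9)
      warning("fft method: spike times quantized to the evaluation grid",
              call. = FALSE)
    t0 <- min(snapped[1], window[1])
    grid <- seq(t0, window[2], by = step)
    counts <- tabulate(round((snapped - t0) / step) + 1L, nbins = length(grid))
    klen <- ceiling(50 * params$decay_tau / step)
    kern <- epsp_kernel(params, seq(0, by = step, length.out = klen))
    n <- length(grid) + klen - 1L
    nfft <- stats::nextn(n, 2)
    conv <- Re(stats::fft(stats::fft(c(counts, numeric(nfft - length(grid)))) *
                            stats::fft(c(kern, numeric(nfft - klen))),
                          inverse = TRUE)) / nfft
    full <- conv[seq_along(grid)] * 1000
    rate <- full[round((times - t0) / step) + 1L]
  }
  structure(list(times = times, rate = pmax(rate, 0), normalized = FALSE),
            class = "rate_trace")
}

#' Exact time-averaged spike density over a window
#'
#' Uses the closed-form kernel integral, so
#' `window_mean_rate(spikes, c(a, b)) * (b - a) / 1000` is exactly the
#' kernel mass falling in the window (spike count for a window covering the
#' whole train plus its tail).
#'
#' @param spikes Numeric spike times (ms).
#' @param window `c(a, b)` in ms.
#' @param params [kernel_params()].
#' @return Mean rate in spikes/s.
#' @export
window_mean_rate <- function(spikes, window, params = kernel_params()) {
  if (length(spikes) == 0) return(0)
  mass <- sum(.kernel_cumint(params, window[2] - spikes) -
                .kernel_cumint(params, window[1] - spikes))
  1000 * mass / (window[2] - window[1])
}

#' Event-aligned window-mean rates
#'
#' @param spikes Spike times (ms, trial clock).
#' @param align_times Event times (ms) to align to.
#' @param window `c(a, b)` relative to each event.
#' @param params [kernel_params()].
#' @return Numeric vector, one mean rate (spikes/s) per event.
#' @export
aligned_window_means <- function(spikes, align_times, window,
                                 params = kernel_params()) {
  vapply(align_times, function(t0)
    window_mean_rate(spikes, t0 + window, params), numeric(1))
}

#' Per-unit baseline rate
#'
#' Mean spike density during the fixation-spot epoch preceding the cue
#' (window relative to cue onset), averaged across trials.
#'
#' @param unit A [unit_record()].
#' @param trials List of [trial_record()]s.
#' @param window Baseline window relative to cue onset, default
#'   `c(-150, 0)` ms.
#' @param params [kernel_params()].
#' @return Scalar baseline rate (spikes/s).
#' @export
unit_baseline <- function(unit, trials, window = c(-150, 0),
                          params = kernel_params()) {
  r <- vapply(trials, function(tr) {
    sp <- unit$spikes[[as.character(tr$trial_id)]]
    window_mean_rate(sp, tr$events$cue_on + window, params)
  }, numeric(1))
  mean(r)
}

#' Normalize a rate trace by a baseline rate
#'
#' Division (not subtraction) by the unit's mean baseline rate is the
#' convention: normalized traces are unitless multiples of baseline. A unit
#' with zero baseline cannot be normalized; the trace is returned unchanged
#' with an `excluded` flag so downstream population matrices can omit it.
#'
#' @param trace A `"rate_trace"` from [convolve_density()].
#' @param baseline Scalar baseline rate (spikes/s), e.g. [unit_baseline()].
#' @return The trace with `rate` divided by baseline and
#'   `normalized = TRUE`, or flagged `excluded` when baseline is zero.
#' @export
normalize_baseline <- function(trace, baseline) {
  if (trace$normalized) stop("trace already normalized", call. = FALSE)
  if (!is.finite(baseline) || baseline <= 0) {
    trace$excluded <- TRUE
    message("normalize_baseline: zero/invalid baseline; unit flagged for exclusion")
    return(trace)
  }
  trace$rate <- trace$rate / baseline
  trace$normalized <- TRUE
  trace$excluded <- FALSE
  trace
}
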