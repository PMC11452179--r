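## Calcium-trace preprocessing and quality/inclusion filtering.

#' Detrend and normalise a raw calcium trace
#'
#' Removes slow drift with a Savitzky-Golay filter (third polynomial order,
#' 60 s window by default), clips the detrended trace below its 2.5th
#' percentile and subtracts that percentile so the trace is non-negative,
#' then divides by the SD of the pre-stimulus segment (samples before `t0`).
#'
#' @param raw raw trace (numeric vector)
#' @param sampling_rate trace sampling rate in Hz
#' @param window_s Savitzky-Golay window length in seconds
#' @param poly_order Savitzky-Golay polynomial order
#' @param t0 stimulus-start sample index (> 1); samples before `t0` form the
#'   baseline window for SD normalisation
#' @return object of class `detrended_trace` with `values`, the removed
#'   percentile offset `eta_2_5`, `baseline_sd`, `t0`, and the filter settings
#'   recorded as provenance
#' @export
detrend_trace <- function(raw, sampling_rate = TRACE_RATE, window_s = 60,
                          poly_order = 3L, t0) {
  stopifnot(t0 > 1, t0 <= length(raw))
  if (sd(raw) == 0)
    stop("degenerate trace: input is constant")
  n <- round(window_s * sampling_rate)
  if (n %% 2 == 0) n <- n + 1L          # sgolay needs an odd window
  if (n >= length(raw))
    stop("trace shorter than the detrending window")
  smooth <- signal::sgolayfilt(raw, p = poly_order, n = n)
  detrended <- raw - smooth
  eta <- as.numeric(quantile(detrended, 0.025, type = 7))
  cpos <- pmax(detrended, eta) - eta
  bsd <- sd(cpos[seq_len(t0 - 1L)])
  if (!is.finite(bsd) || bsd == 0)
    stop("degenerate trace: zero pre-stimulus SD")
  out <- list(values = cpos / bsd, eta_2_5 = eta, baseline_sd = bsd, t0 = t0,
              window_s = window_s, poly_order = poly_order,
              sampling_rate = sampling_rate)
  class(out) <- "detrended_trace"
  out
}

#' Estimate firing rates from a trace
#'
#' The external spike-inference step is replaced by a documented stand-in:
#' either ground-truth passthrough (for pipeline tests) or a non-negative
#' first-order deconvolution assuming an exponential calcium kernel
#' (`r_t = max(0, c_t - gamma c_(t-1))` with `gamma = exp(-1/(tau * rate))`).
#' Rates are linearly interpolated from the trace rate (7.8125 Hz) to the
#' stimulus rate (30 Hz).
#'
#' @param trace a `detrended_trace`, or a numeric vector at `trace_rate`
#' @param method "nonneg_deconvolution" or "ground_truth_passthrough"
#' @param calcium_tau assumed calcium decay (s) for deconvolution
#' @param ground_truth 30 Hz ground-truth rate vector (passthrough method)
#' @param trace_rate,target_rate sampling rates in Hz
#' @param n_out output length in samples; pads by constant extrapolation at
#'   the edges (default: full trace duration at `target_rate`)
#' @return non-negative rate vector at `target_rate`
#' @export
infer_rates <- function(trace,
                        method = c("nonneg_deconvolution",
                                   "ground_truth_passthrough"),
                        calcium_tau = 1.0, ground_truth = NULL,
                        trace_rate = TRACE_RATE, target_rate = FRAME_RATE,
                        n_out = NULL) {
  method <- match.arg(method)
  if (method == "ground_truth_passthrough") {
    if (is.null(ground_truth)) stop("passthrough needs ground_truth rates")
    return(pmax(ground_truth, 0))
  }
  v <- if (inherits(trace, "detrended_trace")) trace$values else trace
  gam <- exp(-1 / (calcium_tau * trace_rate))
  r <- pmax(v - gam * c(0, v[-length(v)]), 0)
  tt_in <- (seq_along(r) - 1L) / trace_rate
  if (is.null(n_out))
    n_out <- floor(tt_in[length(tt_in)] * target_rate) + 1L
  tt_out <- (seq_len(n_out) - 1L) / target_rate
  pmax(stats::approx(tt_in, r, xout = tt_out, rule = 2)$y, 0)
}

#' Response quality index
#'
#' `QI = Var_t[ mean_i r ] / mean_i[ Var_t r ]` for a T x I response matrix
#' (time samples by stimulus repetitions). Identical repeats give 1; iid
#' noise repeats give about 1/I.
#'
#' @param response_matrix numeric matrix `[T x I]`, `I >= 2`, `T >= 2`
#' @return scalar in \[0, 1\] (0 with a warning for flat responses)
#' @export
quality_index <- function(response_matrix) {
  stopifnot(is.matrix(response_matrix), ncol(response_matrix) >= 2,
            nrow(response_matrix) >= 2)
  denom <- mean(apply(response_matrix, 2, var))
  if (denom == 0) {
    warning("flat responses: QI undefined, returning 0")
    return(0)
  }
  min(var(rowMeans(response_matrix)) / denom, 1)
}

#' Default inclusion-filter thresholds
#'
#' Step 1: reliable response, `QI_MB > 0.6` OR `QI_chirp > 0.35`. Steps 2-3:
#' classifier confidence `>= 0.25`. Step 4: mean single-trial test correlation
#' `> 0.3`. MEI-property step: DoG fit cost `< 0.11` in both channels.
#' @return named list of thresholds
#' @export
inclusion_thresholds <- function() {
  list(qi_mb = 0.6, qi_chirp = 0.35, confidence = 0.25,
       test_corr = 0.3, dog_cost = 0.11)
}

#' Apply the sequential inclusion filters to a quality report
#'
#' @param report data.frame with one row per neuron and columns among
#'   `qi_mb`, `qi_chirp`, `classifier_confidence`, `test_corr_single_trial`,
#'   `dog_cost_green`, `dog_cost_uv`
#' @param thresholds as from [inclusion_thresholds()]
#' @param steps which steps to apply (1:4 plus the DoG-cost step 5); masks
#'   are cumulative, so step k includes only cells passing steps < k
#' @return logical matrix `[neuron x step]` of cumulative inclusion masks
#' @export
apply_inclusion_filters <- function(report,
                                    thresholds = inclusion_thresholds(),
                                    steps = 1:5) {
  need <- list(`1` = c("qi_mb", "qi_chirp"),
               `2` = "classifier_confidence",
               `3` = "classifier_confidence",
               `4` = "test_corr_single_trial",
               `5` = c("dog_cost_green", "dog_cost_uv"))
  n <- nrow(report)
  masks <- matrix(TRUE, n, length(steps),
                  dimnames = list(NULL, paste0("step", steps)))
  acc <- rep(TRUE, n)
  for (j in seq_along(steps)) {
    s <- steps[j]
    miss <- setdiff(need[[as.character(s)]], names(report))
    if (length(miss))
      stop("step ", s, " needs report column(s): ",
           paste(miss, collapse = ", "))
    pass <- switch(as.character(s),
      `1` = report$qi_mb > thresholds$qi_mb |
            report$qi_chirp > thresholds$qi_chirp,
      `2` = report$classifier_confidence >= thresholds$confidence,
      `3` = report$classifier_confidence >= thresholds$confidence,
      `4` = report$test_corr_single_trial > thresholds$test_corr,
      `5` = report$dog_cost_green < thresholds$dog_cost &
            report$dog_cost_uv < thresholds$dog_cost)
    pass[is.na(pass)] <- FALSE
    acc <- acc & pass
    masks[, j] <- acc
  }
  masks
}

#' Build a quality report for a simulated recording
#'
#' Stand-in for the chirp/moving-bar quality metrics: both QIs are computed
#' from the repeated test-sequence responses (the synthetic recording's only
#' repeated segment). Classifier confidence is a stand-in drawn from the
#' ground-truth family labels (the external type classifier is out of scope),
#' set to 1 by default.
#'
#' @param pack a `response_pack`
#' @param confidence classifier-confidence stand-in (scalar or per cell)
#' @return data.frame, one row per neuron
#' @export
quality_report <- function(pack, confidence = 1) {
  N <- dim(pack$test_repeats)[1]
  qi <- vapply(seq_len(N), function(n)
    quality_index(t(pack$test_repeats[n, , ])), numeric(1))
  data.frame(cell_id = seq_len(N),
             family = vapply(pack$ground_truth, function(c) c$family, ""),
             qi_mb = qi, qi_chirp = qi,
             classifier_confidence = rep(confidence, length.out = N),
             test_corr_single_trial = NA_real_,
             dog_cost_green = NA_real_, dog_cost_uv = NA_real_)
}
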