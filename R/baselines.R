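#' Minimum norm estimate (MNE)
#'
#' Tikhonov-regularised minimum-norm solution
#' x_hat = H' (H H' + reg I)^{-1} y, the classical baseline for the
#' under-determined EEG inverse problem. With `reg = NULL` the
#' regularisation defaults to trace(H H') / (N * snr_power), tying the
#' ridge strength to an assumed sensor SNR.
#'
#' @param leadfield Lead field (object or matrix).
#' @param y Sensor data (vector or `eeg_measurement`).
#' @param reg Nonnegative ridge parameter; `NULL` for the SNR-based default.
#' @param snr_power Assumed signal-to-noise power ratio used by the default
#'   rule (default 100, i.e. 20 dB).
#' @return Numeric length-K estimate x_hat.
#' @export
mne_solve <- function(leadfield, y, reg = NULL, snr_power = 100) {
  H <- leadfield_matrix(leadfield)
  if (inherits(y, "eeg_measurement")) y <- y$y
  G <- tcrossprod(H)                      # N x N Gram matrix
  if (is.null(reg)) reg <- sum(diag(G)) / (nrow(H) * snr_power)
  if (reg < 0) stop("'reg' must be >= 0")
  drop(crossprod(H, solve(G + diag(reg, nrow(H)), y)))
}

#' Standard sparse Bayesian learner (RVM-VB)
#'
#' The classical Gaussian-Gamma relevance-vector-machine solver estimated by
#' variational Bayes: exactly the [run_fan()] cycle with the lambda weights
#' fixed at 1 (no reweighting). Shares all code paths with [run_fan()].
#'
#' @param leadfield Lead field (object or matrix).
#' @param y Sensor data (vector or `eeg_measurement`).
#' @param config A [solver_config()]; its `lam_mode` is overridden to
#'   `"fixed_ones"`.
#' @return A `vb_state`.
#' @export
rvm_vb_solve <- function(leadfield, y, config = solver_config()) {
  config$lam_mode <- "fixed_ones"
  run_fan(leadfield, y, config)
}
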