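#' Build a Gaussian spatial smoothing kernel
#'
#' The kernel Psi has unit diagonal and off-diagonal entries
#' psi_ij = exp(-r d_ij^2), where d_ij is the distance between sources i and
#' j in mm and r (1/mm^2) controls the spatial extent: large r approaches the
#' identity (no smoothing), small r couples distant sources. In
#' free-orientation mode each Cartesian component is smoothed independently
#' (component c of source i couples only to component c of source j),
#' preserving dipole direction fields.
#'
#' @param source_space A [make_source_space()] object.
#' @param r Spatial decay rate in 1/mm^2 (>= 0; but see `min_condition`).
#' @param leadfield Optional lead field (for the columns-per-source factor).
#' @param truncate Entries below this value are set to exact zero
#'   (default 1e-6), making far-field coupling exactly sparse; use 0 for the
#'   dense exact kernel.
#' @param min_condition Guard: an error is raised when the reciprocal
#'   condition number of the source-level kernel falls below this value
#'   (default 1e-12), e.g. for r close to 0 where Psi approaches the singular
#'   all-ones matrix.
#' @return Object of class `smoothing_kernel`: `psi` (K x K), `psi_src`
#'   (M x M source-level kernel), `r`, `kappa`.
#' @export
build_kernel <- function(source_space, r, leadfield = NULL,
                         truncate = 1e-6, min_condition = 1e-12) {
  if (!is.numeric(r) || length(r) != 1L || r < 0)
    stop("'r' must be a nonnegative scalar")
  kappa <- if (!is.null(leadfield)) leadfield$columns_per_source
           else if (source_space$orientation_mode == "fixed") 1L else 3L
  D <- source_distances(source_space)
  psi <- exp(-r * D^2)
  diag(psi) <- 1
  if (truncate > 0) psi[psi < truncate] <- 0
  rc <- rcond(psi)
  if (rc < min_condition)
    stop(sprintf(paste0("smoothing kernel is numerically singular ",
                        "(rcond %.2e < %.0e); increase r"), rc, min_condition))
  psi_full <- if (kappa == 1L) psi else expand_kernel(psi, kappa)
  structure(list(psi = psi_full, psi_src = psi, r = r, kappa = kappa,
                 distances = D),
            class = "smoothing_kernel")
}

# interleave: component c of source i couples to component c of source j
expand_kernel <- function(psi, kappa) {
  m <- nrow(psi)
  K <- kappa * m
  out <- matrix(0, K, K)
  for (cc in seq_len(kappa)) {
    ii <- seq(cc, K, by = kappa)
    out[ii, ii] <- psi
  }
  out
}

#' Transform a lead field into the smoothed (psi) domain
#'
#' Returns H_psi = H Psi, the lead field seen by the sparse coefficients z
#' with x = Psi z. The result is tagged `psi_domain` so that downstream
#' estimates are back-projected before being interpreted as source
#' amplitudes.
#'
#' @param leadfield A [make_leadfield()] object.
#' @param kernel A [build_kernel()] object.
#' @return A `leadfield` whose `matrix` is H Psi, with `psi_domain = TRUE`.
#' @export
transform_leadfield <- function(leadfield, kernel) {
  H <- leadfield$matrix
  if (ncol(H) != ncol(kernel$psi))
    stop("kernel dimension ", ncol(kernel$psi),
         " does not match lead field columns ", ncol(H))
  out <- leadfield
  out$matrix <- H %*% kernel$psi
  out$psi_domain <- TRUE
  out
}

#' Back-project a psi-domain estimate to source space
#'
#' x_hat = Psi z_hat: a single nonzero coefficient z_j spreads into a
#' spatial bump centred at source j with a Gaussian-in-squared-distance
#' profile.
#'
#' @param z_hat Psi-domain coefficient vector (length K).
#' @param kernel The [build_kernel()] used for the transform.
#' @return Source-domain vector x_hat.
#' @export
backproject <- function(z_hat, kernel) {
  if (length(z_hat) != ncol(kernel$psi))
    stop("'z_hat' length does not match kernel dimension")
  drop(kernel$psi %*% z_hat)
}

#' Run the smoothed-lead-field solver (FanSmooth)
#'
#' Runs the sparse VB solver on H_psi = H Psi, where Psi is the Gaussian
#' spatial kernel with decay rate `r`, then back-projects the sparse
#' psi-domain solution z_hat to the spatially extended source estimate
#' x_hat = Psi z_hat.
#'
#' @param leadfield A [make_leadfield()] object.
#' @param y Sensor data (vector or `eeg_measurement`).
#' @param r Spatial decay rate (1/mm^2); default 0.05.
#' @param config A [solver_config()].
#' @param kernel Optionally a prebuilt [build_kernel()] (overrides `r`).
#' @return List with `state` (psi-domain `vb_state`), `z_hat`, `x_hat`
#'   (back-projected), `amplitude_map` (per-source magnitudes of x_hat),
#'   `kernel`.
#' @export
run_fansmooth <- function(leadfield, y, r = 0.05, config = solver_config(),
                          kernel = NULL) {
  if (is.null(kernel))
    kernel <- build_kernel(leadfield$source_space, r, leadfield)
  H_psi <- transform_leadfield(leadfield, kernel)
  state <- run_fan(H_psi, y, config)
  z_hat <- state$x_hat
  x_hat <- backproject(z_hat, kernel)
  list(state = state, z_hat = z_hat, x_hat = x_hat,
       amplitude_map = amplitude_map(x_hat, leadfield),
       kernel = kernel)
}

#' @export
print.smoothing_kernel <- function(x, ...) {
  cat(sprintf("Smoothing kernel: %d x %d, r = %g /mm^2, %.1f%% nonzero\n",
              nrow(x$psi), ncol(x$psi), x$r, 100 * mean(x$psi != 0)))
  invisible(x)
}
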