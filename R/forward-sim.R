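#' Simulate a sparse activation scene
#'
#' Draws `n_active` active dipoles uniformly without replacement (optionally
#' enforcing a minimum pairwise separation) and samples their amplitudes from
#' a standard normal distribution — one draw per active source in fixed
#' orientation mode, three (one per Cartesian component) in free mode. All
#' other entries of the amplitude vector are exactly zero.
#'
#' @param source_space A [make_source_space()] object.
#' @param n_active Number of active dipoles (1..M).
#' @param amplitude_seed Integer seed; locations and amplitudes are
#'   deterministic given the seed.
#' @param min_separation Minimum pairwise distance (mm) between active
#'   dipoles; 0 disables the constraint.
#' @param max_tries Rejection-sampling retry bound for the separation
#'   constraint.
#' @return Object of class `activation_scene`: `active_indices` (sorted),
#'   `amplitudes` (length K = M or 3M), `truth_positions` (rows of active
#'   dipole positions, mm).
#' @export
simulate_scene <- function(source_space, n_active, amplitude_seed = 1L,
                           min_separation = 0, max_tries = 1000L) {
  m <- n_sources(source_space)
  if (!is.numeric(n_active) || n_active < 1 || n_active > m)
    stop("'n_active' must be between 1 and the number of sources")
  if (min_separation < 0) stop("'min_separation' must be >= 0")
  n_active <- as.integer(n_active)
  kappa <- if (source_space$orientation_mode == "fixed") 1L else 3L

  set.seed(amplitude_seed)
  pos <- source_space$positions
  idx <- NULL
  for (try in seq_len(max_tries)) {
    cand <- sort(sample.int(m, n_active))
    if (n_active == 1L || min_separation == 0 ||
        min(stats::dist(pos[cand, , drop = FALSE])) >= min_separation) {
      idx <- cand
      break
    }
  }
  if (is.null(idx))
    stop("infeasible scene: could not place ", n_active,
         " sources with separation >= ", min_separation, " mm")

  amplitudes <- numeric(kappa * m)
  for (j in idx) {
    cols <- (kappa * (j - 1L) + 1L):(kappa * j)
    amplitudes[cols] <- stats::rnorm(kappa)
  }

  structure(list(active_indices = idx,
                 amplitudes = amplitudes,
                 truth_positions = pos[idx, , drop = FALSE]),
            class = "activation_scene")
}

#' Project a scene through a lead field (noise-free forward model)
#'
#' Computes the sensor potentials y = H x for the scene's amplitude vector.
#'
#' @param leadfield A [make_leadfield()] object.
#' @param scene An [simulate_scene()] object (or any list with an
#'   `amplitudes` vector of matching length).
#' @return Object of class `eeg_measurement`: `y` (length N), `snr_db = Inf`,
#'   `noise_seed = NA`.
#' @export
project <- function(leadfield, scene) {
  x <- scene$amplitudes
  if (length(x) != ncol(leadfield$matrix))
    stop("scene amplitude length ", length(x),
         " does not match lead field columns ", ncol(leadfield$matrix))
  y <- drop(leadfield$matrix %*% x)
  structure(list(y = y, snr_db = Inf, noise_seed = NA_integer_),
            class = "eeg_measurement")
}

#' Add white Gaussian noise at an exact signal-to-noise ratio
#'
#' Draws white Gaussian noise and rescales the realized draw so that the
#' power ratio 10 log10(||y_clean||^2 / ||e||^2) equals `snr_db` exactly
#' (exact-realization calibration), making noisy measurements fully
#' deterministic given the seed. `snr_db = Inf` returns the clean signal.
#'
#' @param y_clean Numeric clean sensor vector, or an `eeg_measurement`.
#' @param snr_db Target SNR in dB (power convention); `Inf` for noise-free.
#' @param seed Integer noise seed.
#' @return `eeg_measurement` with the noisy `y` and the configured `snr_db`.
#' @export
add_noise_snr <- function(y_clean, snr_db, seed = 1L) {
  if (inherits(y_clean, "eeg_measurement")) y_clean <- y_clean$y
  if (is.infinite(snr_db))
    return(structure(list(y = y_clean, snr_db = Inf, noise_seed = NA_integer_),
                     class = "eeg_measurement"))
  sig_pow <- sum(y_clean^2)
  if (sig_pow == 0)
    stop("cannot calibrate noise for an all-zero clean signal at finite SNR")
  set.seed(seed)
  e <- stats::rnorm(length(y_clean))
  target_pow <- sig_pow / 10^(snr_db / 10)
  e <- e * sqrt(target_pow / sum(e^2))
  structure(list(y = y_clean + e, snr_db = snr_db,
                 noise_seed = as.integer(seed)),
            class = "eeg_measurement")
}

#' Realized SNR of a noisy measurement
#'
#' @param y_clean Clean sensor vector.
#' @param y_noisy Noisy sensor vector (same length).
#' @return Realized SNR in dB, 10 log10(||y_clean||^2 / ||y_noisy-y_clean||^2).
#' @export
realized_snr_db <- function(y_clean, y_noisy) {
  10 * log10(sum(y_clean^2) / sum((y_noisy - y_clean)^2))
}

#' One-call synthetic inverse problem
#'
#' Convenience wrapper: source space + lead field + scene + (optionally
#' noisy) measurement, with per-component seeds derived from one seed.
#'
#' @param n_channels Electrodes N.
#' @param m Sources M.
#' @param n_active Active dipoles.
#' @param snr_db SNR in dB (`Inf` = noise-free).
#' @param seed Master seed.
#' @param layout,orientation_mode,model,spacing,min_separation Passed through
#'   to the generators.
#' @return List with `source_space`, `leadfield`, `scene`, `measurement`,
#'   `clean` (noise-free measurement), and the seeds used.
#' @export
simulate_problem <- function(n_channels = 32, m = 300, n_active = 1,
                             snr_db = Inf, seed = 1L,
                             layout = "cube_grid",
                             orientation_mode = "fixed",
                             model = "random_gaussian",
                             spacing = 10, min_separation = 0) {
  seeds <- derive_seeds(seed, 3L)
  ss <- make_source_space(m, layout, spacing, orientation_mode,
                          seed = seeds[1])
  lf <- make_leadfield(ss, n_channels, model, seed = seeds[1])
  scene <- simulate_scene(ss, n_active, amplitude_seed = seeds[2],
                          min_separation = min_separation)
  clean <- project(lf, scene)
  meas <- add_noise_snr(clean, snr_db, seed = seeds[3])
  list(source_space = ss, leadfield = lf, scene = scene,
       measurement = meas, clean = clean, seeds = seeds)
}

# Deterministic stream of sub-seeds below 2^31 from one master seed.
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
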