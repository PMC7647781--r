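#' Construct a synthetic lead field
#'
#' Builds the propagation matrix H mapping dipole amplitudes to scalp
#' potentials. Two generative models are provided:
#'
#' * `"random_gaussian"`: entries i.i.d. standard normal, each column then
#'   scaled to unit Euclidean norm. Geometry-agnostic; makes solver
#'   comparisons independent of depth/conductivity effects.
#' * `"single_shell_sphere"`: analytic current-dipole potentials in a
#'   homogeneous conductor, evaluated at electrodes placed on an outer sphere
#'   enclosing the source space. Columns are deliberately NOT normalised, so
#'   deep sources produce weaker topographies (the depth bias that penalises
#'   minimum-norm solutions).
#'
#' In fixed-orientation mode the three Cartesian columns of each dipole are
#' first formed and then projected onto the dipole's unit orientation, giving
#' one column per source; in free mode all three columns are kept, ordered
#' `[x, y, z]` per dipole.
#'
#' @param source_space A [make_source_space()] object.
#' @param n_channels Number of electrodes N (>= 2).
#' @param model `"random_gaussian"` or `"single_shell_sphere"`.
#' @param seed Integer seed (Gaussian entries; electrode placement is
#'   deterministic).
#' @param average_reference If `TRUE`, subtract the mean across channels from
#'   every column (common average reference). Default `FALSE` (raw
#'   potentials).
#' @return Object of class `leadfield`: list with `matrix` (N x K), `channels`
#'   (labels), `source_space`, `columns_per_source` (1 fixed / 3 free).
#' @examples
#' ss <- make_source_space(27, "cube_grid", 10, "fixed", seed = 1)
#' lf <- make_leadfield(ss, 16, "random_gaussian", seed = 2)
#' dim(lf$matrix)
#' @export
make_leadfield <- function(source_space, n_channels,
                           model = c("random_gaussian", "single_shell_sphere"),
                           seed = 1L, average_reference = FALSE) {
  model <- match.arg(model)
  if (!inherits(source_space, "source_space"))
    stop("'source_space' must be a source_space object")
  if (!is.numeric(n_channels) || n_channels < 2)
    stop("'n_channels' must be >= 2")
  n <- as.integer(n_channels)
  m <- n_sources(source_space)
  kappa <- if (source_space$orientation_mode == "fixed") 1L else 3L

  if (model == "random_gaussian") {
    set.seed(seed)
    H <- matrix(stats::rnorm(n * kappa * m), n, kappa * m)
    H <- sweep(H, 2, sqrt(colSums(H^2)), "/")
  } else {
    H3 <- sphere_dipole_leadfield(source_space$positions, n)
    if (kappa == 1L) {
      # project the three Cartesian columns of each dipole onto its normal
      H <- matrix(0, n, m)
      for (j in seq_len(m)) {
        cols <- (3L * (j - 1L) + 1L):(3L * j)
        H[, j] <- H3[, cols, drop = FALSE] %*% source_space$orientations[j, ]
      }
    } else {
      H <- H3
    }
  }
  if (average_reference) H <- sweep(H, 2, colMeans(H), "-")
  if (any(colSums(H^2) == 0)) stop("lead field has an all-zero column")

  structure(list(matrix = H,
                 channels = sprintf("E%03d", seq_len(n)),
                 source_space = source_space,
                 columns_per_source = kappa,
                 psi_domain = FALSE),
            class = "leadfield")
}

# Potential of a unit current dipole in a homogeneous conductor,
# V(r_e) = m . (r_e - r_0) / (4 pi sigma |r_e - r_0|^3), evaluated at
# electrodes on a sphere with radius 1.2 x the outermost source.
# Returns N x 3M (Cartesian components per dipole).
sphere_dipole_leadfield <- function(positions, n_channels, sigma = 0.33) {
  r_src <- sqrt(rowSums(positions^2))
  radius <- 1.2 * max(max(r_src), 1)
  elec <- fibonacci_sphere(n_channels, radius)
  m <- nrow(positions)
  H <- matrix(0, n_channels, 3L * m)
  for (j in seq_len(m)) {
    d <- sweep(elec, 2, positions[j, ], "-")        # N x 3
    dist3 <- (sqrt(rowSums(d^2)))^3
    H[, (3L * (j - 1L) + 1L):(3L * j)] <- d / (4 * pi * sigma * dist3)
  }
  H
}

fibonacci_sphere <- function(n, radius) {
  i <- seq_len(n) - 0.5
  golden <- (1 + sqrt(5)) / 2
  phi <- acos(1 - 2 * i / n)
  theta <- 2 * pi * i / golden
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Evaluate homogeneous-conductor dipole potentials at given electrodes
#'
#' Direct evaluation of the analytic kernel used by the
#' `"single_shell_sphere"` lead-field model: useful as an independent check
#' of the assembled matrix.
#'
#' @param electrode Numeric length-3 electrode position (mm).
#' @param dipole_pos Numeric length-3 dipole position (mm).
#' @param moment Numeric length-3 dipole moment.
#' @param sigma Conductivity (S/m), default 0.33.
#' @return Scalar potential.
#' @export
dipole_potential <- function(electrode, dipole_pos, moment, sigma = 0.33) {
  d <- electrode - dipole_pos
  sum(moment * d) / (4 * pi * sigma * sum(d^2)^1.5)
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("Lead field: %d channels x %d columns (%d sources, %s orientation)%s\n",
              nrow(x$matrix), ncol(x$matrix), n_sources(x$source_space),
              x$source_space$orientation_mode,
              if (isTRUE(x$psi_domain)) " [psi-domain]" else ""))
  invisible(x)
}
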