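#' Construct a synthetic source space
#'
#' Builds a set of candidate dipole positions (in mm) on either a regular
#' cubic grid or a quasi-uniform spherical surface, together with the dipole
#' orientation mode. Fixed-orientation spaces carry one unit orientation per
#' source (outward radial normals on the sphere, seeded random unit vectors on
#' the grid, mimicking cortical-normal constraints); free-orientation spaces
#' leave the three components of every dipole unconstrained.
#'
#' @param m Number of candidate sources (dipoles), at least 1.
#' @param layout `"cube_grid"` (regular grid, volumetric-style) or
#'   `"sphere_surface"` (Fibonacci lattice on a sphere, cortical-sheet-style).
#' @param spacing Grid spacing in mm (cube layout; stored as metadata for the
#'   sphere layout, whose radius is chosen so that mean nearest-neighbour
#'   distance is close to `spacing`).
#' @param orientation_mode `"fixed"` or `"free"`.
#' @param seed Integer seed controlling the random orientations (cube grid,
#'   fixed mode). Positions are deterministic for a given geometry.
#' @return An object of class `source_space`: list with `positions` (m x 3
#'   matrix, mm), `orientation_mode`, `orientations` (m x 3 unit rows, fixed
#'   mode only), `grid_spacing`.
#' @examples
#' ss <- make_source_space(125, "cube_grid", spacing = 10,
#'                         orientation_mode = "free", seed = 1)
#' dim(ss$positions)
#' @export
make_source_space <- function(m,
                              layout = c("cube_grid", "sphere_surface"),
                              spacing = 10,
                              orientation_mode = c("fixed", "free"),
                              seed = 1L) {
  layout <- match.arg(layout)
  orientation_mode <- match.arg(orientation_mode)
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m))
    stop("'m' must be a positive integer")
  if (!is.numeric(spacing) || spacing <= 0)
    stop("'spacing' must be > 0")
  m <- as.integer(m)

  if (layout == "cube_grid") {
    side <- ceiling(m^(1 / 3) - 1e-9)
    ax <- (seq_len(side) - (side + 1) / 2) * spacing
    grid <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
    positions <- grid[seq_len(m), , drop = FALSE]
  } else {
    # Fibonacci lattice: near-uniform coverage of the sphere surface.
    # Radius set so the mean nearest-neighbour spacing approximates 'spacing':
    # area per point 4*pi*R^2/m ~ spacing^2.
    radius <- spacing * sqrt(m / (4 * pi))
    i <- seq_len(m) - 0.5
    golden <- (1 + sqrt(5)) / 2
    phi <- acos(1 - 2 * i / m)
    theta <- 2 * pi * i / golden
    positions <- radius * cbind(sin(phi) * cos(theta),
                                sin(phi) * sin(theta),
                                cos(phi))
  }
  dimnames(positions) <- list(NULL, c("x", "y", "z"))

  orientations <- NULL
  if (orientation_mode == "fixed") {
    if (layout == "sphere_surface") {
      nrm <- sqrt(rowSums(positions^2))
      orientations <- positions / nrm
    } else {
      set.seed(seed)
      v <- matrix(stats::rnorm(3 * m), m, 3)
      orientations <- v / sqrt(rowSums(v^2))
    }
    dimnames(orientations) <- list(NULL, c("x", "y", "z"))
  }

  structure(list(positions = positions,
                 orientation_mode = orientation_mode,
                 orientations = orientations,
                 grid_spacing = spacing),
            class = "source_space")
}

#' Number of sources in a source space
#' @param source_space A `source_space`.
#' @return Integer count of dipoles.
#' @export
n_sources <- function(source_space) nrow(source_space$positions)

#' Pairwise source distances
#'
#' Euclidean distances between all dipole positions, in mm.
#' @param source_space A `source_space`.
#' @return An M x M symmetric matrix.
#' @export
source_distances <- function(source_space) {
  unname(as.matrix(stats::dist(source_space$positions)))
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf("Source space: %d dipoles, %s orientation, spacing %g mm\n",
              n_sources(x), x$orientation_mode, x$grid_spacing))
  invisible(x)
}
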