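#' Reconstruction error
#'
#' ||x_est - x_true||^2 / ||x_true||^2: scale-sensitive energy mismatch
#' between the estimated and true source vectors. In free-orientation mode
#' both vectors are full 3M component vectors.
#'
#' @param x_est Estimated source vector.
#' @param x_true True source vector (not all-zero).
#' @return Nonnegative scalar (0 = perfect, 1 = as bad as the zero estimate).
#' @export
reconstruction_error <- function(x_est, x_true) {
  if (length(x_est) != length(x_true)) stop("length mismatch")
  denom <- sum(x_true^2)
  if (denom == 0) stop("'x_true' must not be all-zero")
  sum((x_est - x_true)^2) / denom
}

#' Localization error within a neighbourhood
#'
#' For each true source, restricts the candidate grid to sources within
#' `neighborhood_mm` (inclusive) of the true position, takes the candidate
#' with maximal estimated amplitude, and returns its distance to the true
#' position. Ties are broken towards the candidate nearest the true source;
#' if every candidate amplitude in the sphere is exactly zero the
#' neighbourhood radius is returned as a penalty.
#'
#' @param amplitude_map Length-M nonnegative magnitudes (see
#'   [amplitude_map()]).
#' @param source_space The candidate grid.
#' @param true_positions Matrix (or vector) of true source positions, one row
#'   per source, mm.
#' @param neighborhood_mm Search radius in mm (default 25).
#' @return List with `per_source` (mm, one per true source) and `mean` (mm).
#' @export
localization_error <- function(amplitude_map, source_space, true_positions,
                               neighborhood_mm = 25) {
  if (neighborhood_mm <= 0) stop("'neighborhood_mm' must be > 0")
  if (is.null(dim(true_positions)))
    true_positions <- matrix(true_positions, nrow = 1)
  pos <- source_space$positions
  per <- apply(true_positions, 1, function(tp) {
    d <- sqrt(colSums((t(pos) - tp)^2))
    cand <- which(d <= neighborhood_mm)
    if (length(cand) == 0)
      stop("no candidate sources within ", neighborhood_mm,
           " mm of a true source")
    amp <- amplitude_map[cand]
    if (all(amp == 0)) return(neighborhood_mm)
    best <- amp == max(amp)
    min(d[cand][best])                     # nearest among tied maxima
  })
  list(per_source = per, mean = mean(per))
}

#' Detection accuracy: hit rate, false-positive rate, and A'
#'
#' Declares a source detected when its amplitude reaches
#' `threshold_fraction` of the map maximum (default 0.1%). The hit rate H_R
#' is the fraction of true sources counted as hits; the false-positive rate
#' F_R is the fraction of non-true sources detected. A' = (H_R - F_R)/2 +
#' 1/2 approximates the area under the ROC curve.
#'
#' With `hit_rule = "neighborhood"` (default) a true source is a hit when
#' its own grid point is supra-threshold or any supra-threshold source lies
#' within one grid spacing of it; `"own_point"` requires the former.
#'
#' @param amplitude_map Length-M magnitudes.
#' @param truth An `activation_scene`, or an integer vector of true source
#'   indices.
#' @param source_space Needed for the neighbourhood hit rule (defaults to the
#'   strict rule when absent).
#' @param threshold_fraction Detection threshold as a fraction of the map
#'   maximum.
#' @param hit_rule `"neighborhood"` or `"own_point"`.
#' @return List with `h_r`, `f_r`, `a_prime`, `detected` (indices).
#' @export
a_prime <- function(amplitude_map, truth, source_space = NULL,
                    threshold_fraction = 0.001,
                    hit_rule = c("neighborhood", "own_point")) {
  hit_rule <- match.arg(hit_rule)
  true_idx <- if (inherits(truth, "activation_scene")) truth$active_indices
              else as.integer(truth)
  m <- length(amplitude_map)
  mx <- max(amplitude_map)
  if (mx == 0)
    return(list(h_r = 0, f_r = 0, a_prime = 0.5, detected = integer(0)))
  detected <- which(amplitude_map >= threshold_fraction * mx)

  if (hit_rule == "neighborhood" && !is.null(source_space) &&
      length(detected) > 0) {
    pos <- source_space$positions
    spacing <- source_space$grid_spacing
    hit <- vapply(true_idx, function(j) {
      if (j %in% detected) return(TRUE)
      dd <- sqrt(colSums((t(pos[detected, , drop = FALSE]) - pos[j, ])^2))
      any(dd <= spacing)
    }, logical(1))
  } else {
    hit <- true_idx %in% detected
  }
  h_r <- mean(hit)
  n_false <- m - length(true_idx)
  f_r <- if (n_false == 0) 0 else length(setdiff(detected, true_idx)) / n_false
  list(h_r = h_r, f_r = f_r, a_prime = (h_r - f_r) / 2 + 0.5,
       detected = detected)
}

#' Gini coefficient of an amplitude map
#'
#' Standard sparsity summary in [0, 1): 0 for a perfectly flat map, close to
#' 1 when all mass sits on one source. Used to compare the compactness of
#' solver outputs.
#'
#' @param x Nonnegative vector.
#' @return Scalar Gini coefficient.
#' @export
gini <- function(x) {
  x <- sort(abs(x))
  n <- length(x)
  s <- sum(x)
  if (s == 0) return(0)
  sum((2 * seq_len(n) - n - 1) * x) / (n * s)
}

#' Score one estimate against ground truth
#'
#' Bundles the three evaluation measures for a single solved instance.
#'
#' @param x_est Estimated source vector (length K).
#' @param scene The true `activation_scene`.
#' @param leadfield The lead field used.
#' @param neighborhood_mm,threshold_fraction Metric parameters.
#' @return Object of class `metrics_report`: `reconstruction_error`,
#'   `localization_error` (mean mm), `localization_per_source`, `h_r`,
#'   `f_r`, `a_prime`, `gini`.
#' @export
score_estimate <- function(x_est, scene, leadfield,
                           neighborhood_mm = 25, threshold_fraction = 0.001) {
  ss <- leadfield$source_space
  amap <- amplitude_map(x_est, leadfield)
  le <- localization_error(amap, ss, scene$truth_positions, neighborhood_mm)
  ap <- a_prime(amap, scene, ss, threshold_fraction)
  structure(list(
    reconstruction_error = reconstruction_error(x_est, scene$amplitudes),
    localization_error = le$mean,
    localization_per_source = le$per_source,
    h_r = ap$h_r, f_r = ap$f_r, a_prime = ap$a_prime,
    gini = gini(amap)), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("recon error %.4g | loc error %.2f mm | ",
                     "A' %.3f (H_R %.3f, F_R %.4f) | Gini %.3f\n"),
              x$reconstruction_error, x$localization_error,
              x$a_prime, x$h_r, x$f_r, x$gini))
  invisible(x)
}
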