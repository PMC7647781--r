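## Plain-text (JSON) containers. Matrices are stored row-major with 17
## significant digits, so round trips are exact to double precision.
## Variable names follow the documented convention: H (channels x columns,
## [x,y,z] columns per dipole in free mode), pos (M x 3 mm), ori (M x 3 unit
## rows, fixed mode), mode ("fixed"/"free").

write_container <- function(x, path, provenance = NULL) {
  txt <- jsonlite::toJSON(x, digits = I(17), auto_unbox = TRUE, null = "null")
  writeLines(txt, path)
  if (!is.null(provenance)) {
    ptxt <- jsonlite::toJSON(provenance, digits = I(17), auto_unbox = TRUE)
    writeLines(ptxt, paste0(path, ".prov.json"))
  }
  invisible(path)
}

read_container <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  jsonlite::fromJSON(readLines(path, warn = FALSE), simplifyVector = TRUE)
}

default_provenance <- function(...) {
  list(package = "vbsource",
       version = as.character(utils::packageVersion("vbsource")),
       r_version = R.version.string,
       created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       ...)
}

#' Write a lead field to a JSON container
#'
#' @param leadfield A [make_leadfield()] object.
#' @param path Output path.
#' @param provenance Optional named list written to a `.prov.json` sidecar.
#' @return The path, invisibly.
#' @export
write_leadfield <- function(leadfield, path,
                            provenance = default_provenance()) {
  ss <- leadfield$source_space
  write_container(list(
    format = "vbsource-leadfield", format_version = 1L,
    H = unclass(leadfield$matrix),
    channels = leadfield$channels,
    pos = unclass(ss$positions),
    ori = if (is.null(ss$orientations)) NULL else unclass(ss$orientations),
    mode = ss$orientation_mode,
    grid_spacing = ss$grid_spacing,
    columns_per_source = leadfield$columns_per_source,
    psi_domain = isTRUE(leadfield$psi_domain)), path, provenance)
}

#' Read a lead field from a JSON container
#'
#' Validates shapes (N x kappa*M with kappa = 1 for fixed and 3 for free
#' orientation), orientation-mode consistency and finiteness. Containers
#' produced by other tools (e.g. FieldTrip exports converted to JSON) can be
#' ingested by supplying `var_map`, a named character vector mapping this
#' package's variable names to the names used in the file, e.g.
#' `c(H = "leadfield", pos = "sourcepos")`.
#'
#' @param path Input path.
#' @param var_map Optional variable-name remapping table.
#' @return A `leadfield` object.
#' @export
read_leadfield <- function(path, var_map = NULL) {
  raw <- read_container(path)
  get_var <- function(name, required = TRUE) {
    key <- if (!is.null(var_map) && name %in% names(var_map)) var_map[[name]]
           else name
    if (is.null(raw[[key]]) && required)
      stop("container is missing required variable '", key, "'")
    raw[[key]]
  }
  H <- unname(as.matrix(get_var("H")))
  mode <- get_var("mode")
  pos <- unname(as.matrix(get_var("pos")))
  if (ncol(pos) == 3L) dimnames(pos) <- list(NULL, c("x", "y", "z"))
  ori <- get_var("ori", required = FALSE)
  if (!mode %in% c("fixed", "free"))
    stop("variable 'mode' must be 'fixed' or 'free', got '", mode, "'")
  if (!all(is.finite(H))) stop("variable 'H' contains non-finite entries")
  kappa <- if (mode == "fixed") 1L else 3L
  m <- nrow(pos)
  if (ncol(pos) != 3L) stop("variable 'pos' must be M x 3")
  if (ncol(H) != kappa * m)
    stop(sprintf("variable 'H' has %d columns; expected %d (= %d x %d sources, %s mode)",
                 ncol(H), kappa * m, kappa, m, mode))
  if (mode == "fixed") {
    if (is.null(ori)) stop("fixed orientation mode requires variable 'ori'")
    ori <- as.matrix(ori)
    if (!all(abs(sqrt(rowSums(ori^2)) - 1) < 1e-6))
      stop("variable 'ori' rows must be unit vectors")
  } else ori <- NULL
  ss <- structure(list(positions = pos, orientation_mode = mode,
                       orientations = ori,
                       grid_spacing = raw$grid_spacing %||% NA_real_),
                  class = "source_space")
  structure(list(matrix = H,
                 channels = raw$channels %||% sprintf("E%03d", seq_len(nrow(H))),
                 source_space = ss,
                 columns_per_source = kappa,
                 psi_domain = isTRUE(raw$psi_domain)),
            class = "leadfield")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read an activation scene
#' @param scene An `activation_scene`.
#' @param path File path.
#' @param provenance Optional provenance list (sidecar).
#' @return `write_scene`: the path, invisibly; `read_scene`: the scene.
#' @export
write_scene <- function(scene, path, provenance = default_provenance()) {
  write_container(list(format = "vbsource-scene", format_version = 1L,
                       active_indices = scene$active_indices,
                       amplitudes = scene$amplitudes,
                       truth_positions = unclass(scene$truth_positions)),
                  path, provenance)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  raw <- read_container(path)
  structure(list(active_indices = as.integer(raw$active_indices),
                 amplitudes = as.numeric(raw$amplitudes),
                 truth_positions = matrix(as.numeric(raw$truth_positions),
                                          ncol = 3)),
            class = "activation_scene")
}

#' Write / read an EEG measurement
#' @param measurement An `eeg_measurement`.
#' @param path File path.
#' @param provenance Optional provenance list (sidecar).
#' @return `write_measurement`: the path, invisibly; `read_measurement`:
#'   the measurement.
#' @export
write_measurement <- function(measurement, path,
                              provenance = default_provenance()) {
  write_container(list(format = "vbsource-measurement", format_version = 1L,
                       y = measurement$y,
                       snr_db = if (is.infinite(measurement$snr_db)) "Inf"
                                else measurement$snr_db,
                       noise_seed = measurement$noise_seed), path, provenance)
}

#' @rdname write_measurement
#' @export
read_measurement <- function(path) {
  raw <- read_container(path)
  snr <- raw$snr_db
  if (identical(snr, "Inf")) snr <- Inf
  structure(list(y = as.numeric(raw$y), snr_db = as.numeric(snr),
                 noise_seed = raw$noise_seed %||% NA_integer_),
            class = "eeg_measurement")
}

#' Write a solver result to a JSON container
#'
#' Stores the posterior mean, per-source amplitude map, the posterior
#' hyperparameter moments, and iteration bookkeeping.
#'
#' @param result A `vb_state`, a [run_fansmooth()] result, or a plain
#'   estimate vector (e.g. from [mne_solve()]).
#' @param leadfield The lead field solved against.
#' @param path File path.
#' @param method Method label stored in the container.
#' @param provenance Optional provenance list (sidecar).
#' @return The path, invisibly.
#' @export
write_result <- function(result, leadfield, path, method = "fan",
                         provenance = default_provenance()) {
  if (is.list(result) && !inherits(result, "vb_state") &&
      !is.null(result$state)) {
    x_hat <- result$x_hat
    st <- result$state
  } else if (inherits(result, "vb_state")) {
    x_hat <- result$x_hat
    st <- result
  } else {
    x_hat <- as.numeric(result)
    st <- NULL
  }
  write_container(list(
    format = "vbsource-result", format_version = 1L, method = method,
    x_hat = x_hat,
    amplitude_map = amplitude_map(x_hat, leadfield),
    a_hat = st$a_hat, lam = st$lam, beta_hat = st$beta_hat,
    iterations = st$iteration, delta = st$delta,
    converged = st$converged), path, provenance)
}

#' @rdname write_result
#' @export
read_result <- function(path) {
  read_container(path)
}

#' Write / read a group structure
#'
#' Stored as a two-column text table (column_index, group_id) plus JSON
#' metadata recording whether groups overlap.
#'
#' @param groups A [group_structure()].
#' @param path Path of the table file; metadata goes to `<path>.meta.json`.
#' @return `write_groups`: the path, invisibly; `read_groups`: the
#'   structure.
#' @export
write_groups <- function(groups, path) {
  tab <- data.frame(
    column_index = unlist(groups$groups, use.names = FALSE),
    group_id = rep.int(seq_along(groups$groups), groups$sizes))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  writeLines(jsonlite::toJSON(list(overlapping = groups$overlapping),
                              auto_unbox = TRUE),
             paste0(path, ".meta.json"))
  invisible(path)
}

#' @rdname write_groups
#' @export
read_groups <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  meta_path <- paste0(path, ".meta.json")
  overlapping <- if (file.exists(meta_path))
    isTRUE(jsonlite::fromJSON(readLines(meta_path, warn = FALSE))$overlapping)
  else FALSE
  group_structure(split(tab$column_index, tab$group_id),
                  overlapping = overlapping)
}
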