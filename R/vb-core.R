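#' Hyperparameters of the hierarchical sparse prior
#'
#' Gamma hyperpriors on the per-source (or per-group) precision scales a and
#' on the noise precision beta. Defaults are vague (mean b*c = 1, very large
#' variance), the standard noninformative choice in sparse Bayesian learning.
#'
#' @param b_a,c_a Scale and shape of the Gamma prior on each a_i (or a_g).
#' @param b,c Scale and shape of the Gamma prior on the noise precision beta.
#' @return Object of class `hyper_params`.
#' @export
hyper_params <- function(b_a = 1e6, c_a = 1e-6, b = 1e6, c = 1e-6) {
  stopifnot(b_a > 0, c_a > 0, b > 0, c > 0)
  structure(list(b_a = b_a, c_a = c_a, b = b, c = c), class = "hyper_params")
}

#' Solver configuration
#'
#' @param max_iter Maximum number of VB cycles.
#' @param tol Convergence threshold on the relative change of the posterior
#'   mean, ||x^(k+1) - x^(k)|| / max(||x^(k)||, 1e-12).
#' @param lam_floor Lower floor on |x_i| (or ||x_g||) in the lambda
#'   reweighting rule, preventing division by zero for pruned sources.
#' @param hyper A [hyper_params()] object.
#' @param lam_mode `"reweighted"` (lambda_i = 1/max(|x_i|, floor), updated
#'   every cycle) or `"fixed_ones"` (lambda = 1 throughout, recovering the
#'   classical RVM-style sparse Bayesian learner).
#' @param linalg `"auto"` (Woodbury identity when columns outnumber
#'   channels), `"dense"`, or `"woodbury"`.
#' @param track If `TRUE`, record the per-cycle prior precision diagonal
#'   (a*lambda per group) in the returned state (`precision_trace`).
#' @return Object of class `solver_config`.
#' @export
solver_config <- function(max_iter = 500L, tol = 1e-6, lam_floor = 1e-8,
                          hyper = hyper_params(),
                          lam_mode = c("reweighted", "fixed_ones"),
                          linalg = c("auto", "dense", "woodbury"),
                          track = FALSE) {
  stopifnot(tol > 0, lam_floor > 0, max_iter >= 1)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 lam_floor = lam_floor, hyper = hyper,
                 lam_mode = match.arg(lam_mode),
                 linalg = match.arg(linalg),
                 track = isTRUE(track)),
            class = "solver_config")
}

#' Log marginal prior of one source amplitude
#'
#' Log-density (up to an additive constant) of the marginal prior obtained by
#' integrating the Gamma-distributed precision out of the scaled Gaussian
#' prior: a Student-t with shape `c_a` and scale `b_a / lambda_i`, i.e.
#' log[(lambda_i b_a)^(1/2)] - (c_a + 1/2) log(1 + lambda_i b_a x_i^2).
#' Diagnostic aid; not used inside the VB loop.
#'
#' @param x_i Source amplitude (vectorised).
#' @param lam_i Scale parameter lambda_i > 0.
#' @param hyper A [hyper_params()].
#' @return Log-density up to a constant.
#' @export
marginal_log_prior <- function(x_i, lam_i, hyper = hyper_params()) {
  if (any(lam_i <= 0)) stop("'lam_i' must be > 0")
  0.5 * log(lam_i * hyper$b_a) -
    (hyper$c_a + 0.5) * log1p(lam_i * hyper$b_a * x_i^2)
}

## ---- internal state machinery -------------------------------------------

# groups bookkeeping: idx = unlist(groups), gid = group id per entry
group_index <- function(groups) {
  sizes <- lengths(groups)
  list(idx = unlist(groups, use.names = FALSE),
       gid = rep.int(seq_along(groups), sizes),
       sizes = sizes)
}

# prior precision diagonal: Lambda_ii = sum over groups containing i of
# a_g * lambda_g (sum-of-precisions composition for overlapping groups)
prior_precision_diag <- function(a_hat, lam, gix, K) {
  vals <- (a_hat * lam)[gix$gid]
  out <- numeric(K)
  rs <- rowsum(vals, gix$idx)
  out[as.integer(rownames(rs))] <- rs
  out
}

# per-group sums of a per-coefficient vector
group_sum <- function(v, gix) {
  unname(drop(rowsum(v[gix$idx], gix$gid)))
}

# Posterior moments of q(x) for fixed Lambda-diagonal and beta.
# Dense route inverts the K x K matrix; Woodbury route inverts N x N only:
#   C = D - D H' (I/beta + H D H')^{-1} H D,   D = Lambda^{-1}
#   x = D H' (I/beta + H D H')^{-1} y
posterior_moments <- function(H, y, Ldiag, beta_hat, method = "auto",
                              want_full = FALSE) {
  N <- nrow(H); K <- ncol(H)
  if (method == "auto")
    method <- if (K > N && beta_hat > 0) "woodbury" else "dense"
  if (beta_hat == 0) method <- "dense"

  if (method == "dense") {
    A <- beta_hat * crossprod(H) + diag(Ldiag, K)
    C <- chol2inv(chol(A))
    x_hat <- drop(beta_hat * (C %*% crossprod(H, y)))
    c_diag <- diag(C)
    HC <- H %*% C
    tr_HCHt <- sum(HC * H)
    list(x_hat = x_hat, c_diag = c_diag, tr_HCHt = tr_HCHt,
         C_x = if (want_full) C else NULL)
  } else {
    D <- 1 / Ldiag
    Hd <- H * rep(D, each = N)               # H %*% diag(D)
    S <- tcrossprod(Hd, H)                   # H D H'
    M <- S + diag(1 / beta_hat, N)
    R <- chol(M)
    Minv_y <- backsolve(R, forwardsolve(t(R), y))
    x_hat <- drop(D * crossprod(H, Minv_y))
    Minv_H <- backsolve(R, forwardsolve(t(R), H))
    c_diag <- D - D^2 * colSums(H * Minv_H)
    Minv_S <- backsolve(R, forwardsolve(t(R), S))
    tr_HCHt <- sum(diag(S)) - sum(Minv_S * S)
    C_x <- NULL
    if (want_full) C_x <- diag(D, K) - crossprod(Hd, Minv_H) * rep(D, each = K)
    list(x_hat = x_hat, c_diag = c_diag, tr_HCHt = tr_HCHt, C_x = C_x)
  }
}

#' Initialize a VB solver state
#'
#' Builds the state holding all posterior moments: x_hat = 0, lambda = 1,
#' a_hat = 1, beta_hat = N/||y||^2 (unit-SNR heuristic; 1 for all-zero data).
#' The Gamma shapes are fixed by conjugacy: c'_a_g = c_a + d_g/2 and
#' c' = c + N/2 and never change afterwards.
#'
#' @param leadfield A [make_leadfield()] object (or plain matrix).
#' @param y Sensor data vector.
#' @param config A [solver_config()].
#' @param groups Optional [group_structure()]; defaults to one singleton
#'   group per column (the ungrouped solver).
#' @return Object of class `vb_state`.
#' @export
vb_state_init <- function(leadfield, y, config = solver_config(),
                          groups = NULL) {
  H <- leadfield_matrix(leadfield)
  N <- nrow(H); K <- ncol(H)
  if (length(y) != N) stop("length(y) must equal the number of channels")
  if (!all(is.finite(y))) stop("'y' must be finite")
  if (is.null(groups)) groups <- singleton_groups(K)
  validate_groups(groups, K)
  G <- length(groups$groups)
  hy <- config$hyper
  d_g <- lengths(groups$groups)
  structure(list(
    x_hat = numeric(K),
    c_diag = rep(1, K),
    C_x = NULL,
    lam = rep(1, G),
    a_hat = rep(1, G),
    b_prime_a = rep(NA_real_, G),
    c_prime_a = hy$c_a + d_g / 2,
    beta_hat = if (sum(y^2) > 0) N / sum(y^2) else 1,
    b_prime = NA_real_,
    c_prime = hy$c + N / 2,
    tr_HCHt = NA_real_,
    groups = groups,
    iteration = 0L,
    delta = Inf,
    converged = FALSE,
    precision_trace = if (config$track) list() else NULL
  ), class = "vb_state")
}

leadfield_matrix <- function(leadfield) {
  if (inherits(leadfield, "leadfield")) leadfield$matrix
  else if (is.matrix(leadfield)) leadfield
  else stop("'leadfield' must be a leadfield object or a matrix")
}

## ---- single-update operations (exposed for inspection/testing) ----------

#' Update the posterior covariance of the sources
#'
#' Recomputes C_x = (beta H'H + Lambda)^{-1} with the state's current prior
#' precision diagonal Lambda = diag(a_g lambda_g per column) and beta. The
#' Woodbury route gives identical results (to numerical tolerance) while
#' inverting only an N x N matrix.
#'
#' @param leadfield Lead field (object or matrix).
#' @param state A `vb_state`.
#' @param method `"auto"`, `"dense"` or `"woodbury"`.
#' @return The state with `C_x` (full matrix), `c_diag` and `tr_HCHt` updated.
#' @export
update_covariance <- function(leadfield, state, method = "auto") {
  H <- leadfield_matrix(leadfield)
  gix <- group_index(state$groups$groups)
  Ldiag <- prior_precision_diag(state$a_hat, state$lam, gix, ncol(H))
  if (!all(is.finite(Ldiag)) || any(Ldiag <= 0))
    stop("non-positive or non-finite prior precision at iteration ",
         state$iteration)
  mom <- posterior_moments(H, rep(0, nrow(H)), Ldiag, state$beta_hat,
                           method = method, want_full = TRUE)
  state$C_x <- mom$C_x
  state$c_diag <- mom$c_diag
  state$tr_HCHt <- mom$tr_HCHt
  state
}

#' Update the posterior mean of the sources
#'
#' x_hat = C_x beta H' y, using the state's covariance (recomputed if absent).
#'
#' @inheritParams update_covariance
#' @param y Sensor data.
#' @return State with `x_hat` updated.
#' @export
update_mean <- function(leadfield, y, state) {
  H <- leadfield_matrix(leadfield)
  if (is.null(state$C_x)) state <- update_covariance(leadfield, state)
  state$x_hat <- drop(state$beta_hat * (state$C_x %*% crossprod(H, y)))
  state
}

#' Update the precision-scale posteriors q(a_g)
#'
#' Conjugate Gamma updates: 1/b'_g = (lambda_g/2)(||x_g||^2 + sum_i C_ii) +
#' 1/b_a and c'_g = c_a + d_g/2 (so c'_i = c_a + 1/2 for singleton groups);
#' the posterior mean is a_hat_g = b'_g c'_g.
#'
#' @param state A `vb_state`.
#' @param hyper A [hyper_params()].
#' @return State with `b_prime_a`, `c_prime_a`, `a_hat` updated.
#' @export
update_a <- function(state, hyper = hyper_params()) {
  gix <- group_index(state$groups$groups)
  q_g <- group_sum(state$x_hat^2 + state$c_diag, gix)
  inv_b <- (state$lam / 2) * q_g + 1 / hyper$b_a
  state$b_prime_a <- 1 / inv_b
  state$c_prime_a <- hyper$c_a + gix$sizes / 2
  state$a_hat <- state$b_prime_a * state$c_prime_a
  state
}

#' Update the lambda rescaling weights
#'
#' Reweighted mode sets lambda_g = 1 / max(||x_hat_g||, lam_floor) (for
#' singleton groups, 1/max(|x_hat_i|, floor)); `fixed_ones` leaves lambda at
#' 1, recovering standard sparse Bayesian learning.
#'
#' @param state A `vb_state`.
#' @param config A [solver_config()].
#' @return State with `lam` updated.
#' @export
update_lambda <- function(state, config = solver_config()) {
  if (config$lam_mode == "fixed_ones") {
    state$lam <- rep(1, length(state$lam))
    return(state)
  }
  gix <- group_index(state$groups$groups)
  gnorm <- sqrt(group_sum(state$x_hat^2, gix))
  state$lam <- 1 / pmax(gnorm, config$lam_floor)
  state
}

#' Update the noise-precision posterior q(beta)
#'
#' Conjugate Gamma update for the Gaussian likelihood:
#' c' = c + N/2, 1/b' = 1/b + (||y - H x_hat||^2 + tr(H C_x H')) / 2,
#' beta_hat = b' c'. The trace term is the posterior-uncertainty part of
#' E_q||y - Hx||^2.
#'
#' @inheritParams update_mean
#' @param hyper A [hyper_params()].
#' @return State with `b_prime`, `c_prime`, `beta_hat` updated.
#' @export
update_beta <- function(leadfield, y, state, hyper = hyper_params()) {
  H <- leadfield_matrix(leadfield)
  resid <- y - drop(H %*% state$x_hat)
  tr_term <- state$tr_HCHt
  if (!is.finite(tr_term)) {
    if (is.null(state$C_x)) state <- update_covariance(leadfield, state)
    tr_term <- state$tr_HCHt
  }
  inv_bp <- 1 / hyper$b + 0.5 * (sum(resid^2) + tr_term)
  state$b_prime <- 1 / inv_bp
  state$c_prime <- hyper$c + length(y) / 2
  state$beta_hat <- state$b_prime * state$c_prime
  state
}

## ---- the full solver ------------------------------------------------------

# Shared VB cycle for the ungrouped, grouped and lambda-fixed solvers.
# Order within a cycle: lambda (from the previous mean; skipped on the first
# cycle, where the all-zero initial mean carries no information) ->
# covariance+mean -> a -> beta.
vb_engine <- function(H, y, groups, config) {
  N <- nrow(H); K <- ncol(H)
  state <- vb_state_init(H, y, config, groups)
  gix <- group_index(groups$groups)
  hy <- config$hyper
  method <- config$linalg
  last_good <- state

  for (k in seq_len(config$max_iter)) {
    if (config$lam_mode == "reweighted" && k > 1L) {
      gnorm <- sqrt(group_sum(state$x_hat^2, gix))
      state$lam <- 1 / pmax(gnorm, config$lam_floor)
    }
    Ldiag <- prior_precision_diag(state$a_hat, state$lam, gix, K)
    mom <- posterior_moments(H, y, Ldiag, state$beta_hat, method = method)
    x_old <- state$x_hat
    state$x_hat <- mom$x_hat
    state$c_diag <- mom$c_diag
    state$tr_HCHt <- mom$tr_HCHt

    # q(a_g)
    q_g <- group_sum(state$x_hat^2 + state$c_diag, gix)
    inv_b <- (state$lam / 2) * q_g + 1 / hy$b_a
    state$b_prime_a <- 1 / inv_b
    state$a_hat <- state$b_prime_a * state$c_prime_a

    # q(beta)
    resid <- y - drop(H %*% state$x_hat)
    inv_bp <- 1 / hy$b + 0.5 * (sum(resid^2) + state$tr_HCHt)
    state$b_prime <- 1 / inv_bp
    state$beta_hat <- state$b_prime * state$c_prime

    state$iteration <- k
    state$delta <- sqrt(sum((state$x_hat - x_old)^2)) /
      max(sqrt(sum(x_old^2)), 1e-12)
    if (config$track)
      state$precision_trace[[k]] <- state$a_hat * state$lam

    if (!all(is.finite(state$x_hat)) || !is.finite(state$beta_hat)) {
      cond <- structure(
        class = c("solver_failure", "error", "condition"),
        list(message = sprintf("solver diverged at iteration %d", k),
             call = sys.call(-1), state = last_good))
      stop(cond)
    }
    last_good <- state
    if (state$delta < config$tol) {
      state$converged <- TRUE
      break
    }
  }
  state
}

#' Run the lambda-reweighted sparse VB solver (Fan)
#'
#' Iterates the variational updates of the scaled Gaussian-Gamma hierarchy —
#' covariance and mean of q(x), the Gamma posteriors of the per-source
#' precisions and the noise precision, and the lambda reweighting
#' lambda_i = 1/max(|x_hat_i|, floor) — until the relative change of the
#' posterior mean falls below `config$tol` or `config$max_iter` cycles.
#' The solver is fully deterministic.
#'
#' @param leadfield Lead field (object or plain matrix).
#' @param y Sensor data vector (length N), or an `eeg_measurement`.
#' @param config A [solver_config()].
#' @return A converged (or max-iteration) `vb_state`.
#' @examples
#' prob <- simulate_problem(n_channels = 16, m = 60, seed = 3)
#' st <- run_fan(prob$leadfield, prob$measurement)
#' which.max(amplitude_map(st, prob$leadfield))
#' @export
run_fan <- function(leadfield, y, config = solver_config()) {
  H <- leadfield_matrix(leadfield)
  if (inherits(y, "eeg_measurement")) y <- y$y
  vb_engine(H, y, singleton_groups(ncol(H)), config)
}

#' Per-source activation magnitudes
#'
#' Collapses the posterior mean to one nonnegative magnitude per dipole:
#' |x_hat_i| in fixed-orientation mode, the Euclidean norm of each
#' consecutive [x,y,z] component triplet in free mode.
#'
#' @param state A `vb_state` (or any list with `x_hat`), or a plain numeric
#'   estimate vector.
#' @param leadfield The lead field the estimate refers to (provides the
#'   columns-per-source convention).
#' @return Numeric length-M vector of magnitudes.
#' @export
amplitude_map <- function(state, leadfield) {
  x <- if (is.numeric(state)) state else state$x_hat
  kappa <- if (inherits(leadfield, "leadfield")) leadfield$columns_per_source
           else 1L
  if (kappa == 1L) return(abs(x))
  m <- length(x) / kappa
  blocks <- matrix(x, nrow = kappa)
  sqrt(colSums(blocks^2))
}

#' @export
print.vb_state <- function(x, ...) {
  cat(sprintf(
    "VB state: %d coefficients, %d groups; iter %d, delta %.3g, %sconverged\n",
    length(x$x_hat), length(x$lam), x$iteration, x$delta,
    if (x$converged) "" else "NOT "))
  invisible(x)
}
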