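# Small seeded problem instances shared across test files.

tiny_problem <- function(seed = 3, n_channels = 16, m = 60, n_active = 1,
                         snr_db = Inf, ...) {
  simulate_problem(n_channels = n_channels, m = m, n_active = n_active,
                   snr_db = snr_db, seed = seed, ...)
}

fast_config <- function(...) solver_config(max_iter = 200, tol = 1e-8, ...)

# brute-force ridge solution minimising ||y - Hx||^2 + reg ||x||^2
ridge_oracle <- function(H, y, reg) {
  K <- ncol(H)
  drop(solve(crossprod(H) + diag(reg, K), crossprod(H, y)))
}
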