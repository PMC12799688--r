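# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed and a counter
#'
#' Experiment drivers hand every sub-task (a web, a TIM set, a community
#' replicate) its own RNG seed derived deterministically from the master seed,
#' so any single condition can be re-run in isolation. The derivation is a
#' fixed affine map modulo 2^31 - 1; it is not cryptographic, only collision
#' -sparse over the counter ranges used here.
#'
#' @param master integer master seed.
#' @param key non-negative integer counter identifying the sub-task.
#' @return a single integer seed in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(master, key) {
  m <- 2147483647
  s <- (as.double(master) %% m) * 48271 + (as.double(key) + 1) * 104729
  as.integer(s %% (m - 1) + 1)
}

# off-diagonal logical mask for a square matrix
offdiag_mask <- function(S) {
  m <- matrix(TRUE, S, S)
  diag(m) <- FALSE
  m
}

# population variance / covariance (divide by n, not n - 1): matrix-ensemble
# convention of the random-matrix stability literature
pop_var <- function(x) mean(x^2) - mean(x)^2
pop_cov <- function(x, y) mean(x * y) - mean(x) * mean(y)

stop_if_not_square <- function(M, name = "matrix") {
  if (!is.matrix(M) || nrow(M) != ncol(M)) {
    stop(sprintf("`%s` must be a square matrix", name), call. = FALSE)
  }
  if (!all(is.finite(M))) {
    stop(sprintf("`%s` contains non-finite entries", name), call. = FALSE)
  }
  invisible(M)
}
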