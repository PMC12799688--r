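#' Real part of the leading eigenvalue
#'
#' Local asymptotic stability of a community at equilibrium is governed by
#' the sign of the largest real part among the eigenvalues of the community
#' matrix. Following the convention of setting all self-regulation terms to
#' zero to isolate the contribution of inter-specific structure, the diagonal
#' is zeroed before the eigendecomposition (a trace-zero matrix always has
#' `Re(lambda_1) >= 0`, so the value reads as the amount of uniform
#' self-regulation that would be needed to stabilise the system).
#'
#' @param A a square community matrix.
#' @param zero_diagonal zero the diagonal before decomposing (default `TRUE`).
#' @return the maximum real part over eigenvalues of `A`.
#' @examples
#' leading_eigenvalue_real(matrix(c(0, 1, -1, 0), 2, 2)) # rotation: 0
#' leading_eigenvalue_real(matrix(c(0, 1, 1, 0), 2, 2)) # mutualism: 1
#' @export
leading_eigenvalue_real <- function(A, zero_diagonal = TRUE) {
  stop_if_not_square(A, "A")
  if (zero_diagonal) diag(A) <- 0
  ev <- tryCatch(
    eigen(A, only.values = TRUE)$values,
    error = function(e) {
      stop("eigenvalue computation failed: ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  max(Re(ev))
}

#' Instability score
#'
#' Natural log of [leading_eigenvalue_real()] with zero diagonal; the scale
#' on which instability responses to TIM frequency are compared. Requires a
#' strictly positive leading real part (guaranteed for any nonzero matrix
#' with zero diagonal except for degenerate cases with
#' `Re(lambda_1) = 0`).
#'
#' @param A a square community matrix.
#' @return `log(Re(lambda_1))`.
#' @export
instability_score <- function(A) {
  lam <- leading_eigenvalue_real(A, zero_diagonal = TRUE)
  if (lam <= 0) {
    stop(sprintf(
      "instability score undefined: Re(lambda_1) = %g is not positive", lam
    ), call. = FALSE)
  }
  log(lam)
}

#' Size of the feasibility domain
#'
#' The feasibility domain of a community matrix `A` (diagonal included) is
#' the set of intrinsic growth-rate directions for which all species attain a
#' positive equilibrium abundance. Its normalised size is the probability
#' `Omega(A)` that a growth-rate vector drawn uniformly on the unit sphere
#' yields `-solve(A) %*% r` componentwise positive — equivalently, the
#' orthant probability that a centred multivariate Gaussian with covariance
#' `solve(t(A) %*% A)` is all-positive. The per-species scaling
#' `omega(A) = Omega(A)^(1/S)` makes communities of different richness
#' comparable. The orthant probability is computed with the Genz-Bretz
#' quasi-Monte-Carlo algorithm under a fixed internal RNG seed, so repeated
#' calls on the same matrix return identical values.
#'
#' @param A an invertible square matrix, diagonal as intended for the
#'   analysis (feasibility depends non-trivially on self-regulation; -2 is
#'   the usual default, with 0 and -5 as sensitivity settings).
#' @param abseps absolute error tolerance of the orthant integration.
#' @param maxpts maximum integrand evaluations.
#' @param inner_seed RNG seed for the quasi-Monte-Carlo lattice.
#' @return a list with `omega_big` (Omega), `omega_small` (omega),
#'   `error` (reported integration error) and `method = "genz"`.
#' @examples
#' feasibility_domain(diag(-2, 3))$omega_small # 0.5
#' @seealso [mc_feasibility()] for the sphere-sampling oracle.
#' @export
feasibility_domain <- function(A, abseps = 1e-4, maxpts = 25000L,
                               inner_seed = 1905L) {
  stop_if_not_square(A, "A")
  kap <- kappa(A, exact = FALSE)
  if (!is.finite(kap) || kap > 1e12) {
    stop(sprintf(
      "matrix is singular or near-singular (condition number %.3g)", kap
    ), call. = FALSE)
  }
  S <- nrow(A)
  Sigma <- solve(crossprod(A))
  Sigma <- (Sigma + t(Sigma)) / 2
  res <- withr::with_seed(inner_seed, {
    mvtnorm::pmvnorm(
      lower = rep(0, S), upper = rep(Inf, S), mean = rep(0, S),
      sigma = Sigma,
      algorithm = mvtnorm::GenzBretz(abseps = abseps, maxpts = maxpts)
    )
  })
  omega <- max(0, min(1, as.numeric(res)))
  list(
    omega_big = omega,
    omega_small = omega^(1 / S),
    error = attr(res, "error"),
    method = "genz"
  )
}

#' Monte-Carlo feasibility oracle
#'
#' Direct sphere-sampling estimate of `Omega(A)`: draw standard-Gaussian
#' growth-rate vectors (direction uniform on the sphere), solve for the
#' equilibrium `-solve(A) %*% r`, and report the fraction that is
#' componentwise positive, with its binomial standard error. Serves as an
#' independent check on [feasibility_domain()].
#'
#' @param A an invertible square matrix.
#' @param n_samples number of random directions (>= 1000).
#' @return a list with `omega_big` (the estimate), `omega_small`, `se`
#'   (binomial standard error) and `method = "monte_carlo"`.
#' @export
mc_feasibility <- function(A, n_samples = 1e5) {
  stop_if_not_square(A, "A")
  stopifnot(n_samples >= 1000)
  S <- nrow(A)
  R <- matrix(stats::rnorm(S * n_samples), nrow = S)
  X <- -solve(A, R)
  hits <- colSums(X > 0) == S
  p <- mean(hits)
  list(
    omega_big = p,
    omega_small = p^(1 / S),
    se = sqrt(p * (1 - p) / n_samples),
    method = "monte_carlo"
  )
}

#' Bivariate orthant probability, closed form
#'
#' For a 2 x 2 system the orthant probability underlying `Omega` has the
#' closed form `1/4 + asin(rho) / (2 * pi)`, where `rho` is the correlation
#' of the implied Gaussian. Exposed for validation.
#'
#' @param rho correlation in `[-1, 1]`.
#' @return a probability.
#' @keywords internal
#' @export
orthant2_closed_form <- function(rho) {
  stopifnot(rho >= -1, rho <= 1)
  0.25 + asin(rho) / (2 * pi)
}
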