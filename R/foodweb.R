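#' Trophic strength distribution parameters
#'
#' Parameters of the bivariate Gaussian from which each trophic link draws its
#' two linearized per-capita effects: the effect of the consumer on the
#' resource (mean `mu_rc`, typically negative) and of the resource on the
#' consumer (mean `mu_cr`, typically positive), with correlation `rho`. The
#' defaults (`mu_rc = -1`, `mu_cr = 1`, sds `0.5`, `rho = -0.8`) give
#' predator-prey pairs whose reciprocal effects are strongly negatively
#' correlated, in line with empirical interaction-strength estimates.
#'
#' @param mu_rc mean effect of the consumer on the resource.
#' @param mu_cr mean effect of the resource on the consumer.
#' @param sd_rc,sd_cr standard deviations of the two effects (must be > 0).
#' @param rho correlation between the paired effects, in `[-1, 1]`.
#' @return an object of class `strength_params` (a named list).
#' @examples
#' strength_params()
#' strength_params(rho = -0.5)
#' @export
strength_params <- function(mu_rc = -1, mu_cr = 1, sd_rc = 0.5, sd_cr = 0.5,
                            rho = -0.8) {
  stopifnot(sd_rc > 0, sd_cr > 0, rho >= -1, rho <= 1)
  structure(
    list(mu_rc = mu_rc, mu_cr = mu_cr, sd_rc = sd_rc, sd_cr = sd_cr, rho = rho),
    class = "strength_params"
  )
}

#' @export
print.strength_params <- function(x, ...) {
  cat("Trophic strength distribution (bivariate Gaussian)\n")
  cat(sprintf("  consumer-on-resource: N(%g, %g)\n", x$mu_rc, x$sd_rc))
  cat(sprintf("  resource-on-consumer: N(%g, %g)\n", x$mu_cr, x$sd_cr))
  cat(sprintf("  correlation: %g\n", x$rho))
  invisible(x)
}

new_food_web <- function(S, links, niche, target_connectance) {
  structure(
    list(
      S = as.integer(S),
      links = links, # integer matrix, columns consumer, resource
      niche = niche,
      target_connectance = target_connectance
    ),
    class = "food_web"
  )
}

#' Generate a niche-model food web
#'
#' Draws a trophic topology from the niche model: each species receives a
#' niche value `n_i ~ Uniform(0, 1)`, a feeding range `r_i = n_i * x` with
#' `x ~ Beta(1, 1/(2C) - 1)` (so the expected directed connectance `L / S^2`
#' equals `C_target`), and a feeding centre uniform on `[r_i / 2, n_i]`.
#' Species `i` then consumes every species whose niche value falls inside its
#' feeding interval. The species with the smallest niche value is forced basal
#' (range zero), a standard implementation convention.
#'
#' Webs are subject to validity rules and regenerated on failure (up to
#' `max_tries` attempts): self-links arising from the niche interval are
#' removed; webs with an unconnected species, more than one weakly connected
#' component, or realized connectance deviating from `C_target` by more than
#' `tolerance` (relative) are rejected. Duplicate niche values are resampled.
#'
#' @param S number of species (>= 3).
#' @param C_target target directed connectance `L / S^2`, in `(0, 0.5)`.
#' @param tolerance maximum relative deviation of realized from target
#'   connectance before a web is rejected.
#' @param max_tries attempts before giving up with an error.
#' @return a `food_web` object: species count `S`, an integer link matrix with
#'   columns `consumer` and `resource` (species indexed `1..S` in increasing
#'   niche order), the niche values, and the target connectance.
#' @examples
#' set.seed(1)
#' web <- generate_niche_web(30, 0.2)
#' web
#' connectance_web(web)
#' @seealso [parameterise_trophic()], [trophic_adjacency()]
#' @export
generate_niche_web <- function(S, C_target, tolerance = 0.15,
                               max_tries = 1000) {
  stopifnot(S >= 3, C_target > 0, C_target < 0.5)
  beta_shape <- 1 / (2 * C_target) - 1
  last_fail <- "no attempt made"
  for (try in seq_len(max_tries)) {
    niche <- sort(stats::runif(S))
    while (anyDuplicated(niche) > 0) {
      dup <- duplicated(niche)
      niche[dup] <- stats::runif(sum(dup))
      niche <- sort(niche)
    }
    range_frac <- stats::rbeta(S, 1, beta_shape)
    r <- niche * range_frac
    r[1] <- 0 # smallest-niche species forced basal
    centre <- stats::runif(S, r / 2, niche)

    lo <- centre - r / 2
    hi <- centre + r / 2
    eats <- outer(lo, niche, `<=`) & outer(hi, niche, `>=`)
    diag(eats) <- FALSE # no self-links

    idx <- which(eats, arr.ind = TRUE)
    links <- cbind(consumer = idx[, 1], resource = idx[, 2])
    L <- nrow(links)
    if (L == 0) {
      last_fail <- "no links realized"
      next
    }

    deg <- tabulate(c(links[, 1], links[, 2]), nbins = S)
    if (any(deg == 0)) {
      last_fail <- "species with zero total degree"
      next
    }
    g <- igraph::graph_from_edgelist(links, directed = TRUE)
    if (igraph::count_components(g, mode = "weak") > 1) {
      last_fail <- "web not weakly connected"
      next
    }
    realized <- L / S^2
    if (abs(realized - C_target) / C_target > tolerance) {
      last_fail <- sprintf(
        "realized connectance %.4f outside +/-%.0f%% of target %.3f",
        realized, 100 * tolerance, C_target
      )
      next
    }
    return(new_food_web(S, links, niche, C_target))
  }
  stop(
    sprintf(
      "failed to generate a valid niche web in %d tries (last failure: %s)",
      max_tries, last_fail
    ),
    call. = FALSE
  )
}

#' Construct a food web from an explicit link list
#'
#' Escape hatch for small hand-built topologies (tests, toy examples). Links
#' are validated against the same invariants the niche generator enforces:
#' no self-links and every species in at least one link.
#'
#' @param links two-column integer matrix or data frame (consumer, resource),
#'   species indexed `1..S`.
#' @param S species count; defaults to the largest id in `links`.
#' @param niche optional niche values (defaults to equally spaced).
#' @param target_connectance recorded target; defaults to realized `L / S^2`.
#' @return a `food_web`.
#' @examples
#' food_web(rbind(c(2, 1), c(3, 2))) # chain: 3 eats 2 eats 1
#' @export
food_web <- function(links, S = max(links), niche = NULL,
                     target_connectance = NULL) {
  links <- as.matrix(links)
  storage.mode(links) <- "integer"
  stopifnot(ncol(links) == 2, nrow(links) >= 1, all(links >= 1), all(links <= S))
  colnames(links) <- c("consumer", "resource")
  if (any(links[, 1] == links[, 2])) {
    stop("self-links are not allowed", call. = FALSE)
  }
  if (any(tabulate(c(links), nbins = S) == 0)) {
    stop("every species must appear in at least one link", call. = FALSE)
  }
  if (is.null(niche)) niche <- seq_len(S) / (S + 1)
  if (is.null(target_connectance)) target_connectance <- nrow(links) / S^2
  new_food_web(S, links, niche, target_connectance)
}

#' @rdname food_web
#' @param n chain length for `chain_web()`: species `m + 1` eats species `m`.
#' @export
chain_web <- function(n) {
  stopifnot(n >= 2)
  food_web(cbind(2:n, 1:(n - 1)), S = n)
}

#' @export
print.food_web <- function(x, ...) {
  cat(sprintf(
    "Niche-model food web: %d species, %d links (connectance %.3f, target %.3f)\n",
    x$S, nrow(x$links), connectance_web(x), x$target_connectance
  ))
  invisible(x)
}

#' Realized directed connectance of a food web
#'
#' Number of directed consumer-resource links divided by `S^2`, the
#' convention of the niche-model literature (matrix-level connectance in
#' [connectance()] uses `S * (S - 1)` instead; both are documented where
#' used).
#'
#' @param web a `food_web`.
#' @return a fraction in `[0, 1]`.
#' @export
connectance_web <- function(web) {
  stopifnot(inherits(web, "food_web"))
  nrow(web$links) / web$S^2
}

#' Parameterise trophic links with correlated bivariate-Gaussian strengths
#'
#' For every link (consumer `j`, resource `i`) a correlated pair of effects is
#' drawn from the bivariate Gaussian in `params`: the effect of the consumer
#' on the resource goes to `B[i, j]` and the effect of the resource on the
#' consumer to `B[j, i]`. Non-link entries and the diagonal are zero. Draws
#' are not truncated, so a consumer-on-resource effect may occasionally be
#' positive, as the Gaussian allows. In the rare case of mutual feeding (both
#' `i` eats `j` and `j` eats `i`), the linearized contributions of the two
#' links are combined additively in the shared cells.
#'
#' @param web a `food_web`.
#' @param params a [strength_params()] object.
#' @return an S x S numeric matrix with attribute `role = "trophic"`; entry
#'   `(i, j)` is the per-capita effect of species `j` on species `i`.
#' @examples
#' set.seed(1)
#' web <- generate_niche_web(20, 0.2)
#' B <- parameterise_trophic(web)
#' mean(B[B != 0])
#' @export
parameterise_trophic <- function(web, params = strength_params()) {
  stopifnot(inherits(web, "food_web"), inherits(params, "strength_params"))
  S <- web$S
  B <- matrix(0, S, S)
  L <- nrow(web$links)
  if (L > 0) {
    Sigma <- matrix(
      c(
        params$sd_rc^2, params$rho * params$sd_rc * params$sd_cr,
        params$rho * params$sd_rc * params$sd_cr, params$sd_cr^2
      ),
      2, 2
    )
    draws <- MASS::mvrnorm(L, mu = c(params$mu_rc, params$mu_cr), Sigma = Sigma)
    draws <- matrix(draws, ncol = 2) # mvrnorm drops dims at L = 1
    cons <- web$links[, "consumer"]
    res <- web$links[, "resource"]
    # accumulate (handles mutual-feeding collisions additively)
    rows <- c(res, cons)
    cols <- c(cons, res)
    vals <- c(draws[, 1], draws[, 2])
    lin <- (cols - 1L) * S + rows
    sums <- rowsum(vals, lin)
    B[as.integer(rownames(sums))] <- sums[, 1]
  }
  attr(B, "role") <- "trophic"
  B
}

#' Undirected trophic adjacency of a food web
#'
#' Symmetric boolean relation: `TRUE` at `(i, j)` iff `i` eats `j` or `j` eats
#' `i`. Used by the TIM distribution models that condition on whether a
#' modifier is trophically connected to the interactors it modifies.
#'
#' @param web a `food_web`.
#' @return an S x S logical matrix with `FALSE` diagonal.
#' @export
trophic_adjacency <- function(web) {
  stopifnot(inherits(web, "food_web"))
  S <- web$S
  adj <- matrix(FALSE, S, S)
  adj[web$links] <- TRUE
  out <- adj | t(adj)
  diag(out) <- FALSE
  out
}
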