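#' TIM distribution models
#'
#' Tags of the seven trophic-interaction-modification distribution models plus
#' the random non-trophic-effect baseline used for benchmarking:
#' \describe{
#'   \item{random}{every (resource, consumer, modifier) triple with a real
#'     trophic link is equally likely; drawn sign kept.}
#'   \item{nearby_only}{modifier must be trophically linked to at least one of
#'     the two interactors.}
#'   \item{far_only}{modifier must not be trophically linked to either
#'     interactor.}
#'   \item{facilitating}{random topology, all modifications strengthen the
#'     link (positive strength).}
#'   \item{interfering}{random topology, all modifications weaken the link
#'     (negative strength).}
#'   \item{reciprocal}{TIMs occur in tight pairs: if k modifies the link from
#'     consumer j to resource i, then i modifies the link from j to k; drawn
#'     signs kept.}
#'   \item{mutual_interference}{the reciprocal pair topology with all signs
#'     forced negative: two resources sharing a consumer each weaken the
#'     other's consumption.}
#'   \item{random_nte_baseline}{not a TIM model: the matching number of
#'     non-trophic effects scattered independently over the matrix (see
#'     [build_random_nte()]).}
#' }
#' @export
tim_models <- c(
  "random", "nearby_only", "far_only", "facilitating", "interfering",
  "reciprocal", "mutual_interference"
)

#' @rdname tim_models
#' @export
paired_tim_models <- c("reciprocal", "mutual_interference")

#' Enumerate candidate trophic interaction modifications
#'
#' Lists every admissible TIM triple (resource `i`, consumer `j`, modifier
#' `k`) for a distribution model: `(j, i)` must be a trophic link of `web` and
#' `k` must be a third species (`k != i, j`; species never modify their own
#' interactions). The topology-free models (`random`, `facilitating`,
#' `interfering`) share the full candidate set; `nearby_only` keeps triples
#' whose modifier is trophically linked to an interactor and `far_only` keeps
#' the complement, so the two partition the full set. The paired models
#' (`reciprocal`, `mutual_interference`) enumerate unordered pairs of
#' resources `{i, k}` sharing a consumer `j`; each pair yields the two TIMs
#' `(i, j, k)` and `(k, j, i)` and is sampled atomically.
#'
#' @param web a `food_web`.
#' @param model one of [tim_models].
#' @return a tibble with integer columns `i` (resource), `j` (consumer), `k`
#'   (modifier) and, for paired models, `pair_id` (two rows per pair);
#'   attribute `paired` records whether candidates are pairs.
#' @examples
#' web <- chain_web(3) # species 3 eats 2, 2 eats 1
#' enumerate_tim_candidates(web, "random")
#' @export
enumerate_tim_candidates <- function(web, model = tim_models) {
  model <- match.arg(model)
  stopifnot(inherits(web, "food_web"))
  S <- web$S
  cons <- web$links[, "consumer"]
  res <- web$links[, "resource"]

  if (model %in% paired_tim_models) {
    out <- purrr::map_dfr(unique(cons), function(j) {
      rj <- sort(res[cons == j])
      if (length(rj) < 2) {
        return(NULL)
      }
      pairs <- utils::combn(rj, 2)
      tibble::tibble(
        i = c(pairs[1, ], pairs[2, ]),
        j = as.integer(j),
        k = c(pairs[2, ], pairs[1, ]),
        half = rep(1:2, each = ncol(pairs)),
        pid = rep(seq_len(ncol(pairs)), 2)
      )
    })
    if (nrow(out) == 0) {
      stop(sprintf("no candidate TIM pairs for model '%s' in this web", model),
        call. = FALSE
      )
    }
    out <- out[order(out$j, out$pid, out$half), c("i", "j", "k")]
    out$pair_id <- rep(seq_len(nrow(out) / 2), each = 2)
    out <- tibble::as_tibble(out)
  } else {
    n_link <- length(cons)
    k <- rep(seq_len(S), each = n_link)
    i <- rep(res, S)
    j <- rep(cons, S)
    keep <- k != i & k != j
    out <- tibble::tibble(i = i[keep], j = j[keep], k = k[keep])
    if (model %in% c("nearby_only", "far_only")) {
      adj <- trophic_adjacency(web)
      near <- adj[cbind(out$k, out$i)] | adj[cbind(out$k, out$j)]
      out <- if (model == "nearby_only") out[near, ] else out[!near, ]
    }
    if (nrow(out) == 0) {
      stop(sprintf("no candidate TIMs for model '%s' in this web", model),
        call. = FALSE
      )
    }
  }
  attr(out, "paired") <- model %in% paired_tim_models
  attr(out, "model") <- model
  out
}

#' Target mean magnitude of non-trophic effects
#'
#' Half the mean absolute trophic interaction strength of `B` (nonzero
#' off-diagonal entries). TIM strength draws are calibrated so that the mean
#' magnitude of the resulting non-trophic effects equals this value,
#' reflecting meta-analytic evidence that non-trophic effects are of the same
#' order as, but somewhat weaker than, trophic ones.
#'
#' @param B a trophic interaction matrix.
#' @return a positive scalar.
#' @examples
#' B <- matrix(c(0, 1, -1, 0), 2, 2)
#' compute_alpha(B) # 0.5
#' @export
compute_alpha <- function(B) {
  stop_if_not_square(B, "B")
  vals <- B[offdiag_mask(nrow(B))]
  vals <- vals[vals != 0]
  if (length(vals) == 0) {
    stop("`B` has no nonzero off-diagonal entries", call. = FALSE)
  }
  0.5 * mean(abs(vals))
}

#' Sample a set of trophic interaction modifications
#'
#' Draws `round(lambda * S)` TIMs uniformly without replacement from the
#' model's candidate set (for paired models, whole pairs are drawn and each
#' member counts separately toward the target, so the count is rounded to the
#' nearest even number). Strengths `c_ijk` are drawn from a Gaussian with mean
#' 0 and standard deviation `alpha * sqrt(pi) / sqrt(2)`, which makes the mean
#' magnitude of draws equal `alpha` (half-normal mean). Signs are then
#' adjusted per model: `facilitating` takes absolute values, `interfering` and
#' `mutual_interference` take negative absolute values, all other models keep
#' the drawn sign.
#'
#' @param web a `food_web`.
#' @param model one of [tim_models].
#' @param lambda target number of TIMs per species (the per-species frequency).
#' @param alpha target mean magnitude of individual non-trophic effects;
#'   usually [compute_alpha()] of the trophic matrix.
#' @param candidates optional precomputed candidate tibble from
#'   [enumerate_tim_candidates()] (must match `model`).
#' @return a `tim_set`: a tibble with columns `i`, `j`, `k`, `c` and
#'   attributes `model`, `lambda`, `alpha`, `S`.
#' @examples
#' set.seed(1)
#' web <- generate_niche_web(20, 0.2)
#' tims <- sample_tim_set(web, "random", lambda = 2, alpha = 0.5)
#' nrow(tims) # round(2 * 20)
#' @export
sample_tim_set <- function(web, model = tim_models, lambda, alpha,
                           candidates = NULL) {
  model <- match.arg(model)
  stopifnot(lambda >= 0, alpha > 0)
  S <- web$S
  paired <- model %in% paired_tim_models
  n_target <- if (paired) 2L * as.integer(round(lambda * S / 2)) else
    as.integer(round(lambda * S))

  if (n_target == 0L) {
    out <- tibble::tibble(
      i = integer(), j = integer(), k = integer(), c = numeric()
    )
    return(new_tim_set(out, model, lambda, alpha, S))
  }
  if (is.null(candidates)) {
    candidates <- enumerate_tim_candidates(web, model)
  } else if (!identical(attr(candidates, "model"), model)) {
    stop("`candidates` were enumerated for a different model", call. = FALSE)
  }

  if (paired) {
    n_pairs <- nrow(candidates) / 2
    if (n_target / 2 > n_pairs) {
      stop(sprintf(
        "model '%s' has only %d candidate pairs (max lambda ~ %.2f); %d needed",
        model, n_pairs, 2 * n_pairs / S, n_target / 2
      ), call. = FALSE)
    }
    take <- sample.int(n_pairs, n_target / 2)
    sel <- candidates[candidates$pair_id %in% take, c("i", "j", "k")]
  } else {
    if (n_target > nrow(candidates)) {
      stop(sprintf(
        "model '%s' has only %d candidate TIMs (max lambda ~ %.2f); %d needed",
        model, nrow(candidates), nrow(candidates) / S, n_target
      ), call. = FALSE)
    }
    sel <- candidates[sample.int(nrow(candidates), n_target), c("i", "j", "k")]
  }

  strength <- stats::rnorm(nrow(sel), mean = 0, sd = alpha * sqrt(pi / 2))
  strength <- switch(model,
    facilitating = abs(strength),
    interfering = -abs(strength),
    mutual_interference = -abs(strength),
    strength
  )
  sel$c <- strength
  new_tim_set(tibble::as_tibble(sel), model, lambda, alpha, S)
}

new_tim_set <- function(tbl, model, lambda, alpha, S) {
  structure(
    tbl,
    model = model, lambda = lambda, alpha = alpha, S = as.integer(S),
    class = c("tim_set", class(tibble::tibble()))
  )
}

#' @export
print.tim_set <- function(x, ...) {
  cat(sprintf(
    "TIM set: model '%s', %d TIMs (lambda = %g, alpha = %g, S = %d)\n",
    attr(x, "model"), nrow(x), attr(x, "lambda"), attr(x, "alpha"),
    attr(x, "S")
  ))
  NextMethod()
}

#' Collapse a TIM set into a non-trophic effect matrix
#'
#' Each TIM (resource `i`, consumer `j`, modifier `k`, strength `c`)
#' linearizes into exactly two non-trophic effects of the modifier: `+c` on
#' the consumer (cell `(j, k)`) and `-c` on the resource (cell `(i, k)`) — a
#' facilitating modification helps the consumer and harms the resource, an
#' interfering one the reverse. Effects of distinct TIMs landing on the same
#' cell are combined additively. The diagonal is untouched.
#'
#' @param tims a `tim_set` (or tibble with columns `i`, `j`, `k`, `c`).
#' @param S number of species (defaults to the `S` attribute of `tims`).
#' @return an S x S matrix with attribute `role = "nontrophic"`.
#' @examples
#' tims <- tibble::tibble(i = 1L, j = 2L, k = 3L, c = 0.4)
#' build_nte_matrix(tims, S = 3)
#' @export
build_nte_matrix <- function(tims, S = attr(tims, "S")) {
  stopifnot(!is.null(S), all(c("i", "j", "k", "c") %in% names(tims)))
  if (nrow(tims) > 0 && max(tims$i, tims$j, tims$k) > S) {
    stop("TIM species ids exceed S", call. = FALSE)
  }
  C <- matrix(0, S, S)
  if (nrow(tims) > 0) {
    rows <- c(tims$j, tims$i)
    cols <- c(tims$k, tims$k)
    vals <- c(tims$c, -tims$c)
    lin <- (cols - 1L) * S + rows
    sums <- rowsum(vals, lin)
    C[as.integer(rownames(sums))] <- sums[, 1]
  }
  attr(C, "role") <- "nontrophic"
  C
}

#' Random non-trophic-effect baseline matrix
#'
#' Benchmark against which the structured TIM models are compared: the same
#' number of non-trophic effects, but scattered independently over distinct
#' off-diagonal cells with Gaussian strengths (mean 0, sd
#' `alpha * sqrt(pi) / sqrt(2)`, the same calibration as TIM strengths). When
#' benchmarking a TIM set, use `n_effects` equal to twice the TIM count, since
#' each TIM contributes two non-trophic effects.
#'
#' @param n_effects number of nonzero cells; at most `S * (S - 1)`.
#' @param alpha target mean magnitude of effects.
#' @param S number of species.
#' @return an S x S matrix with attribute `role = "nontrophic"`.
#' @export
build_random_nte <- function(n_effects, alpha, S) {
  stopifnot(n_effects >= 0, alpha > 0, S >= 2)
  capacity <- S * (S - 1)
  if (n_effects > capacity) {
    stop(sprintf(
      "n_effects = %d exceeds the %d off-diagonal cells at S = %d",
      n_effects, capacity, S
    ), call. = FALSE)
  }
  C <- matrix(0, S, S)
  if (n_effects > 0) {
    cells <- which(offdiag_mask(S))
    sel <- cells[sample.int(capacity, n_effects)]
    C[sel] <- stats::rnorm(n_effects, 0, alpha * sqrt(pi / 2))
  }
  attr(C, "role") <- "nontrophic"
  C
}
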