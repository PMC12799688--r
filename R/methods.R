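# tidy()/glance() methods and re-exports.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a food web into its edge list
#'
#' @param x a `food_web`.
#' @param ... unused.
#' @return a tibble with columns `consumer`, `resource`, `consumer_niche`,
#'   `resource_niche`.
#' @export
tidy.food_web <- function(x, ...) {
  tibble::tibble(
    consumer = as.integer(x$links[, "consumer"]),
    resource = as.integer(x$links[, "resource"]),
    consumer_niche = x$niche[x$links[, "consumer"]],
    resource_niche = x$niche[x$links[, "resource"]]
  )
}

#' @rdname tidy.food_web
#' @export
glance.food_web <- function(x, ...) {
  out_deg <- tabulate(x$links[, "consumer"], nbins = x$S)
  tibble::tibble(
    S = x$S,
    L = nrow(x$links),
    connectance = connectance_web(x),
    target_connectance = x$target_connectance,
    n_basal = sum(out_deg == 0)
  )
}

#' Tidy a TIM set
#'
#' @param x a `tim_set`.
#' @param ... unused.
#' @return `tidy()`: the (resource, consumer, modifier, strength) tibble with
#'   the model tag as a column; `glance()`: a one-row summary.
#' @export
tidy.tim_set <- function(x, ...) {
  tibble::tibble(
    model = attr(x, "model"),
    i = x$i, j = x$j, k = x$k, c = x$c
  )
}

#' @rdname tidy.tim_set
#' @export
glance.tim_set <- function(x, ...) {
  tibble::tibble(
    model = attr(x, "model"),
    lambda = attr(x, "lambda"),
    alpha = attr(x, "alpha"),
    S = attr(x, "S"),
    n_tims = nrow(x),
    mean_abs_strength = if (nrow(x) > 0) mean(abs(x$c)) else NA_real_,
    frac_positive = if (nrow(x) > 0) mean(x$c > 0) else NA_real_
  )
}

#' Tidy a critical-strength search
#'
#' @param x a `critical_strength` object.
#' @param ... unused.
#' @return `tidy()`: the evaluated strength sweep (one row per tested
#'   strength); `glance()`: a one-row summary with the critical strength.
#' @export
tidy.critical_strength <- function(x, ...) {
  dplyr::mutate(x$sweep, scenario = x$scenario, N = x$N, .before = 1)
}

#' @rdname tidy.critical_strength
#' @export
glance.critical_strength <- function(x, ...) {
  tibble::tibble(
    scenario = x$scenario, N = x$N, critical_strength = x$value,
    censored = x$censored, monotone_sweep = x$monotone_sweep,
    n_communities = x$n_communities, quantile = x$quantile, seed = x$seed
  )
}
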