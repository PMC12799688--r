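# Orchestration of the two simulation experiments:
#  (1) structure/dynamics sweep over TIM distribution models and frequencies;
#  (2) diversity-stability sweep of critical strengths over HOI scenarios.
# Both emit tidy tibbles, one row per evaluated condition, each carrying the
# child seed that produced it so any row can be regenerated in isolation.

#' Structure and dynamics sweep over TIM distribution models
#'
#' For each generated web, each distribution model and each TIM frequency
#' `lambda`, samples a TIM set, collapses it into the non-trophic matrix `C`,
#' assembles `A = B + C`, and records the six structural metrics, the
#' leading-eigenvalue instability (zero diagonal), and — optionally — the
#' feasibility-domain size at each requested self-regulation value. The
#' `random_nte_baseline` model replaces the TIM set with the matching number
#' of independently scattered non-trophic effects (two per TIM). Failures of
#' any stage (e.g. candidate exhaustion for sparse models at high `lambda`)
#' are recorded per row with a reason code and the run continues.
#'
#' @param S species per web.
#' @param C_target target web connectance.
#' @param models character vector drawn from [tim_models] and/or
#'   `"random_nte_baseline"`.
#' @param lambda numeric vector of TIM frequencies per species.
#' @param n_webs number of independent webs.
#' @param diagonals self-regulation values at which feasibility is computed
#'   (ignored unless `feasibility = TRUE`).
#' @param feasibility compute feasibility-domain sizes (the expensive step).
#' @param params trophic strength distribution.
#' @param seed master seed; every row records its derived child seed.
#' @return a tibble of class `structure_records`, one row per
#'   (web, model, lambda, diagonal) — `diagonal` is `NA` when
#'   `feasibility = FALSE` — with the metric columns and a `failure` reason
#'   column (`NA` on success).
#' @examples
#' run_structure_experiment(
#'   S = 20, n_webs = 2, models = c("random", "mutual_interference"),
#'   lambda = c(0, 4), seed = 1
#' )
#' @export
run_structure_experiment <- function(S = 60, C_target = 0.2,
                                     models = c(tim_models, "random_nte_baseline"),
                                     lambda = seq(0, 30, by = 2),
                                     n_webs = 100, diagonals = -2,
                                     feasibility = FALSE,
                                     params = strength_params(), seed = 1) {
  stopifnot(
    length(lambda) > 0, n_webs >= 1,
    all(models %in% c(tim_models, "random_nte_baseline"))
  )
  if (!feasibility) diagonals <- NA_real_

  grid <- tidyr::expand_grid(
    web_id = seq_len(n_webs), model = models, lambda = lambda
  )
  grid$key <- seq_len(nrow(grid))

  webs <- lapply(seq_len(n_webs), function(w) {
    set.seed(derive_seed(seed, w))
    web <- generate_niche_web(S, C_target)
    B <- parameterise_trophic(web, params)
    list(web = web, B = B, alpha = compute_alpha(B))
  })

  one_condition <- function(web_id, model, lambda, key) {
    child <- derive_seed(seed, n_webs + key)
    set.seed(child)
    w <- webs[[web_id]]
    base <- tibble::tibble(
      web_id = web_id, model = model, lambda = lambda, seed = child
    )
    result <- tryCatch(
      {
        C <- if (model == "random_nte_baseline") {
          n_tims <- as.integer(round(lambda * S))
          build_random_nte(2L * n_tims, w$alpha, S)
        } else {
          build_nte_matrix(sample_tim_set(w$web, model, lambda, w$alpha), S)
        }
        A0 <- assemble_community(w$B, C, diagonal = 0)
        lam1 <- leading_eigenvalue_real(A0)
        metrics <- structure_metrics(w$B, C)
        rows <- purrr::map_dfr(diagonals, function(d) {
          out <- dplyr::bind_cols(
            base, metrics,
            tibble::tibble(
              re_lambda1 = lam1,
              instability = if (lam1 > 0) log(lam1) else NA_real_,
              diagonal = d,
              omega_big = NA_real_, omega_small = NA_real_
            )
          )
          if (feasibility && !is.na(d)) {
            feas <- tryCatch(
              feasibility_domain(assemble_community(w$B, C, diagonal = d)),
              error = function(e) NULL
            )
            if (!is.null(feas)) {
              out$omega_big <- feas$omega_big
              out$omega_small <- feas$omega_small
            }
          }
          out
        })
        rows$failure <- NA_character_
        rows
      },
      error = function(e) {
        dplyr::bind_cols(
          base,
          tibble::tibble(
            connectance_A = NA_real_, connectance_C = NA_real_,
            variance_C = NA_real_, degree_heterogeneity = NA_real_,
            pairwise_correlation = NA_real_, cov_BC = NA_real_,
            re_lambda1 = NA_real_, instability = NA_real_,
            diagonal = diagonals[1], omega_big = NA_real_,
            omega_small = NA_real_, failure = conditionMessage(e)
          )
        )
      }
    )
    result
  }

  records <- purrr::pmap_dfr(grid, one_condition)
  class(records) <- c("structure_records", class(records))
  attr(records, "settings") <- list(
    S = S, C_target = C_target, n_webs = n_webs, seed = seed,
    feasibility = feasibility, diagonals = diagonals
  )
  records
}

#' Diversity-stability sweep over HOI scenarios
#'
#' Runs [critical_strength()] for every combination of scenario and species
#' count and gathers the results in a tidy summary, one row per cell, with
#' the full strength sweeps attached as a list-column.
#'
#' @param scenarios character vector drawn from [hoi_scenarios].
#' @param N_values integer vector of community sizes.
#' @param n_communities communities per strength evaluation.
#' @param quantile persistence quantile defining the critical strength.
#' @param grid,n_bisect,t_max passed to [critical_strength()].
#' @param quick use a reduced search (8-point grid, 4 bisection steps) for
#'   exploratory runs.
#' @param seed master seed.
#' @return a tibble of class `hoi_records` with columns `scenario`, `N`,
#'   `critical_strength`, `censored`, `monotone_sweep`, `seed` and the
#'   list-column `sweep`.
#' @examples
#' \donttest{
#' run_hoi_experiment("pairwise_random", N_values = 10,
#'   n_communities = 5, quick = TRUE, seed = 1)
#' }
#' @export
run_hoi_experiment <- function(scenarios = hoi_scenarios,
                               N_values = c(10, 20, 30),
                               n_communities = 50, quantile = 0.9,
                               grid = NULL, n_bisect = 8, t_max = 500,
                               quick = FALSE, seed = 1) {
  stopifnot(all(scenarios %in% hoi_scenarios), length(N_values) > 0)
  if (quick) {
    n_bisect <- min(n_bisect, 4L)
  }
  cells <- tidyr::expand_grid(scenario = scenarios, N = as.integer(N_values))
  out <- purrr::pmap_dfr(
    cbind(cells, key = seq_len(nrow(cells))),
    function(scenario, N, key) {
      child <- derive_seed(seed, key)
      this_grid <- grid
      if (is.null(this_grid) && quick) {
        this_grid <- if (scenario == "pairwise_random") {
          10^seq(-3, 1, length.out = 8)
        } else {
          10^seq(-2, 2, length.out = 8)
        }
      }
      cs <- critical_strength(
        scenario, N,
        n_communities = n_communities, quantile = quantile,
        grid = this_grid, n_bisect = n_bisect, t_max = t_max, seed = child
      )
      tibble::tibble(
        scenario = scenario, N = N, critical_strength = cs$value,
        censored = cs$censored, monotone_sweep = cs$monotone_sweep,
        seed = child, sweep = list(cs$sweep)
      )
    }
  )
  class(out) <- c("hoi_records", class(out))
  attr(out, "settings") <- list(
    n_communities = n_communities, quantile = quantile, seed = seed,
    quick = quick
  )
  out
}

#' Summarise experiment records per condition
#'
#' Grouped means, standard deviations and replicate counts of every numeric
#' metric column — the numeric counterpart of the smoothed per-condition
#' curves used to present these sweeps graphically.
#'
#' @param records a tibble of experiment records.
#' @param ... grouping columns (tidy-select), e.g. `model, lambda` or
#'   `scenario, N`. Defaults to `model, lambda` for `structure_records` and
#'   `scenario, N` for `hoi_records`.
#' @return a tibble with one row per group and, per metric `m`, columns
#'   `m_mean`, `m_sd`, plus `n_replicates` and `n_failed`.
#' @examples
#' rec <- run_structure_experiment(
#'   S = 15, n_webs = 2, models = "random", lambda = c(0, 2), seed = 1
#' )
#' summarise_experiment(rec)
#' @export
summarise_experiment <- function(records, ...) {
  groups <- rlang::enquos(...)
  if (length(groups) == 0) {
    default <- if (inherits(records, "hoi_records")) {
      c("scenario", "N")
    } else {
      c("model", "lambda")
    }
    default <- intersect(default, names(records))
    if (length(default) == 0) {
      stop("no grouping columns supplied and no defaults found", call. = FALSE)
    }
    grouped <- dplyr::group_by(records, dplyr::across(dplyr::all_of(default)))
  } else {
    grouped <- dplyr::group_by(records, !!!groups)
  }
  drop_cols <- intersect(c("web_id", "seed", "key"), names(records))
  grouped <- dplyr::select(
    grouped, -dplyr::any_of(drop_cols), -dplyr::where(is.list)
  )
  out <- dplyr::summarise(
    grouped,
    dplyr::across(
      dplyr::where(is.numeric),
      list(
        mean = ~ mean(.x, na.rm = TRUE),
        sd = ~ stats::sd(.x, na.rm = TRUE)
      ),
      .names = "{.col}_{.fn}"
    ),
    n_replicates = dplyr::n(),
    n_failed = if ("failure" %in% names(dplyr::pick(dplyr::everything()))) {
      sum(!is.na(.data$failure))
    } else {
      0L
    },
    .groups = "drop"
  )
  # conditions with many failures are suspect; flag them
  out$high_failure <- out$n_failed > 0.2 * out$n_replicates
  out
}

#' Write experiment records to CSV
#'
#' Deterministic column order, UTF-8, list-columns dropped (the nested
#' strength sweeps of HOI records are unnested into a second file with
#' suffix `_sweeps`).
#'
#' @param records a records tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  flat <- records[, !vapply(records, is.list, logical(1)), drop = FALSE]
  utils::write.csv(flat, path, row.names = FALSE, fileEncoding = "UTF-8")
  if ("sweep" %in% names(records)) {
    sweeps <- tidyr::unnest(
      records[, c("scenario", "N", "sweep")],
      cols = "sweep"
    )
    utils::write.csv(
      sweeps, sub("(\\.csv)?$", "_sweeps.csv", path, perl = TRUE),
      row.names = FALSE, fileEncoding = "UTF-8"
    )
  }
  invisible(path)
}
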