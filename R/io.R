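# Plain-text serialisation: edge lists as TSV with a JSON sidecar, matrices
# and TIM sets as dense CSV.

#' Read and write food webs
#'
#' Webs are stored as a two-column tab-separated edge list
#' (`consumer_id`, `resource_id`, 0-based ids) plus a JSON sidecar
#' (`<path>.json`) holding `S`, the niche values, the target connectance and
#' an optional seed.
#'
#' @param web a `food_web`.
#' @param path edge-list file path.
#' @param seed optional integer recorded in the sidecar.
#' @return `write_food_web()`: `path`, invisibly. `read_food_web()`: a
#'   `food_web`.
#' @export
write_food_web <- function(web, path, seed = NULL) {
  stopifnot(inherits(web, "food_web"))
  edges <- data.frame(
    consumer_id = web$links[, "consumer"] - 1L,
    resource_id = web$links[, "resource"] - 1L
  )
  utils::write.table(edges, path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  sidecar <- list(
    S = web$S, niche = web$niche,
    target_connectance = web$target_connectance
  )
  if (!is.null(seed)) sidecar$seed <- seed
  writeLines(
    jsonlite::toJSON(sidecar, auto_unbox = TRUE, digits = NA),
    paste0(path, ".json")
  )
  invisible(path)
}

#' @rdname write_food_web
#' @export
read_food_web <- function(path) {
  edges <- utils::read.table(path, header = TRUE, sep = "\t")
  sidecar <- jsonlite::fromJSON(paste0(path, ".json"))
  new_food_web(
    S = sidecar$S,
    links = cbind(
      consumer = edges$consumer_id + 1L,
      resource = edges$resource_id + 1L
    ),
    niche = sidecar$niche,
    target_connectance = sidecar$target_connectance
  )
}

#' Read and write interaction matrices as dense CSV
#'
#' Dense CSV with species ids as header row and first column.
#'
#' @param M a square matrix.
#' @param path file path.
#' @param role optional role tag (`trophic`, `nontrophic`, `combined`)
#'   restored on read via the matching attribute.
#' @return `write_matrix_csv()`: `path`, invisibly; `read_matrix_csv()`: the
#'   matrix.
#' @export
write_matrix_csv <- function(M, path, role = attr(M, "role")) {
  stop_if_not_square(M, "M")
  S <- nrow(M)
  dimnames(M) <- list(seq_len(S), seq_len(S))
  df <- data.frame(species = rownames(M), M, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path, role = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  dimnames(M) <- NULL
  if (!is.null(role)) attr(M, "role") <- role
  M
}

#' Write a TIM set to CSV
#'
#' Columns `model`, `i`, `j`, `k`, `c`.
#'
#' @param tims a `tim_set`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_tim_set <- function(tims, path) {
  utils::write.csv(tidy(tims), path, row.names = FALSE)
  invisible(path)
}
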