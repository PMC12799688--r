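# Small hand-built topologies used across test files.

# star web: one hub consumer (species n + 1) eating n resources
star_web <- function(n_resources = 3) {
  food_web(cbind(n_resources + 1L, seq_len(n_resources)), S = n_resources + 1L)
}

# fully bidirectionally connected 3-species web (every ordered pair a link)
full_web3 <- function() {
  links <- expand.grid(consumer = 1:3, resource = 1:3)
  links <- links[links$consumer != links$resource, ]
  food_web(as.matrix(links), S = 3)
}

# random stable matrix with negative diagonal, for feasibility checks
random_stable_matrix <- function(S) {
  repeat {
    A <- matrix(stats::rnorm(S^2, sd = 0.3), S, S)
    diag(A) <- -1
    if (max(Re(eigen(A, only.values = TRUE)$values)) < 0) {
      return(A)
    }
  }
}
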