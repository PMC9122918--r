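# Shared fixtures, built in code at test time.

default_series <- function(seed = 1) generate_chemostat_series(seed = seed)

default_proteome <- function(series = default_series(), seed = 1, ...) {
  generate_proteome(series, seed = seed, ...)
}

# a tiny linear-chain model: uptake -> A -> B -> export
chain_model <- function(parallel = FALSE) {
  mets <- data.frame(
    id = c("A", "B"), external = FALSE, stringsAsFactors = FALSE
  )
  rx <- list(
    EX_in = list(c(A = -1), -1, 0),
    R1 = list(c(A = -1, B = 1), 0, 1000),
    EX_out = list(c(B = -1), 0, 1000)
  )
  if (parallel) {
    rx <- append(rx, list(R2 = list(c(A = -1, B = 1), 0, 1000)), after = 2)
  }
  metabolic_model(
    mets,
    data.frame(
      id = names(rx),
      lb = vapply(rx, `[[`, 0, 2), ub = vapply(rx, `[[`, 0, 3),
      stringsAsFactors = FALSE
    ),
    lapply(rx, `[[`, 1),
    objective = "EX_out"
  )
}

# midpoint-rule quadrature of the normal mass over [l, u], log scale
quadrature_interval_term <- function(mu, sd, l, u, n = 40001) {
  if (u <= l) {
    return(stats::dnorm(l, mu, sd, log = TRUE))
  }
  h <- (u - l) / n
  xs <- l + (seq_len(n) - 0.5) * h
  log(sum(stats::dnorm(xs, mu, sd)) * h) - log(u - l)
}

# hand rank-based Spearman: average ranks + product-moment formula
spearman_oracle <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- mean(which(sort(v) == v[i]))
    r
  }
  rx <- avg_rank(x)
  ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
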