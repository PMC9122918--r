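#' Functional-group mass fractions
#'
#' Aggregates an abundance table into per-group fractions per condition:
#' `fraction(g, c) = sum_{i in g} w_i x_ic / sum_i w_i x_ic`. With molecular
#' weights as `weights` and copies-per-cell abundances this yields proteome
#' mass fractions; without weights, molecule fractions. Entities missing
#' from the category map fall into `"other"`.
#'
#' @param abundances an [omics_table()].
#' @param category_map data frame (`entity_id`, `category`); each entity may
#'   appear at most once.
#' @param weights optional named vector of per-entity mass weights (e.g.
#'   molecular weights in kDa).
#' @return matrix group x condition of fractions; columns sum to 1.
#' @export
compute_group_fractions <- function(abundances, category_map, weights = NULL) {
  stopifnot(inherits(abundances, "omics_table"))
  if (anyDuplicated(category_map$entity_id)) {
    dup <- category_map$entity_id[duplicated(category_map$entity_id)][1]
    stop("entity mapped to two categories: ", dup)
  }
  vals <- abundances$values
  if (!is.null(weights)) {
    w <- weights[rownames(vals)]
    if (any(is.na(w))) stop("weights missing for some entities")
    vals <- vals * w
  }
  cat_of <- stats::setNames(category_map$category, category_map$entity_id)
  grp <- unname(cat_of[rownames(vals)])
  grp[is.na(grp)] <- "other"
  tot <- colSums(vals)
  if (any(tot <= 0)) {
    stop(
      "condition with non-positive total abundance: ",
      colnames(vals)[which(tot <= 0)[1]]
    )
  }
  agg <- rowsum(vals, grp)
  sweep(agg, 2, tot, `/`)
}

new_allocation_fit <- function(group, mode, breakpoint, segments, rss) {
  structure(
    list(
      group = group, mode = mode, breakpoint = breakpoint,
      segments = segments, rss = rss
    ),
    class = "allocation_fit"
  )
}

#' @export
print.allocation_fit <- function(x, ...) {
  cat("allocation_fit (", x$mode, ")")
  if (!is.na(x$breakpoint %||% NA)) cat(", breakpoint =", x$breakpoint)
  cat("\n")
  print(x$segments)
  invisible(x)
}

ols_segment <- function(fractions, mu) {
  if (stats::sd(fractions) == 0) {
    # degenerate: flat data; Pearson r undefined rather than 0
    return(data.frame(
      slope = 0, intercept = fractions[1], pearson_r = NA_real_
    ))
  }
  fit <- stats::lm(fractions ~ mu)
  data.frame(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    pearson_r = stats::cor(mu, fractions)
  )
}

#' Fit a linear allocation law
#'
#' Ordinary least squares of group fraction on growth rate, with the Pearson
#' correlation of the fit. Zero-variance fractions give slope 0 and an
#' undefined (NA) correlation.
#'
#' @param fractions fraction vector (one per condition).
#' @param mu strictly increasing growth-rate vector, length >= 3.
#' @param group optional group label carried into the result.
#' @return an `allocation_fit` with `mode = "single"`.
#' @export
fit_linear_allocation <- function(fractions, mu, group = NA_character_) {
  if (length(fractions) != length(mu) || length(mu) < 3) {
    stop("need matched fraction/mu vectors of length >= 3")
  }
  if (any(diff(mu) <= 0)) stop("mu must be strictly increasing")
  seg <- ols_segment(fractions, mu)
  pred <- seg$slope * mu + seg$intercept
  new_allocation_fit(group, "single", NA_real_, seg, sum((fractions - pred)^2))
}

#' Fit a piecewise-linear allocation law
#'
#' Two OLS segments split at a breakpoint (the point at the breakpoint
#' belongs to both segments). With `breakpoint = "estimate"` the breakpoint
#' is chosen by exhaustive search over interior growth rates, minimizing the
#' total residual sum of squares; ties resolve to the smallest candidate.
#'
#' @param fractions fraction vector.
#' @param mu strictly increasing growth-rate vector.
#' @param breakpoint numeric rate, or `"estimate"`.
#' @param group optional label.
#' @return an `allocation_fit` with `mode = "piecewise"`; `segments` has one
#'   row per segment (below, above).
#' @export
fit_piecewise_allocation <- function(fractions, mu, breakpoint = "estimate",
                                     group = NA_character_) {
  if (length(fractions) != length(mu)) stop("length mismatch")
  if (any(diff(mu) <= 0)) stop("mu must be strictly increasing")
  fit_at <- function(bp) {
    lo <- mu <= bp
    hi <- mu >= bp
    if (sum(lo) < 3 || sum(hi) < 3) {
      return(NULL)
    }
    s1 <- ols_segment(fractions[lo], mu[lo])
    s2 <- ols_segment(fractions[hi], mu[hi])
    rss <- sum((fractions[lo] - (s1$slope * mu[lo] + s1$intercept))^2) +
      sum((fractions[hi] - (s2$slope * mu[hi] + s2$intercept))^2)
    segs <- rbind(s1, s2)
    segs$segment <- c("below", "above")
    new_allocation_fit(group, "piecewise", bp, segs, rss)
  }
  if (identical(breakpoint, "estimate")) {
    candidates <- mu[mu > min(mu) & mu < max(mu)]
    fits <- Filter(Negate(is.null), lapply(candidates, fit_at))
    if (!length(fits)) stop("too few points for any valid breakpoint split")
    rss <- vapply(fits, `[[`, 0, "rss")
    # ties (within numerical noise) resolve to the smallest breakpoint
    best <- which(rss <= min(rss) + 1e-12)[1]
    fits[[best]]
  } else {
    if (breakpoint <= min(mu) || breakpoint >= max(mu)) {
      stop("breakpoint must lie strictly inside the mu range")
    }
    out <- fit_at(breakpoint)
    if (is.null(out)) stop("too few points per segment at this breakpoint")
    out
  }
}

#' Detect the critical (Crabtree) and decoupling rates
#'
#' The critical rate is the smallest growth rate with ethanol secretion
#' above `ethanol_threshold`; the decoupling rate is the smallest with
#' RQ > 1 + `rq_tolerance`. Either is `NA` when never exceeded.
#'
#' @param series a `chemostat_series`.
#' @param ethanol_threshold flux threshold (default 1e-6).
#' @param rq_tolerance RQ tolerance (default 1e-6).
#' @return list with `critical_rate` and `decoupling_rate`.
#' @export
detect_critical_rate <- function(series, ethanol_threshold = 1e-6,
                                 rq_tolerance = 1e-6) {
  if (ethanol_threshold < 0) stop("threshold must be >= 0")
  eth <- which(series$q_etoh > ethanol_threshold)
  dec <- which(series$rq > 1 + rq_tolerance)
  list(
    critical_rate = if (length(eth)) series$mu[min(eth)] else NA_real_,
    decoupling_rate = if (length(dec)) series$mu[min(dec)] else NA_real_
  )
}

#' Respiratory quotient
#'
#' CO2 production rate over the magnitude of O2 consumption.
#'
#' @param q_co2 CO2 production flux (positive).
#' @param q_o2 O2 exchange flux (nonzero; uptake negative by convention).
#' @return `q_co2 / abs(q_o2)`.
#' @export
respiratory_quotient <- function(q_co2, q_o2) {
  if (any(q_o2 == 0)) stop("zero O2 uptake: RQ undefined")
  q_co2 / abs(q_o2)
}

#' Approximate ribosome translation rate
#'
#' Order-of-magnitude estimate of the elongation rate: the proteome-wide
#' residue synthesis demand `mu * total residues per cell` divided by the
#' ribosome count, with ribosomes counted as translation-group residue mass
#' over `residues_per_ribosome`. The result is flagged approximate - it
#' ignores the active-ribosome fraction and uses a uniform residue count
#' per protein unless a per-protein map is given.
#'
#' @param proteome [omics_table()] in copies per cell (one or more
#'   conditions).
#' @param category_map data frame (`entity_id`, `category`) with a
#'   `translation` category.
#' @param mu growth rate (1/h) of the chosen condition.
#' @param condition condition id (default: first column).
#' @param residues_per_ribosome amino acids per ribosome (default 12000).
#' @param residues_per_protein single value or named per-entity vector
#'   (default 450).
#' @return amino acids per ribosome per second, with attribute
#'   `approximate = TRUE`.
#' @export
translation_rate <- function(proteome, category_map, mu,
                             condition = colnames(proteome$values)[1],
                             residues_per_ribosome = 12000,
                             residues_per_protein = 450) {
  stopifnot(mu > 0, residues_per_ribosome > 0)
  copies <- proteome$values[, condition]
  res <- if (length(residues_per_protein) == 1) {
    rep(residues_per_protein, length(copies))
  } else {
    unname(residues_per_protein[names(copies)])
  }
  total_residues <- sum(copies * res)
  cat_of <- stats::setNames(category_map$category, category_map$entity_id)
  trans <- names(copies)[cat_of[names(copies)] %in% "translation"]
  ribo_residues <- sum(copies[trans] * res[match(trans, names(copies))])
  if (!length(trans) || ribo_residues == 0) {
    stop("zero translation-group mass: cannot count ribosomes")
  }
  n_ribosomes <- ribo_residues / residues_per_ribosome
  k <- (mu / 3600) * total_residues / n_ribosomes
  attr(k, "approximate") <- TRUE
  k
}
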