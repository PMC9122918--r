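#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. The p value uses the exact
#' permutation distribution for n <= `exact_max` without ties (where the
#' large-sample approximation is weak) and the t approximation otherwise.
#'
#' @param x,y numeric vectors of equal length >= 3; pairs with missing
#'   values are dropped.
#' @param exact_max largest n for which the exact p value is used
#'   (default 9).
#' @return list with `r`, `p`, `n`. A constant vector gives `r = NA`.
#' @export
spearman <- function(x, y, exact_max = 9) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  rx <- rank(x)
  ry <- rank(y)
  r <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  p <- if (n <= exact_max && !ties) {
    suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
    )
  } else if (abs(r) >= 1) {
    0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = unname(r), p = unname(p), n = n)
}

#' Pearson correlation
#'
#' Product-moment correlation with a two-sided t-test p value.
#'
#' @inheritParams spearman
#' @return list with `r`, `p`, `n`; constant input gives `r = NA`.
#' @export
pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; monotone and capped at 1.
#'
#' @param p_values vector of p values in \[0, 1\] (NA allowed).
#' @return adjusted q values.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Correlate two omics tables entity by entity
#'
#' Pairs entities of `a` and `b` (directly by id, or through a two-column
#' id map such as gene-reaction links), computes the chosen correlation per
#' pair across shared conditions, adjusts p values by Benjamini-Hochberg,
#' and calls significance by sign at `q < alpha`. Pairs with fewer than 3
#' complete observations are suppressed.
#'
#' @param a,b [omics_table()]s (or plain matrices for `b`, e.g. fluxes).
#' @param method `"spearman"` or `"pearson"`.
#' @param alpha FDR threshold (default 0.05).
#' @param id_map optional data frame with columns `a_id`, `b_id`.
#' @return data frame of correlation records: `entity`, `b_entity`, `r`,
#'   `p_value`, `q_value`, `n`, `call`.
#' @export
correlate_table <- function(a, b, method = c("spearman", "pearson"),
                            alpha = 0.05, id_map = NULL) {
  method <- match.arg(method)
  av <- if (inherits(a, "omics_table")) a$values else as.matrix(a)
  bv <- if (inherits(b, "omics_table")) b$values else as.matrix(b)
  shared_cond <- intersect(colnames(av), colnames(bv))
  if (length(shared_cond) < 3) stop("need at least 3 shared conditions")
  if (is.null(id_map)) {
    ids <- intersect(rownames(av), rownames(bv))
    id_map <- data.frame(a_id = ids, b_id = ids, stringsAsFactors = FALSE)
  }
  keep <- id_map$a_id %in% rownames(av) & id_map$b_id %in% rownames(bv)
  dropped <- sum(!keep)
  if (dropped) {
    message(dropped, " mapped pair(s) dropped: entity not present in both tables")
  }
  id_map <- id_map[keep, , drop = FALSE]
  if (!nrow(id_map)) stop("no shared entities between the two tables")
  fun <- if (method == "spearman") spearman else pearson
  rec <- lapply(seq_len(nrow(id_map)), function(i) {
    x <- av[id_map$a_id[i], shared_cond]
    y <- bv[id_map$b_id[i], shared_cond]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) {
      return(NULL)
    }
    s <- fun(x[ok], y[ok])
    data.frame(
      entity = id_map$a_id[i], b_entity = id_map$b_id[i],
      r = s$r, p_value = s$p, n = s$n, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, Filter(Negate(is.null), rec))
  if (is.null(out)) stop("no pair had 3 complete observations")
  out$q_value <- bh_adjust(out$p_value)
  out$call <- ifelse(
    is.na(out$q_value) | out$q_value >= alpha, "ns",
    ifelse(out$r > 0, "significant_positive", "significant_negative")
  )
  rownames(out) <- NULL
  out
}

#' One-sided set enrichment
#'
#' Hypergeometric upper-tail (one-sided Fisher) enrichment of `hits` within
#' each annotation set against `background`, with Benjamini-Hochberg
#' adjustment across sets.
#'
#' @param hits character vector of significant entities (subset of
#'   `background`).
#' @param background character vector of all tested entities.
#' @param annotation named list: set name -> member entities.
#' @param alpha FDR threshold for the `enriched` flag (default 0.05).
#' @return data frame `set`, `hits_in_set`, `set_size`, `p`, `q`,
#'   `enriched`.
#' @export
enrich <- function(hits, background, annotation, alpha = 0.05) {
  if (!length(background)) stop("empty background")
  hits <- intersect(hits, background)
  res <- lapply(names(annotation), function(s) {
    members <- intersect(annotation[[s]], background)
    k <- length(intersect(hits, members))
    # hypergeometric upper tail P(X >= k)
    p <- stats::phyper(k - 1, length(members),
      length(background) - length(members), length(hits),
      lower.tail = FALSE
    )
    data.frame(
      set = s, hits_in_set = k, set_size = length(members),
      p = p, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out$enriched <- out$q < alpha
  rownames(out) <- NULL
  out
}
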