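#' Piecewise-linear proteome allocation laws
#'
#' An allocation law describes the mass fraction of the proteome assigned to
#' one functional group as a continuous piecewise-linear function of the
#' specific growth rate. `allocation_law()` builds one from per-segment
#' slopes/intercepts; `predict_allocation()` evaluates it.
#'
#' @param group category name.
#' @param segments data frame with columns `mu_lo`, `mu_hi`, `slope`,
#'   `intercept` (fraction scale); segments must tile the mu range without
#'   gaps and meet continuously at the breakpoints.
#' @return an `allocation_law` object.
#' @export
allocation_law <- function(group, segments) {
  segments <- as.data.frame(segments)
  stopifnot(all(c("mu_lo", "mu_hi", "slope", "intercept") %in% names(segments)))
  segments <- segments[order(segments$mu_lo), , drop = FALSE]
  if (nrow(segments) > 1) {
    for (k in seq_len(nrow(segments) - 1)) {
      if (abs(segments$mu_hi[k] - segments$mu_lo[k + 1]) > 1e-12) {
        stop("allocation law segments for '", group, "' leave a gap")
      }
      b <- segments$mu_hi[k]
      left <- segments$slope[k] * b + segments$intercept[k]
      right <- segments$slope[k + 1] * b + segments$intercept[k + 1]
      if (abs(left - right) > 1e-9) {
        stop("allocation law segments for '", group, "' are discontinuous at ", b)
      }
    }
  }
  structure(
    list(
      group = group, segments = segments,
      breakpoints = segments$mu_hi[-nrow(segments)]
    ),
    class = "allocation_law"
  )
}

# Single- or two-segment law helper: constant slope `slope1` up to `bp`,
# then `slope2`, continuous at the breakpoint.
two_segment_law <- function(group, f0, slope1, bp, slope2, mu_hi = Inf) {
  f_bp <- f0 + slope1 * bp
  allocation_law(group, data.frame(
    mu_lo = c(0, bp), mu_hi = c(bp, mu_hi),
    slope = c(slope1, slope2),
    intercept = c(f0, f_bp - slope2 * bp)
  ))
}

#' @rdname allocation_law
#' @param law an `allocation_law`.
#' @param mu vector of growth rates (1/h).
#' @export
predict_allocation <- function(law, mu) {
  seg <- law$segments
  out <- rep(NA_real_, length(mu))
  for (k in seq_len(nrow(seg))) {
    # right-closed so a rate sitting exactly on a breakpoint uses the upper
    # segment; continuity makes the choice value-neutral
    sel <- mu >= seg$mu_lo[k] & (mu < seg$mu_hi[k] | k == nrow(seg))
    out[sel] <- seg$slope[k] * mu[sel] + seg$intercept[k]
  }
  out
}

#' Default functional-group allocation laws
#'
#' The eleven-category default mirrors the canonical chemostat allocation
#' pattern: the translation (ribosomal) fraction follows the growth law
#' 0.35*mu + 0.13 over the whole range; amino acid biosynthesis rises to a
#' 13% plateau at the critical rate; the mitochondrial fraction rises below
#' the critical rate and declines with slope -0.14 above it; glycolysis and
#' chaperones decline under respiration and flatten after the switch; lipid
#' metabolism is constant then declining; four smaller housekeeping groups
#' are constant; the unnamed remainder of the proteome ("other") absorbs
#' whatever fraction is left so the columns always sum to one.
#'
#' @param critical_rate breakpoint growth rate (1/h).
#' @return named list of [allocation_law()] objects (without "other").
#' @export
default_allocation_laws <- function(critical_rate = 0.28) {
  bp <- critical_rate
  laws <- list(
    allocation_law("translation", data.frame(
      mu_lo = 0, mu_hi = Inf, slope = 0.35, intercept = 0.13
    )),
    two_segment_law("amino_acid_biosynthesis", 0.04, 0.09 / bp, bp, 0),
    two_segment_law("mitochondria", 0.10, 0.20, bp, -0.14),
    two_segment_law("glycolysis", 0.15, -0.15, bp, 0),
    two_segment_law("chaperones", 0.08, -0.10, bp, 0),
    two_segment_law("lipid_metabolism", 0.03, 0, bp, -0.02),
    allocation_law("nucleotide_biosynthesis", data.frame(
      mu_lo = 0, mu_hi = Inf, slope = 0, intercept = 0.030
    )),
    allocation_law("transport", data.frame(
      mu_lo = 0, mu_hi = Inf, slope = 0, intercept = 0.025
    )),
    allocation_law("stress_response", data.frame(
      mu_lo = 0, mu_hi = Inf, slope = 0, intercept = 0.020
    )),
    allocation_law("cell_cycle", data.frame(
      mu_lo = 0, mu_hi = Inf, slope = 0, intercept = 0.015
    ))
  )
  stats::setNames(laws, vapply(laws, `[[`, "", "group"))
}

#' Generate a synthetic absolute proteome
#'
#' Builds a copies-per-cell proteome whose functional-group mass fractions
#' follow the supplied allocation laws exactly (at `cv_noise = 0`). Each
#' group's mass is split over its proteins by a fixed lognormal composition
#' that does not change across conditions; molecular weights are drawn once
#' per protein, and mass fractions are converted to molecule counts using
#' the per-condition protein content of the series.
#'
#' @param series a [generate_chemostat_series()] result.
#' @param laws named list of [allocation_law()]s (default
#'   [default_allocation_laws()] at the series' critical rate). An "other"
#'   group automatically absorbs the remaining mass fraction.
#' @param n_proteins_per_group proteins simulated per category.
#' @param cv_noise coefficient of variation of multiplicative measurement
#'   noise (0 = noiseless).
#' @param seed integer seed.
#' @param composition_sdlog natural-log SD of the within-group abundance
#'   composition (default 1.5, giving the several-decade dynamic range seen
#'   in absolute proteomes).
#' @return list with elements `proteome` ([omics_table()], copies per cell),
#'   `categories` (data frame `entity_id`, `category`), `mw` (named vector,
#'   kDa), and `fractions` (true group-by-condition mass-fraction matrix).
#' @export
generate_proteome <- function(series,
                              laws = default_allocation_laws(
                                attr(series, "critical_rate") %||% 0.28
                              ),
                              n_proteins_per_group = 227,
                              cv_noise = 0,
                              seed = 1,
                              composition_sdlog = 1.5) {
  mu <- series$mu
  cond <- series$condition
  groups <- vapply(laws, `[[`, "", "group")
  frac <- vapply(laws, predict_allocation, numeric(length(mu)), mu = mu)
  frac <- t(frac) # group x condition
  dimnames(frac) <- list(groups, cond)
  if (any(frac <= 0)) {
    bad <- which(frac <= 0, arr.ind = TRUE)[1, ]
    stop(
      "allocation law '", groups[bad[1]], "' predicts a non-positive ",
      "fraction at condition ", cond[bad[2]]
    )
  }
  tot <- colSums(frac)
  if (any(tot >= 1)) {
    stop(
      "allocation laws predict fraction sums >= 1 at condition ",
      cond[which(tot >= 1)[1]]
    )
  }
  frac <- rbind(frac, other = 1 - tot)
  all_groups <- c(groups, "other")

  with_seed(seed, {
    n_g <- length(all_groups)
    n_p <- n_proteins_per_group * n_g
    ids <- sprintf("P%04d", seq_len(n_p))
    category <- rep(all_groups, each = n_proteins_per_group)
    mw <- exp(stats::rnorm(n_p, log(50), 0.35)) # kDa
    names(mw) <- ids

    # fixed within-group composition of mass
    w <- exp(stats::rnorm(n_p, 0, composition_sdlog))
    for (g in all_groups) {
      sel <- category == g
      w[sel] <- w[sel] / sum(w[sel])
    }

    mass_frac <- w * frac[category, , drop = FALSE] # protein x condition
    protein_pg <- series$protein_content
    copies <- sweep(mass_frac, 2, protein_pg * 1e-12 * AVOGADRO, `*`) /
      (mw * 1000)
    if (cv_noise > 0) {
      copies <- copies * matrix(
        lognormal_noise(length(copies), cv_noise),
        nrow = nrow(copies)
      )
    }
    rownames(copies) <- ids
    colnames(copies) <- cond

    list(
      proteome = omics_table(copies, unit = "copies_per_cell"),
      categories = data.frame(
        entity_id = ids, category = category,
        stringsAsFactors = FALSE
      ),
      mw = mw,
      fractions = frac
    )
  })
}

#' Generate a synthetic transcriptome coupled to a proteome
#'
#' Per gene, (log mRNA, log protein) pairs follow a bivariate model: a
#' gene-specific protein-per-mRNA offset drawn from a lognormal with wide
#' spread (emulating the orders-of-magnitude range of protein/mRNA ratios),
#' and within-gene log deviations across conditions correlated with the
#' protein deviations at `within_gene_log_correlation`. Defaults are chosen
#' so the pooled log-log regression of protein on mRNA over all
#' gene-condition points has a coefficient of determination near 0.52.
#'
#' @param proteome an [omics_table()] in copies per cell.
#' @param log_ratio_mean mean of the natural-log protein/mRNA ratio
#'   (default 5, i.e. ~150 protein molecules per mRNA).
#' @param log_ratio_sd SD of the gene-specific log ratio (default 1.75, calibrated so the pooled log-log R-squared of protein on mRNA is ~0.52 under the default proteome).
#' @param within_gene_log_correlation correlation of within-gene log
#'   deviations (default 0.72).
#' @param seed integer seed.
#' @return an [omics_table()] of mRNA copies per cell, same dimensions as
#'   `proteome`.
#' @export
generate_transcriptome <- function(proteome,
                                   log_ratio_mean = 5,
                                   log_ratio_sd = 1.75,
                                   within_gene_log_correlation = 0.72,
                                   seed = 1) {
  stopifnot(inherits(proteome, "omics_table"))
  if (proteome$unit != "copies_per_cell") {
    stop("proteome must be in copies_per_cell")
  }
  rho <- within_gene_log_correlation
  if (rho < -1 || rho > 1) stop("correlation must lie in [-1, 1]")
  if (log_ratio_sd < 0) stop("configuration error: log_ratio_sd must be >= 0")

  lp <- log(proteome$values)
  n_g <- nrow(lp)
  n_c <- ncol(lp)
  gene_mean <- rowMeans(lp)
  dev <- lp - gene_mean

  with_seed(seed, {
    beta <- stats::rnorm(n_g, log_ratio_mean, log_ratio_sd)
    # within-gene deviation scale preserved; orthogonal noise completes the
    # target correlation
    s_g <- sqrt(rowMeans(dev^2))
    noise <- matrix(stats::rnorm(n_g * n_c), n_g, n_c) * s_g
    lm_mat <- (gene_mean - beta) + rho * dev + sqrt(1 - rho^2) * noise
    mrna <- exp(lm_mat)
    dimnames(mrna) <- dimnames(proteome$values)
    omics_table(mrna, unit = "copies_per_cell")
  })
}

#' Generate a synthetic phosphoproteome
#'
#' Simulates phosphopeptide intensities on top of a proteome: each protein
#' carries `n_peptides_per_protein` phosphopeptides with lognormal baseline
#' intensities. For categories named in `trend_spec`, the configured fraction
#' of peptides receives a monotone intensity trend versus the growth rate
#' (e.g. the linear decline of glycolytic phosphosites as cells grow faster);
#' the remaining peptides are flat.
#'
#' @param proteome an [omics_table()].
#' @param categories data frame (`entity_id`, `category`) mapping proteins to
#'   functional groups.
#' @param mu growth-rate vector matching the proteome's conditions.
#' @param trend_spec named list, `category = list(direction, fraction)` with
#'   direction one of `"increasing"`, `"decreasing"`, `"flat"` and fraction
#'   in \[0, 1\]. Default: all glycolytic peptides decreasing.
#' @param n_peptides_per_protein phosphopeptides per protein (default 2).
#' @param cv_noise multiplicative noise CV (default 0).
#' @param trend_logfc total natural-log intensity change across the mu range
#'   for trended peptides (default 1.5).
#' @param seed integer seed.
#' @return list with `phospho` ([omics_table()], intensities) and
#'   `peptide_map` (data frame `peptide_id`, `protein_id`, `category`,
#'   `trend`).
#' @export
generate_phosphoproteome <- function(proteome,
                                     categories,
                                     mu,
                                     trend_spec = list(
                                       glycolysis = list("decreasing", 1.0)
                                     ),
                                     n_peptides_per_protein = 2,
                                     cv_noise = 0,
                                     trend_logfc = 1.5,
                                     seed = 1) {
  stopifnot(inherits(proteome, "omics_table"))
  if (length(mu) != ncol(proteome$values)) {
    stop("mu must have one value per proteome condition")
  }
  for (spec in trend_spec) {
    dir <- spec[[1]]
    if (!dir %in% c("increasing", "decreasing", "flat")) {
      stop("configuration error: unknown trend direction '", dir, "'")
    }
    fr <- spec[[2]]
    if (fr < 0 || fr > 1) {
      stop("configuration error: trend fraction must lie in [0, 1]")
    }
  }
  cat_of <- stats::setNames(categories$category, categories$entity_id)
  prot_ids <- rownames(proteome$values)
  n_pep <- length(prot_ids) * n_peptides_per_protein

  with_seed(seed, {
    protein_id <- rep(prot_ids, each = n_peptides_per_protein)
    peptide_id <- sprintf("%s_ph%d", protein_id, seq_len(n_peptides_per_protein))
    category <- unname(cat_of[protein_id])
    trend <- rep("flat", n_pep)
    for (g in names(trend_spec)) {
      dir <- trend_spec[[g]][[1]]
      fr <- trend_spec[[g]][[2]]
      sel <- which(category == g)
      if (length(sel) && dir != "flat" && fr > 0) {
        n_tr <- ceiling(fr * length(sel))
        trend[sel[seq_len(n_tr)]] <- dir
      }
    }
    base <- exp(stats::rnorm(n_pep, log(1e6), 1))
    mu_scaled <- (mu - min(mu)) / (max(mu) - min(mu))
    slope <- ifelse(trend == "increasing", trend_logfc,
      ifelse(trend == "decreasing", -trend_logfc, 0)
    )
    intensity <- base * exp(outer(slope, mu_scaled))
    if (cv_noise > 0) {
      intensity <- intensity * matrix(
        lognormal_noise(length(intensity), cv_noise),
        nrow = nrow(intensity)
      )
    }
    rownames(intensity) <- peptide_id
    colnames(intensity) <- colnames(proteome$values)
    list(
      phospho = omics_table(intensity, unit = "intensity"),
      peptide_map = data.frame(
        peptide_id = peptide_id, protein_id = protein_id,
        category = category, trend = trend, stringsAsFactors = FALSE
      )
    )
  })
}
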