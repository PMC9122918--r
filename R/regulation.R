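#' Enzyme hierarchical regulation coefficient
#'
#' Between two steady states, `rho_e = ln(e_test/e_ref) / ln(J_test/J_ref)`:
#' the share of the flux change explained by the enzyme-abundance change.
#' Values in the open band (0.5, 1.5) classify the reaction as regulated
#' mainly by enzyme abundance. Zero or sign-flipping fluxes make the
#' coefficient undefined.
#'
#' @param e_ref,e_test positive enzyme abundances at the reference and test
#'   conditions.
#' @param J_ref,J_test fluxes of equal sign at the two conditions.
#' @param band classification band (default `c(0.5, 1.5)`).
#' @return list with `rho_e`, `classification`
#'   (`"enzyme_regulated"`, `"not_enzyme_regulated"` or `"undefined"`) and
#'   `reason` when undefined.
#' @export
rho_e <- function(e_ref, e_test, J_ref, J_test, band = c(0.5, 1.5)) {
  if (e_ref <= 0 || e_test <= 0) stop("enzyme abundances must be positive")
  undef <- function(reason) {
    list(rho_e = NA_real_, classification = "undefined", reason = reason)
  }
  if (J_ref == 0 || J_test == 0) {
    return(undef("zero flux"))
  }
  if (sign(J_ref) != sign(J_test)) {
    return(undef("flux sign flip"))
  }
  lj <- log(J_test / J_ref)
  if (lj == 0) {
    return(undef("zero flux fold-change"))
  }
  rho <- log(e_test / e_ref) / lj
  list(
    rho_e = rho,
    classification = if (rho > band[1] && rho < band[2]) {
      "enzyme_regulated"
    } else {
      "not_enzyme_regulated"
    },
    reason = NA_character_
  )
}

#' Infer a functional phosphorylation event for one peptide
#'
#' Pearson correlation between the log fold-changes of a reaction flux and a
#' phosphopeptide intensity across conditions (both relative to the same
#' reference): a significantly positive correlation is read as the
#' phosphosite activating enzyme activity, a negative one as inhibiting.
#'
#' @param flux_foldchanges fold-changes (> 0) of the flux per condition.
#' @param phospho_foldchanges matching phosphopeptide fold-changes (> 0).
#' @param alpha significance level applied to the (single-test) p value;
#'   for many peptides use [fpe_screen()] which adjusts across peptides.
#' @param log_scale set FALSE if the inputs are already log fold-changes.
#' @return list with `r`, `p`, `call` (`"activating"`, `"inhibiting"`,
#'   `"none"`).
#' @export
infer_fpe <- function(flux_foldchanges, phospho_foldchanges, alpha = 0.05,
                      log_scale = TRUE) {
  if (length(flux_foldchanges) != length(phospho_foldchanges)) {
    stop("fold-change vectors must match")
  }
  x <- if (log_scale) log2(flux_foldchanges) else flux_foldchanges
  y <- if (log_scale) log2(phospho_foldchanges) else phospho_foldchanges
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("need at least 3 shared conditions")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    return(list(r = NA_real_, p = NA_real_, call = "none"))
  }
  s <- pearson(x[ok], y[ok])
  call <- if (!is.na(s$p) && s$p < alpha) {
    if (s$r > 0) "activating" else "inhibiting"
  } else {
    "none"
  }
  list(r = s$r, p = s$p, call = call)
}

#' Screen many phosphopeptides for functional phosphorylation events
#'
#' Applies [infer_fpe()] over a peptide-reaction pairing table and adjusts
#' the p values by Benjamini-Hochberg across all tested peptides before
#' calling significance.
#'
#' @param flux_fc matrix reaction x condition of fold-changes.
#' @param phospho_fc matrix peptide x condition of fold-changes.
#' @param pairing data frame with columns `peptide_id`, `reaction`.
#' @param alpha FDR threshold (default 0.05).
#' @param log_scale as in [infer_fpe()].
#' @return data frame `peptide_id`, `reaction`, `r`, `p`, `q`, `call`.
#' @export
fpe_screen <- function(flux_fc, phospho_fc, pairing, alpha = 0.05,
                       log_scale = TRUE) {
  rec <- lapply(seq_len(nrow(pairing)), function(i) {
    pep <- pairing$peptide_id[i]
    rxn <- pairing$reaction[i]
    res <- infer_fpe(flux_fc[rxn, ], phospho_fc[pep, ],
      alpha = 1, log_scale = log_scale
    )
    data.frame(
      peptide_id = pep, reaction = rxn, r = res$r, p = res$p,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rec)
  out$q <- bh_adjust(out$p)
  out$call <- ifelse(
    is.na(out$q) | out$q >= alpha, "none",
    ifelse(out$r > 0, "activating", "inhibiting")
  )
  rownames(out) <- NULL
  out
}

#' Monotone trend of an intensity series versus growth rate
#'
#' Spearman correlation of intensities against the growth rate; the sign is
#' reported when significant at `alpha`, otherwise `"flat"`.
#'
#' @param intensities intensity vector.
#' @param mu growth-rate vector (>= 3 conditions).
#' @param alpha significance level (default 0.05).
#' @return `"increasing"`, `"decreasing"` or `"flat"`.
#' @export
trend_test <- function(intensities, mu, alpha = 0.05) {
  if (length(intensities) < 3 || length(intensities) != length(mu)) {
    stop("need matched vectors over at least 3 conditions")
  }
  if (length(unique(intensities)) < 3) {
    warning("ties reduce effective sample below 3; reporting flat")
    return("flat")
  }
  s <- spearman(intensities, mu)
  if (is.na(s$r) || is.na(s$p) || s$p >= alpha) {
    return("flat")
  }
  if (s$r > 0) "increasing" else "decreasing"
}

#' Mass share of a subset within a group
#'
#' @param group_members entity ids of the group.
#' @param weights named abundance/mass vector covering the group.
#' @param subset entity ids (must be members of the group).
#' @return the fraction of group mass carried by the subset.
#' @export
mass_weighted_share <- function(group_members, weights, subset) {
  if (!all(subset %in% group_members)) {
    stop("subset must be contained in group_members")
  }
  tot <- sum(weights[group_members], na.rm = TRUE)
  if (tot == 0) stop("zero group mass")
  sum(weights[subset], na.rm = TRUE) / tot
}
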