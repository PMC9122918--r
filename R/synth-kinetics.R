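#' Ground-truth loglinear kinetics for one reaction
#'
#' Encapsulates the quantities of the loglinear thermokinetic flux model for
#' a single reaction: intrinsic turnover numbers `a_true` (one per
#' metabolite), the reference enzymatic specific flux `j0`, enzyme levels per
#' condition and metabolite concentration ratios relative to the reference
#' condition. The implied flux at condition c is
#' `J_c = e_c * (j0 + sum_i a_i * ln(Xratio_ic))`.
#'
#' @param reaction reaction id.
#' @param a_true numeric vector of intrinsic turnover numbers, named by
#'   metabolite.
#' @param j0 reference enzymatic specific flux.
#' @param e_profile positive enzyme level per condition (named vector).
#' @param x_ratio matrix metabolites x conditions of concentration ratios
#'   X_c/X_0 (> 0); the reference column must be exactly 1.
#' @param reference reference condition id (default: first condition).
#' @return a `true_kinetics` object.
#' @export
true_kinetics <- function(reaction, a_true, j0, e_profile, x_ratio,
                          reference = colnames(x_ratio)[1]) {
  x_ratio <- as.matrix(x_ratio)
  if (any(x_ratio <= 0)) stop("x_ratio_profile must be strictly positive")
  if (!is.finite(j0)) stop("j0 must be finite")
  if (any(e_profile <= 0)) stop("enzyme profile must be positive")
  if (length(a_true) != nrow(x_ratio)) {
    stop("a_true needs one entry per metabolite row of x_ratio")
  }
  if (!reference %in% colnames(x_ratio)) {
    stop("reference condition not found in x_ratio columns")
  }
  if (any(abs(x_ratio[, reference] - 1) > 1e-12)) {
    stop("reference-column ratios must be exactly 1")
  }
  j <- j0 + drop(crossprod(log(x_ratio), a_true))
  if (any(!is.finite(j))) {
    stop(
      "implied specific flux non-finite for reaction ", reaction,
      " at condition ", colnames(x_ratio)[which(!is.finite(j))[1]]
    )
  }
  structure(
    list(
      reaction = reaction,
      metabolites = rownames(x_ratio) %||% paste0("M", seq_along(a_true)),
      a_true = a_true, j0 = j0,
      e_profile = e_profile, x_ratio = x_ratio,
      reference = reference
    ),
    class = "true_kinetics"
  )
}

#' Draw a random ground-truth kinetic reaction
#'
#' Convenience generator for simulation studies: intrinsic turnover numbers
#' with magnitudes uniform on `a_magnitude` and random sign (so both
#' activating and inhibiting effects of appreciable size occur), enzyme
#' levels and metabolite ratios lognormal around 1, reference at the first
#' condition.
#'
#' @param reaction reaction id.
#' @param n_metabolites number of metabolites (I).
#' @param conditions condition ids (n > I required downstream).
#' @param seed integer seed.
#' @param a_magnitude range of |a_true| (default 0.5 to 2): allosteric
#'   effects of appreciable magnitude, on the same scale as the specific
#'   flux.
#' @param ratio_sdlog natural-log SD of metabolite ratios (default 1).
#' @param j0_range range of the uniform draw for the reference specific
#'   flux; kept on the same scale as `a_magnitude` so the empirical prior
#'   of the inference (centered on the observed specific fluxes, with their
#'   spread) is a sensible prior for the turnover numbers, mirroring their
#'   shared dimension.
#' @return a [true_kinetics()] object.
#' @export
random_true_kinetics <- function(reaction, n_metabolites, conditions, seed,
                                 a_magnitude = c(0.5, 2), ratio_sdlog = 1,
                                 j0_range = c(0, 2)) {
  with_seed(seed, {
    n <- length(conditions)
    x <- matrix(
      exp(stats::rnorm(n_metabolites * n, 0, ratio_sdlog)),
      n_metabolites, n,
      dimnames = list(paste0("M", seq_len(n_metabolites)), conditions)
    )
    x[, 1] <- 1
    a <- stats::runif(n_metabolites, a_magnitude[1], a_magnitude[2]) *
      sample(c(-1, 1), n_metabolites, replace = TRUE)
    names(a) <- rownames(x)
    e <- exp(stats::rnorm(n, 0, 0.3))
    names(e) <- conditions
    j0 <- stats::runif(1, j0_range[1], j0_range[2])
    true_kinetics(reaction, a, j0, e, x)
  })
}

#' Generate a kinetic dataset from ground truth
#'
#' Emits the observable tables of the thermokinetic analysis for a list of
#' ground-truth reactions: point fluxes (exactly consistent with the
#' loglinear model at `noise_sd = 0`), enzyme levels, metabolite ratio
#' matrices, and symmetric multiplicative flux-variability intervals
#' `point +/- fva_halfwidth * |point|`.
#'
#' @param truth list of [true_kinetics()] objects.
#' @param fva_halfwidth half-width of the FVA band as a fraction of the
#'   point flux (>= 0).
#' @param noise_sd additive Gaussian noise SD on fluxes (0 = exact).
#' @param seed integer seed.
#' @return list with `flux`, `flux_lower`, `flux_upper`, `enzyme` (reaction
#'   x condition matrices), `x_ratio` (named list of metabolite-ratio
#'   matrices) and `reference` (named character vector of reference
#'   conditions).
#' @export
generate_kinetic_dataset <- function(truth, fva_halfwidth = 0.05,
                                     noise_sd = 0, seed = 1) {
  if (fva_halfwidth < 0) stop("fva_halfwidth must be >= 0")
  if (inherits(truth, "true_kinetics")) truth <- list(truth)
  conds <- colnames(truth[[1]]$x_ratio)
  rxns <- vapply(truth, `[[`, "", "reaction")
  with_seed(seed, {
    flux <- t(vapply(truth, function(tk) {
      j <- tk$j0 + drop(crossprod(log(tk$x_ratio), tk$a_true))
      tk$e_profile * j
    }, numeric(length(conds))))
    if (noise_sd > 0) {
      flux <- flux + matrix(
        stats::rnorm(length(flux), 0, noise_sd),
        nrow = nrow(flux)
      )
    }
    enzyme <- t(vapply(truth, `[[`, numeric(length(conds)), "e_profile"))
    dimnames(flux) <- dimnames(enzyme) <- list(rxns, conds)
    list(
      flux = flux,
      flux_lower = flux - fva_halfwidth * abs(flux),
      flux_upper = flux + fva_halfwidth * abs(flux),
      enzyme = enzyme,
      x_ratio = stats::setNames(lapply(truth, `[[`, "x_ratio"), rxns),
      reference = stats::setNames(
        vapply(truth, `[[`, "", "reference"), rxns
      )
    )
  })
}
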