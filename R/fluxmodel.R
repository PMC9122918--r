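#' Enzyme-constraint parameters
#'
#' Parameters of the GECKO-style enzyme-constrained extension: the mass
#' fraction of the proteome that is metabolic enzyme, the average saturation
#' assumed for unmeasured enzymes, the total protein content, and the
#' non-growth-associated maintenance.
#'
#' @param f metabolic-enzyme mass fraction, g/g (default 0.4461).
#' @param sigma average saturation of unmeasured enzymes (default 0.49).
#' @param protein_content protein per biomass, g/gDW (default 0.46, the
#'   reference value at dilution rate 0.1/h).
#' @param ngam non-growth-associated maintenance, mmol ATP/gDW/h
#'   (default 0.7).
#' @return an `ec_params` list.
#' @export
ec_params <- function(f = 0.4461, sigma = 0.49, protein_content = 0.46,
                      ngam = 0.7) {
  stopifnot(f > 0, f <= 1, sigma > 0, sigma <= 1, protein_content > 0,
    ngam >= 0)
  structure(
    list(f = f, sigma = sigma, protein_content = protein_content, ngam = ngam),
    class = "ec_params"
  )
}

# assemble the LP matrices for a (possibly enzyme-constrained) model
build_lp_problem <- function(model, constraints = NULL) {
  S <- stoichiometry_matrix(model)
  rxns <- model$reactions$id
  lb <- stats::setNames(model$reactions$lb, rxns)
  ub <- stats::setNames(model$reactions$ub, rxns)
  if (!is.null(constraints)) {
    for (r in names(constraints)) {
      if (!r %in% rxns) stop("unknown reaction in constraints: ", r)
      lb[r] <- constraints[[r]][1]
      ub[r] <- constraints[[r]][2]
    }
  }
  n_r <- length(rxns)
  vars <- rxns
  Aineq <- NULL
  bineq <- NULL

  ec <- model$ec # NULL unless add_enzyme_constraints() was applied
  if (!is.null(ec)) {
    enz_ids <- ec$usage$enzyme
    vars <- c(rxns, paste0("u_", enz_ids))
    S <- cbind(S, matrix(0, nrow(S), length(enz_ids)))
    lb <- c(lb, stats::setNames(rep(0, length(enz_ids)), paste0("u_", enz_ids)))
    ub <- c(ub, stats::setNames(ec$usage$bound, paste0("u_", enz_ids)))
    # coupling rows v_r - kcat * u_e <= 0
    ann <- model$enzymes[model$enzymes$reaction %in% rxns, , drop = FALSE]
    rows <- list()
    for (k in seq_len(nrow(ann))) {
      row <- stats::setNames(numeric(length(vars)), vars)
      row[ann$reaction[k]] <- 1
      row[paste0("u_", ann$enzyme[k])] <- -ann$kcat[k]
      rows[[k]] <- row
    }
    Aineq <- do.call(rbind, rows)
    bineq <- rep(0, nrow(Aineq))
    # shared pool over unmeasured enzymes: sum mw_e * u_e <= pool
    un <- which(!ec$usage$measured)
    if (length(un)) {
      pool_row <- stats::setNames(numeric(length(vars)), vars)
      pool_row[paste0("u_", enz_ids[un])] <- ec$usage$mw[un]
      Aineq <- rbind(Aineq, pool_row)
      bineq <- c(bineq, ec$pool)
    }
  }
  list(
    S = S, vars = vars, lb = lb, ub = ub,
    Aineq = Aineq, bineq = bineq, rxns = rxns
  )
}

#' Flux balance analysis
#'
#' Solves the steady-state LP `S v = 0` under the model's (optionally
#' overridden) flux bounds, optimizing the objective reaction. Works on both
#' plain models and enzyme-constrained models produced by
#' [add_enzyme_constraints()].
#'
#' @param model a [metabolic_model()].
#' @param constraints named list `reaction = c(lb, ub)` overriding bounds.
#' @param objective objective reaction id (default the model's).
#' @param sense `"max"` or `"min"`.
#' @return a `flux_solution`: list with `status`, `objective_value`,
#'   `fluxes` (named vector) and, for enzyme-constrained models, `usage`
#'   (named vector of enzyme usage variables, mmol/gDW).
#' @export
fba <- function(model, constraints = NULL, objective = model$objective,
                sense = c("max", "min")) {
  sense <- match.arg(sense)
  lp <- build_lp_problem(model, constraints)
  obj <- as.numeric(lp$vars == objective)
  res <- solve_lp(obj,
    Aeq = lp$S, beq = rep(0, nrow(lp$S)),
    Aineq = lp$Aineq, bineq = lp$bineq,
    lb = lp$lb, ub = lp$ub, maximize = (sense == "max")
  )
  if (res$status != "optimal") {
    return(structure(
      list(
        status = res$status, objective_value = NA_real_,
        fluxes = NULL, usage = NULL
      ),
      class = "flux_solution"
    ))
  }
  v <- stats::setNames(res$solution, lp$vars)
  structure(
    list(
      status = "optimal",
      objective_value = res$objective,
      fluxes = v[lp$rxns],
      usage = if (length(lp$vars) > length(lp$rxns)) {
        stats::setNames(
          v[-seq_along(lp$rxns)],
          sub("^u_", "", lp$vars[-seq_along(lp$rxns)])
        )
      } else {
        NULL
      }
    ),
    class = "flux_solution"
  )
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("flux_solution:", x$status)
  if (x$status == "optimal") cat(", objective =", x$objective_value)
  cat("\n")
  invisible(x)
}

#' Flux variability analysis
#'
#' For each requested reaction, minimizes and maximizes its flux subject to
#' the model constraints and any fixed reaction values (e.g. growth fixed at
#' the measured rate).
#'
#' @param model a [metabolic_model()].
#' @param constraints named list of bound overrides, as in [fba()].
#' @param fixed named numeric vector of reaction values to pin (lb = ub).
#' @param reactions reaction ids to scan (default: all).
#' @return data frame `reaction`, `lower`, `upper`.
#' @export
fva <- function(model, constraints = NULL, fixed = NULL, reactions = NULL) {
  constraints <- constraints %||% list()
  if (!is.null(fixed)) {
    for (r in names(fixed)) constraints[[r]] <- c(fixed[r], fixed[r])
  }
  reactions <- reactions %||% model$reactions$id
  lp <- build_lp_problem(model, constraints)
  out <- data.frame(
    reaction = reactions, lower = NA_real_, upper = NA_real_,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(reactions)) {
    obj <- as.numeric(lp$vars == reactions[i])
    for (sense in c(FALSE, TRUE)) {
      res <- solve_lp(obj,
        Aeq = lp$S, beq = rep(0, nrow(lp$S)),
        Aineq = lp$Aineq, bineq = lp$bineq,
        lb = lp$lb, ub = lp$ub, maximize = sense
      )
      if (res$status != "optimal") {
        stop(
          "FVA infeasible for ", reactions[i],
          " under the fixed constraint set (",
          paste(names(fixed), collapse = ", "), ")"
        )
      }
      out[i, if (sense) "upper" else "lower"] <- res$objective
    }
  }
  out
}

# copies/cell -> mmol/gDW given pg dry mass per cell
copies_to_mmol_per_gdw <- function(copies, cell_mass_pg) {
  copies / AVOGADRO * 1000 / (cell_mass_pg * 1e-12)
}

#' Overlay proteomics as enzyme constraints (GECKO-style)
#'
#' Adds per-enzyme usage variables to the model: each annotated reaction is
#' capped at `kcat * usage`, measured enzymes are bounded at mean + 1 SD
#' (converted from copies per cell to mmol/gDW), complexes are bounded by
#' the average of their measured subunits, and all unmeasured enzymes draw
#' from a shared mass pool `(protein_content - measured mass) * f * sigma`.
#' Zero measurements count as unmeasured.
#'
#' @param model a [metabolic_model()] with enzyme annotations.
#' @param measured named list or data frame: protein id -> c(mean, sd) in
#'   copies per cell.
#' @param params an [ec_params()].
#' @param quant a [quant_params()] (supplies the cell dry mass).
#' @return the model with an `ec` component; [fba()]/[fva()] on it solve the
#'   enzyme-constrained LP.
#' @export
add_enzyme_constraints <- function(model, measured = list(),
                                   params = ec_params(),
                                   quant = quant_params()) {
  if (is.null(model$enzymes)) stop("model carries no enzyme annotations")
  get_meas <- function(p) {
    m <- unname(unlist(measured[[p]]))
    if (is.null(m) || m[1] <= 0) {
      return(NULL)
    }
    c(mean = m[1], sd = if (length(m) > 1) m[2] else 0)
  }
  enz_ids <- unique(model$enzymes$enzyme)
  mw <- stats::setNames(
    model$enzymes$mw[match(enz_ids, model$enzymes$enzyme)], enz_ids
  )
  bound <- numeric(length(enz_ids))
  is_meas <- logical(length(enz_ids))
  measured_mass <- 0 # g/gDW
  for (k in seq_along(enz_ids)) {
    e <- enz_ids[k]
    subunits <- model$complexes[[e]]
    if (!is.null(subunits)) {
      vals <- Filter(Negate(is.null), lapply(subunits, get_meas))
      if (length(vals)) {
        caps <- vapply(vals, function(m) m["mean"] + m["sd"], 0)
        means <- vapply(vals, `[[`, 0, "mean")
        bound[k] <- copies_to_mmol_per_gdw(mean(caps), quant$cell_mass)
        is_meas[k] <- TRUE
        measured_mass <- measured_mass +
          copies_to_mmol_per_gdw(mean(means), quant$cell_mass) * mw[k]
      }
    } else {
      m <- get_meas(e)
      if (!is.null(m)) {
        bound[k] <- copies_to_mmol_per_gdw(m["mean"] + m["sd"], quant$cell_mass)
        is_meas[k] <- TRUE
        measured_mass <- measured_mass +
          copies_to_mmol_per_gdw(m["mean"], quant$cell_mass) * mw[k]
      }
    }
    if (!is_meas[k]) bound[k] <- Inf # limited by the pool instead
  }
  pool <- (params$protein_content - measured_mass) * params$f * params$sigma
  if (pool < 0) {
    stop(
      "measured enzyme mass (", signif(measured_mass, 4),
      " g/gDW) exceeds the protein content; rescale the measurements"
    )
  }
  model$ec <- list(
    usage = data.frame(
      enzyme = enz_ids, bound = bound, mw = unname(mw),
      measured = is_meas, stringsAsFactors = FALSE
    ),
    pool = pool, params = params, quant = quant
  )
  class(model) <- c("ec_model", class(model))
  model
}

#' Enzyme usage fractions
#'
#' Ratio of the model-required enzyme amount to the measured abundance,
#' per enzyme: a proxy for enzyme saturation. Enzymes without a (positive)
#' measurement are excluded.
#'
#' @param ec_solution a [fba()] solution on an enzyme-constrained model.
#' @param measured named list: protein/enzyme id -> c(mean, sd) copies/cell.
#' @param quant a [quant_params()].
#' @return named vector of usage fractions.
#' @export
enzyme_usage <- function(ec_solution, measured, quant = quant_params()) {
  if (is.null(ec_solution$usage)) {
    stop("solution does not come from an enzyme-constrained model")
  }
  out <- c()
  for (e in names(ec_solution$usage)) {
    m <- measured[[e]]
    if (is.null(m) || m[1] <= 0) next
    required_copies <- ec_solution$usage[e] / 1000 * AVOGADRO *
      (quant$cell_mass * 1e-12)
    out[e] <- unname(required_copies / m[1])
  }
  out
}

#' Correlate enzyme usage with growth rate
#'
#' @param usages matrix enzyme x condition of usage fractions.
#' @param mu growth-rate vector (>= 3 conditions).
#' @return data frame `enzyme`, `r`, `above_0.8`, `above_0.99`; enzymes with
#'   zero variance are reported with `r = NA` and excluded from the flags.
#' @export
usage_growth_correlation <- function(usages, mu) {
  if (length(mu) < 3) stop("need at least 3 conditions")
  r <- apply(usages, 1, function(u) {
    if (stats::sd(u) == 0 || stats::sd(mu) == 0) {
      return(NA_real_)
    }
    stats::cor(u, mu)
  })
  data.frame(
    enzyme = rownames(usages), r = r,
    above_0.8 = !is.na(r) & r > 0.8,
    above_0.99 = !is.na(r) & r > 0.99,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Relax enzyme bounds until a growth target is feasible
#'
#' Iteratively doubles the bound of the measured enzyme whose relaxation
#' most increases the growth optimum (a finite-difference estimate of the
#' bound's shadow price) until the model grows at `target_growth` with the
#' available glucose. A feasible model is returned unchanged with an empty
#' change log.
#'
#' @param ec_model an enzyme-constrained model.
#' @param target_growth required growth rate (1/h).
#' @param glucose_bound maximum glucose uptake (mmol/gDW/h), applied to
#'   `glucose_reaction`.
#' @param max_iter maximum relaxations before giving up.
#' @param glucose_reaction id of the glucose exchange reaction.
#' @return list `model` (relaxed), `log` (data frame `iteration`, `enzyme`,
#'   `old_bound`, `new_bound`).
#' @export
flexibilize <- function(ec_model, target_growth, glucose_bound,
                        max_iter = 30, glucose_reaction = "EX_glc") {
  if (is.null(ec_model$ec)) stop("flexibilize needs an enzyme-constrained model")
  constraints <- stats::setNames(
    list(c(-glucose_bound, 0)), glucose_reaction
  )
  log_df <- data.frame(
    iteration = integer(), enzyme = character(),
    old_bound = numeric(), new_bound = numeric(), stringsAsFactors = FALSE
  )
  for (it in seq_len(max_iter + 1)) {
    sol <- fba(ec_model, constraints = constraints)
    if (sol$status == "optimal" &&
      sol$objective_value >= target_growth - 1e-9) {
      return(list(model = ec_model, log = log_df))
    }
    if (it > max_iter) break
    base <- if (sol$status == "optimal") sol$objective_value else -Inf
    usage <- ec_model$ec$usage
    cand <- which(usage$measured & is.finite(usage$bound))
    if (!length(cand)) break
    gain <- vapply(cand, function(k) {
      trial <- ec_model
      trial$ec$usage$bound[k] <- usage$bound[k] * 2
      s <- fba(trial, constraints = constraints)
      if (s$status == "optimal") s$objective_value else -Inf
    }, 0)
    best <- cand[which.max(gain)]
    if (!is.finite(max(gain)) || max(gain) <= base + 1e-12) {
      # no single enzyme helps; relax the tightest-bound enzyme anyway
      best <- cand[which.min(usage$bound[cand])]
    }
    old <- ec_model$ec$usage$bound[best]
    ec_model$ec$usage$bound[best] <- old * 2
    log_df <- rbind(log_df, data.frame(
      iteration = it, enzyme = usage$enzyme[best],
      old_bound = old, new_bound = old * 2, stringsAsFactors = FALSE
    ))
  }
  stop(
    "flexibilize: max_iter reached without attaining growth ",
    target_growth, "; relaxations so far: ",
    paste(log_df$enzyme, collapse = ", ")
  )
}
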