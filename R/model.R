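#' Stoichiometric metabolic model
#'
#' A lightweight constraint-based model: metabolites flagged internal or
#' external (external metabolites are excluded from the steady-state mass
#' balance), reactions with stoichiometry and flux bounds, an objective
#' reaction, and optional GECKO-style enzyme annotations (kcat per
#' reaction-enzyme pair, enzyme molecular weights, complex subunit maps).
#'
#' Sign convention: exchange fluxes are negative for uptake and positive for
#' secretion. Bounds are in mmol per gram dry weight per hour.
#'
#' @param metabolites data frame with columns `id` and logical `external`.
#' @param reactions data frame with columns `id`, `lb`, `ub`.
#' @param stoich named list (by reaction id) of named stoichiometry vectors
#'   (negative = consumed).
#' @param objective objective reaction id.
#' @param enzymes optional data frame `reaction`, `enzyme`, `kcat` (1/h),
#'   `mw` (kDa).
#' @param complexes optional named list: enzyme id -> character vector of
#'   subunit protein ids.
#' @return a `metabolic_model` object.
#' @export
metabolic_model <- function(metabolites, reactions, stoich, objective,
                            enzymes = NULL, complexes = NULL) {
  stopifnot(
    all(c("id", "external") %in% names(metabolites)),
    all(c("id", "lb", "ub") %in% names(reactions))
  )
  if (any(reactions$lb > reactions$ub)) {
    stop("reaction bounds must satisfy lb <= ub")
  }
  if (!objective %in% reactions$id) stop("objective reaction not in model")
  missing_stoich <- setdiff(reactions$id, names(stoich))
  if (length(missing_stoich)) {
    stop("missing stoichiometry for: ", paste(missing_stoich, collapse = ", "))
  }
  if (!is.null(enzymes) && any(enzymes$kcat <= 0)) {
    stop("kcat values must be positive")
  }
  structure(
    list(
      metabolites = metabolites, reactions = reactions, stoich = stoich,
      objective = objective, enzymes = enzymes, complexes = complexes
    ),
    class = "metabolic_model"
  )
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(
    "metabolic_model:", nrow(x$reactions), "reactions,",
    sum(!x$metabolites$external), "internal /",
    sum(x$metabolites$external), "external metabolites\n"
  )
  cat("objective:", x$objective, "\n")
  if (!is.null(x$enzymes)) {
    cat("enzyme annotations:", nrow(x$enzymes), "reaction-enzyme pairs\n")
  }
  invisible(x)
}

#' Stoichiometric matrix over internal metabolites
#'
#' @param model a [metabolic_model()].
#' @return matrix internal metabolites x reactions.
#' @export
stoichiometry_matrix <- function(model) {
  mets <- model$metabolites$id[!model$metabolites$external]
  rxns <- model$reactions$id
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (r in rxns) {
    st <- model$stoich[[r]]
    keep <- intersect(names(st), mets)
    S[keep, r] <- st[keep]
  }
  S
}

#' Build the packaged toy metabolic network
#'
#' A ~24-reaction model of central carbon metabolism: glucose uptake, the
#' ten-step EMP glycolysis, the fermentation branch (pyruvate decarboxylase
#' and alcohol dehydrogenase to ethanol + CO2), a lumped TCA cycle, lumped
#' oxidative phosphorylation with a configurable P/O ratio, O2/CO2/ethanol
#' exchange, a fixed non-growth-associated ATP maintenance, and a biomass
#' reaction drawing G6P, pyruvate, redox and ATP. The network is balanced
#' over its internal metabolites (including the ATP/ADP and NAD/NADH
#' conjugate pairs) and supports both purely respiratory and
#' respirofermentative optima.
#'
#' @param po P/O ratio of oxidative phosphorylation (ATP per NADH,
#'   default 1.5).
#' @param ngam non-growth-associated maintenance, mmol ATP/gDW/h
#'   (default 0.7).
#' @param glucose_bound maximum glucose uptake (default 10).
#' @return a [metabolic_model()] with enzyme annotations, objective
#'   `BIOMASS`.
#' @export
build_toy_model <- function(po = 1.5, ngam = 0.7, glucose_bound = 10) {
  mets <- data.frame(
    id = c(
      "GLC_e", "O2_e", "CO2_e", "ETOH_e",
      "GLC", "G6P", "F6P", "FBP", "DHAP", "GAP", "BPG", "PG3", "PG2",
      "PEP", "PYR", "ACALD", "ETOH", "CO2", "O2", "NAD", "NADH",
      "ATP", "ADP"
    ),
    stringsAsFactors = FALSE
  )
  # all species are balanced: the EX_* reactions are the only boundary
  # crossings, so the exchange bounds really cap uptake/secretion
  mets$external <- FALSE

  UB <- 1000
  rx <- list(
    EX_glc = list(c(GLC_e = -1), -glucose_bound, 0),
    EX_o2 = list(c(O2_e = -1), -UB, 0),
    EX_co2 = list(c(CO2_e = -1), 0, UB),
    EX_etoh = list(c(ETOH_e = -1), 0, UB),
    GLCt = list(c(GLC_e = -1, GLC = 1), 0, UB),
    O2t = list(c(O2_e = -1, O2 = 1), 0, UB),
    CO2t = list(c(CO2 = -1, CO2_e = 1), 0, UB),
    ETOHt = list(c(ETOH = -1, ETOH_e = 1), 0, UB),
    HXK = list(c(GLC = -1, ATP = -1, G6P = 1, ADP = 1), 0, UB),
    PGI = list(c(G6P = -1, F6P = 1), 0, UB),
    PFK = list(c(F6P = -1, ATP = -1, FBP = 1, ADP = 1), 0, UB),
    FBA = list(c(FBP = -1, DHAP = 1, GAP = 1), 0, UB),
    TPI = list(c(DHAP = -1, GAP = 1), 0, UB),
    GAPD = list(c(GAP = -1, NAD = -1, BPG = 1, NADH = 1), 0, UB),
    PGK = list(c(BPG = -1, ADP = -1, PG3 = 1, ATP = 1), 0, UB),
    PGM = list(c(PG3 = -1, PG2 = 1), 0, UB),
    ENO = list(c(PG2 = -1, PEP = 1), 0, UB),
    PYK = list(c(PEP = -1, ADP = -1, PYR = 1, ATP = 1), 0, UB),
    PDC = list(c(PYR = -1, ACALD = 1, CO2 = 1), 0, UB),
    ADH = list(c(ACALD = -1, NADH = -1, ETOH = 1, NAD = 1), 0, UB),
    TCA = list(c(PYR = -1, NAD = -5, CO2 = 3, NADH = 5), 0, UB),
    OXPHOS = list(
      c(NADH = -1, O2 = -0.5, ADP = -po, NAD = 1, ATP = po), 0, UB
    ),
    NGAM = list(c(ATP = -1, ADP = 1), ngam, ngam),
    BIOMASS = list(
      c(G6P = -5, PYR = -2, NADH = -2, ATP = -40, NAD = 2, ADP = 40),
      0, UB
    )
  )
  reactions <- data.frame(
    id = names(rx),
    lb = vapply(rx, `[[`, 0, 2),
    ub = vapply(rx, `[[`, 0, 3),
    stringsAsFactors = FALSE
  )
  stoich <- lapply(rx, `[[`, 1)

  enz <- data.frame(
    reaction = c(
      "HXK", "PGI", "PFK", "FBA", "TPI", "GAPD", "PGK", "PGM", "ENO",
      "PYK", "PDC", "ADH", "TCA", "OXPHOS"
    ),
    enzyme = c(
      "E_HXK", "E_PGI", "E_PFK", "E_FBA", "E_TPI", "E_GAPD", "E_PGK",
      "E_PGM", "E_ENO", "E_PYK", "E_PDC", "E_ADH", "E_TCA", "CPX_OXPHOS"
    ),
    kcat = c(rep(2e5, 10), 2e5, 2e5, 1e5, 5e4),
    mw = c(rep(55, 10), 60, 37, 200, 600),
    stringsAsFactors = FALSE
  )
  complexes <- list(CPX_OXPHOS = c("POX1", "POX2", "POX3", "POX4"))

  metabolic_model(mets, reactions, stoich,
    objective = "BIOMASS",
    enzymes = enz, complexes = complexes
  )
}

#' Write / read a metabolic model as JSON
#'
#' The JSON schema stores metabolites (`id`, `external`), reactions (`id`,
#' `lb`, `ub`, `stoichiometry` as an id->coefficient map), the objective,
#' and optional `enzymes` / `complexes` blocks.
#'
#' @param model a [metabolic_model()].
#' @param path file path.
#' @export
write_model_json <- function(model, path) {
  doc <- list(
    metabolites = model$metabolites,
    reactions = lapply(model$reactions$id, function(r) {
      i <- match(r, model$reactions$id)
      list(
        id = r,
        lb = model$reactions$lb[i], ub = model$reactions$ub[i],
        stoichiometry = as.list(model$stoich[[r]])
      )
    }),
    objective = model$objective,
    enzymes = model$enzymes,
    complexes = model$complexes
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path)
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    data.frame(
      id = m$id, external = isTRUE(m$external),
      stringsAsFactors = FALSE
    )
  }))
  reactions <- do.call(rbind, lapply(doc$reactions, function(r) {
    data.frame(
      id = r$id,
      lb = r$lb %||% -LP_BIG, ub = r$ub %||% LP_BIG,
      stringsAsFactors = FALSE
    )
  }))
  stoich <- stats::setNames(
    lapply(doc$reactions, function(r) unlist(r$stoichiometry)),
    reactions$id
  )
  enzymes <- NULL
  if (!is.null(doc$enzymes) && length(doc$enzymes)) {
    enzymes <- do.call(rbind, lapply(doc$enzymes, function(e) {
      data.frame(
        reaction = e$reaction, enzyme = e$enzyme,
        kcat = e$kcat, mw = e$mw, stringsAsFactors = FALSE
      )
    }))
  }
  complexes <- if (length(doc$complexes)) {
    lapply(doc$complexes, function(x) unlist(x))
  } else {
    NULL
  }
  metabolic_model(mets, reactions, stoich, doc$objective, enzymes, complexes)
}
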