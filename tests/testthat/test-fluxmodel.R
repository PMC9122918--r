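test_that("FBA solves chain conservation and reports infeasibility", {
  m <- chain_model()
  sol <- fba(m)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 1, tolerance = 1e-9)
  expect_equal(unname(sol$fluxes), c(-1, 1, 1), tolerance = 1e-9)
  # forcing more export than uptake allows is infeasible
  bad <- fba(m, constraints = list(EX_out = c(2, 2)))
  expect_equal(bad$status, "infeasible")
  expect_true(is.na(bad$objective_value))
  expect_null(bad$fluxes)
})

test_that("toy-model optima match the hand-derived LP solutions", {
  m <- build_toy_model()
  # respiratory optimum at glucose uptake 1: growth 19.3/163, no ethanol
  sol <- fba(m, constraints = list(EX_glc = c(-1, 0)))
  expect_equal(sol$objective_value, 19.3 / 163, tolerance = 1e-9)
  expect_equal(unname(sol$fluxes["EX_etoh"]), 0, tolerance = 1e-9)
  expect_equal(
    unname(sol$fluxes["EX_o2"]), -0.5 * (12 - 72 * 19.3 / 163),
    tolerance = 1e-9
  )
  expect_lt(max(abs(stoichiometry_matrix(m) %*% sol$fluxes)), 1e-8)
  # O2-limited: fermentation stacks on top of saturated respiration
  lim <- fba(m, constraints = list(EX_glc = c(-1, 0), EX_o2 = c(-1, 0)))
  z <- 4.3 / 55
  expect_equal(lim$objective_value, z, tolerance = 1e-9)
  expect_equal(
    unname(lim$fluxes["EX_etoh"]), (10 - 72 * z) / 6,
    tolerance = 1e-9
  )
  # fixing growth above respiratory capacity forces ethanol secretion
  push <- fba(m,
    constraints = list(
      EX_glc = c(-1, 0), EX_o2 = c(-1, 0),
      BIOMASS = c(0.07, 0.07)
    ),
    objective = "EX_etoh", sense = "min"
  )
  expect_gt(push$objective_value, 0)
})

test_that("FVA brackets the point solution and resolves alternates", {
  # fully determined chain: all interval widths zero
  m <- chain_model()
  iv <- fva(m, constraints = list(EX_in = c(-1, -1)))
  expect_equal(iv$lower, iv$upper, tolerance = 1e-9)
  # two equivalent parallel routes carrying total 1: each spans [0, 1]
  mp <- chain_model(parallel = TRUE)
  ivp <- fva(mp,
    constraints = list(EX_in = c(-1, -1)),
    reactions = c("R1", "R2")
  )
  expect_equal(ivp$lower, c(0, 0), tolerance = 1e-9)
  expect_equal(ivp$upper, c(1, 1), tolerance = 1e-9)
  # point solution inside its FVA interval, growth fixed at the optimum
  toy <- build_toy_model()
  solt <- fba(toy, constraints = list(EX_glc = c(-1, -1)))
  ivt <- fva(toy,
    constraints = list(EX_glc = c(-1, -1)),
    fixed = c(BIOMASS = solt$objective_value),
    reactions = c("PGI", "OXPHOS", "EX_co2")
  )
  for (i in seq_len(nrow(ivt))) {
    v <- solt$fluxes[[ivt$reaction[i]]]
    expect_gte(v, ivt$lower[i] - 1e-7)
    expect_lte(v, ivt$upper[i] + 1e-7)
  }
  expect_error(
    fva(toy,
      constraints = list(EX_glc = c(-1, -1)),
      fixed = c(BIOMASS = 10), reactions = "PGI"
    ),
    "infeasible"
  )
})

test_that("enzyme constraints cap fluxes at kcat times usage", {
  m <- build_toy_model()
  qp <- quant_params(cell_mass = 13)
  # one measured enzyme: flux cap = kcat * converted bound
  meas <- list(E_PYK = c(1e4, 0))
  ecm <- add_enzyme_constraints(m, meas, ec_params(), qp)
  cap <- ecm$ec$usage$bound[ecm$ec$usage$enzyme == "E_PYK"]
  expect_equal(cap, 1e4 / 6.02214076e23 * 1000 / 13e-12, tolerance = 1e-9)
  sol <- fba(ecm, constraints = list(EX_glc = c(-10, 0)))
  kcat <- m$enzymes$kcat[m$enzymes$enzyme == "E_PYK"]
  expect_lte(sol$fluxes[["PYK"]], kcat * cap + 1e-9)
  # the PYK bound binds at this measurement level
  expect_equal(sol$fluxes[["PYK"]], kcat * cap, tolerance = 1e-6)
  # complexes: bound from the average of measured subunits
  ecc <- add_enzyme_constraints(
    m, list(POX1 = c(2, 0), POX2 = c(4, 0)), ec_params(), qp
  )
  expect_equal(
    ecc$ec$usage$bound[ecc$ec$usage$enzyme == "CPX_OXPHOS"],
    3 / 6.02214076e23 * 1000 / 13e-12,
    tolerance = 1e-9
  )
  # zero measurements count as unmeasured
  ecz <- add_enzyme_constraints(m, list(E_PYK = c(0, 0)), ec_params(), qp)
  expect_false(
    ecz$ec$usage$measured[ecz$ec$usage$enzyme == "E_PYK"]
  )
})

test_that("the shared pool bounds total unmeasured enzyme mass", {
  m <- build_toy_model()
  params <- ec_params()
  ecm <- add_enzyme_constraints(m, list(), params, quant_params())
  expect_equal(
    ecm$ec$pool, params$protein_content * params$f * params$sigma
  )
  sol <- fba(ecm, constraints = list(EX_glc = c(-10, 0)))
  mass <- sum(ecm$ec$usage$mw * sol$usage[ecm$ec$usage$enzyme])
  expect_lte(mass, ecm$ec$pool + 1e-9)
  # enzyme-constrained optimum cannot exceed the unconstrained one
  plain <- fba(m, constraints = list(EX_glc = c(-10, 0)))
  expect_lte(sol$objective_value, plain$objective_value + 1e-9)
  # an over-measured proteome exhausts the pool
  huge <- stats::setNames(
    rep(list(c(1e12, 0)), 13),
    setdiff(unique(m$enzymes$enzyme), "CPX_OXPHOS")
  )
  expect_error(
    add_enzyme_constraints(m, huge, params, quant_params()),
    "exceeds the protein content"
  )
})

test_that("enzyme usage is required over measured", {
  m <- build_toy_model()
  qp <- quant_params()
  meas <- list(E_PYK = c(1e4, 0))
  ecm <- add_enzyme_constraints(m, meas, ec_params(), qp)
  sol <- fba(ecm, constraints = list(EX_glc = c(-10, 0)))
  u <- enzyme_usage(sol, meas, qp)
  # the binding bound means full usage
  expect_equal(unname(u["E_PYK"]), 1, tolerance = 1e-6)
  # doubling the measurement halves usage
  u2 <- enzyme_usage(sol, list(E_PYK = c(2e4, 0)), qp)
  expect_equal(unname(u2["E_PYK"]), 0.5, tolerance = 1e-6)
  expect_error(enzyme_usage(fba(m), meas, qp), "enzyme-constrained")
})

test_that("usage-growth correlation flags the configured thresholds", {
  mu <- seq(0.1, 0.4, length.out = 6)
  usages <- rbind(
    prop = mu * 2,
    noisy = mu + c(0.02, -0.01, 0.03, -0.02, 0.01, 0),
    flat = rep(1, 6),
    anti = rev(mu)
  )
  rec <- usage_growth_correlation(usages, mu)
  expect_equal(rec$r[rec$enzyme == "prop"], 1)
  expect_true(rec$above_0.8[rec$enzyme == "prop"])
  expect_true(rec$above_0.99[rec$enzyme == "prop"])
  expect_true(is.na(rec$r[rec$enzyme == "flat"]))
  expect_false(rec$above_0.8[rec$enzyme == "flat"])
  expect_false(rec$above_0.8[rec$enzyme == "anti"])
  # threshold partition agrees with direct filtering
  expect_equal(rec$above_0.8, !is.na(rec$r) & rec$r > 0.8)
  expect_error(usage_growth_correlation(usages[, 1:2], mu[1:2]), "3")
})

test_that("flexibilization relaxes exactly the constructed bottleneck", {
  m <- build_toy_model()
  qp <- quant_params()
  # feasible model: no-op with an empty log
  ecm_ok <- add_enzyme_constraints(m, list(), ec_params(), qp)
  ok <- flexibilize(ecm_ok, target_growth = 0.05, glucose_bound = 10)
  expect_equal(nrow(ok$log), 0)
  # tiny PYK bound blocks growth; only E_PYK should be relaxed
  ecm <- add_enzyme_constraints(m, list(E_PYK = c(1e4, 0)), ec_params(), qp)
  fx <- flexibilize(ecm, target_growth = 0.1, glucose_bound = 10)
  expect_gt(nrow(fx$log), 0)
  expect_equal(unique(fx$log$enzyme), "E_PYK")
  expect_equal(fx$log$new_bound, fx$log$old_bound * 2)
  post <- fba(fx$model, constraints = list(EX_glc = c(-10, 0)))
  expect_gte(post$objective_value, 0.1 - 1e-9)
  expect_error(
    flexibilize(ecm, target_growth = 0.1, glucose_bound = 10, max_iter = 1),
    "max_iter"
  )
})

test_that("model JSON round-trips through the schema", {
  m <- build_toy_model()
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_model_json(m, path)
  m2 <- read_model_json(path)
  expect_equal(m2$reactions, m$reactions, ignore_attr = TRUE)
  expect_equal(m2$objective, m$objective)
  expect_equal(m2$enzymes, m$enzymes, ignore_attr = TRUE)
  for (r in m$reactions$id) {
    expect_equal(m2$stoich[[r]], m$stoich[[r]])
  }
  sol <- fba(m2, constraints = list(EX_glc = c(-1, 0)))
  expect_equal(sol$objective_value, 19.3 / 163, tolerance = 1e-9)
})
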