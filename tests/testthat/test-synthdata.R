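test_that("chemostat series honours the physiological invariants", {
  s <- default_series()
  expect_true(all(diff(s$mu) > 0))
  crit <- attr(s, "critical_rate")
  expect_true(all(s$q_etoh[s$mu < crit] == 0))
  expect_true(all(s$q_etoh[s$mu >= crit] > 0))
  expect_true(all(abs(s$rq[s$mu < attr(s, "decoupling_rate")] - 1) < 1e-9))
  expect_equal(s$rq, s$q_co2 / abs(s$q_o2), tolerance = 1e-12)
  expect_true(all(s$q_o2 < 0))
  expect_true(all(s$q_co2 > 0))
  # glucose uptake magnitude increases with growth rate
  expect_true(all(diff(abs(s$q_gluc)) > 0))
})

test_that("chemostat generation is a pure function of its seed", {
  expect_identical(
    generate_chemostat_series(seed = 11),
    generate_chemostat_series(seed = 11)
  )
  a <- generate_chemostat_series(seed = 1)
  b <- generate_chemostat_series(seed = 2)
  expect_false(identical(a$q_gluc, b$q_gluc))
  # mu grid itself is deterministic
  expect_identical(a$mu, b$mu)
})

test_that("rate-parameter ordering violations are rejected by name", {
  expect_error(
    generate_chemostat_series(mu_min = 0.3, critical_rate = 0.28),
    "mu_min"
  )
  expect_error(
    generate_chemostat_series(critical_rate = 0.5, mu_max = 0.4),
    "critical_rate"
  )
  expect_error(
    generate_chemostat_series(decoupling_rate = 0.3, critical_rate = 0.28),
    "decoupling_rate"
  )
})

test_that("noiseless proteome reproduces the allocation laws exactly", {
  s <- default_series()
  pr <- default_proteome(s)
  frac <- compute_group_fractions(pr$proteome, pr$categories,
    weights = pr$mw
  )
  expect_equal(colSums(frac), rep(1, ncol(frac)),
    ignore_attr = TRUE, tolerance = 1e-12
  )
  laws <- default_allocation_laws(attr(s, "critical_rate"))
  for (g in names(laws)) {
    expect_equal(
      unname(frac[g, ]), predict_allocation(laws[[g]], s$mu),
      tolerance = 1e-12
    )
  }
  # the spelled-out growth law: translation fraction at mu = 0.2
  expect_equal(
    unname(frac["translation", which.min(abs(s$mu - 0.2125))]),
    0.35 * 0.2125 + 0.13,
    tolerance = 1e-12
  )
})

test_that("degenerate one-protein group carries its whole group mass", {
  s <- default_series()
  laws <- list(allocation_law(
    "solo",
    data.frame(mu_lo = 0, mu_hi = Inf, slope = 0, intercept = 0.4)
  ))
  pr <- generate_proteome(s, laws = laws, n_proteins_per_group = 1, seed = 3)
  frac <- compute_group_fractions(pr$proteome, pr$categories,
    weights = pr$mw
  )
  expect_equal(unname(frac["solo", ]), rep(0.4, nrow(s)), tolerance = 1e-12)
  # and the single "solo" protein owns all of it
  solo <- pr$categories$entity_id[pr$categories$category == "solo"]
  expect_length(solo, 1)
})

test_that("over-committed allocation laws fail with the condition named", {
  s <- default_series()
  laws <- list(allocation_law(
    "greedy",
    data.frame(mu_lo = 0, mu_hi = Inf, slope = 3, intercept = 0.1)
  ))
  expect_error(generate_proteome(s, laws = laws), "sums >= 1")
})

test_that("transcriptome couples to the proteome as configured", {
  s <- default_series()
  pr <- generate_proteome(s, n_proteins_per_group = 30, seed = 2)
  # perfect coupling, no gene-specific offset spread: monotone image
  tr <- generate_transcriptome(pr$proteome,
    log_ratio_sd = 0,
    within_gene_log_correlation = 1, seed = 4
  )
  varying <- which(apply(pr$proteome$values, 1, stats::sd) > 0)
  for (g in varying[1:20]) {
    expect_equal(
      spearman(tr$values[g, ], pr$proteome$values[g, ])$r, 1
    )
  }
  # zero coupling: per-gene correlations centred on zero
  tr0 <- generate_transcriptome(pr$proteome,
    within_gene_log_correlation = 0, seed = 5
  )
  rs <- vapply(varying, function(g) {
    spearman(tr0$values[g, ], pr$proteome$values[g, ])$r
  }, 0)
  expect_lt(abs(mean(rs)), 3 * stats::sd(rs) / sqrt(length(rs)) + 0.05)
  # invalid configurations
  expect_error(
    generate_transcriptome(pr$proteome, log_ratio_sd = -1),
    "log_ratio_sd"
  )
  expect_error(
    generate_transcriptome(pr$proteome, within_gene_log_correlation = 1.2),
    "correlation"
  )
})

test_that("phosphoproteome trends follow the trend specification", {
  s <- default_series()
  pr <- generate_proteome(s, n_proteins_per_group = 10, seed = 6)
  ph <- generate_phosphoproteome(
    pr$proteome, pr$categories, s$mu,
    trend_spec = list(glycolysis = list("decreasing", 1.0)),
    seed = 7
  )
  crit <- attr(s, "critical_rate")
  resp <- s$mu < crit
  gly <- ph$peptide_map$peptide_id[ph$peptide_map$category == "glycolysis"]
  for (p in gly) {
    expect_lt(spearman(ph$phospho$values[p, resp], s$mu[resp])$r, 0)
  }
  # flat spec with zero noise: identical intensities across conditions
  ph_flat <- generate_phosphoproteome(
    pr$proteome, pr$categories, s$mu,
    trend_spec = list(glycolysis = list("flat", 1.0)), seed = 7
  )
  flat_rows <- ph_flat$phospho$values[gly, , drop = FALSE]
  expect_equal(apply(flat_rows, 1, stats::sd), rep(0, length(gly)),
    ignore_attr = TRUE
  )
  # seeding contract
  ph2 <- generate_phosphoproteome(pr$proteome, pr$categories, s$mu, seed = 7)
  ph3 <- generate_phosphoproteome(pr$proteome, pr$categories, s$mu, seed = 7)
  expect_identical(ph2$phospho$values, ph3$phospho$values)
  expect_error(
    generate_phosphoproteome(pr$proteome, pr$categories, s$mu,
      trend_spec = list(glycolysis = list("sideways", 1))
    ),
    "direction"
  )
  expect_error(
    generate_phosphoproteome(pr$proteome, pr$categories, s$mu,
      trend_spec = list(glycolysis = list("flat", 1.4))
    ),
    "fraction"
  )
})

test_that("kinetic dataset satisfies the loglinear model identically", {
  conds <- paste0("c", 1:9)
  # hand example: one metabolite, a = 2, ratio = e, e^c = 1, j0 = 1 -> J = 3
  x <- matrix(exp(1), 1, 9, dimnames = list("M1", conds))
  x[, 1] <- 1
  tk <- true_kinetics("R1", c(M1 = 2),
    j0 = 1,
    e_profile = stats::setNames(rep(1, 9), conds), x_ratio = x
  )
  ds <- generate_kinetic_dataset(list(tk), fva_halfwidth = 0.1, seed = 1)
  expect_equal(unname(ds$flux["R1", 2]), 3)
  expect_equal(unname(ds$flux["R1", 1]), 1) # reference identity
  expect_equal(unname(ds$flux_lower["R1", 2]), 3 - 0.3)
  expect_equal(unname(ds$flux_upper["R1", 2]), 3 + 0.3)

  # round trip: model prediction reproduces random noiseless datasets
  for (k in 1:5) {
    tk <- random_true_kinetics("R", 2, conds, seed = 40 + k)
    ds <- generate_kinetic_dataset(list(tk), fva_halfwidth = 0.05, seed = k)
    prob <- thermo_problem_from_dataset(ds, "R")
    expect_equal(
      unname(predict_specific_flux(tk$a_true, prob)),
      unname(ds$flux["R", ] / ds$enzyme["R", ]),
      tolerance = 1e-12
    )
  }
  # all ratios 1: specific flux equals j0 everywhere
  x1 <- matrix(1, 2, 9, dimnames = list(c("M1", "M2"), conds))
  tk1 <- true_kinetics("R", c(M1 = 1.5, M2 = -0.8),
    j0 = 2.5,
    e_profile = stats::setNames(exp(stats::rnorm(9, 0, 0.2)), conds),
    x_ratio = x1
  )
  ds1 <- generate_kinetic_dataset(list(tk1), seed = 2)
  expect_equal(unname(ds1$flux["R", ] / ds1$enzyme["R", ]), rep(2.5, 9))
})

test_that("invalid kinetic ground truths are rejected", {
  conds <- paste0("c", 1:4)
  x <- matrix(1, 1, 4, dimnames = list("M1", conds))
  e <- stats::setNames(rep(1, 4), conds)
  expect_error(true_kinetics("R", 1, Inf, e, x), "finite")
  xneg <- x
  xneg[1, 2] <- -1
  expect_error(true_kinetics("R", 1, 1, e, xneg), "positive")
  xref <- x
  xref[1, 1] <- 2
  expect_error(true_kinetics("R", 1, 1, e, xref), "reference")
})

test_that("toy network is balanced, connected and feasible", {
  m <- build_toy_model()
  S <- stoichiometry_matrix(m)
  # a nonzero steady-state flux exists at glucose uptake 1
  sol <- fba(m, constraints = list(EX_glc = c(-1, -1)))
  expect_equal(sol$status, "optimal")
  expect_gt(sol$objective_value, 0)
  expect_lt(max(abs(S %*% sol$fluxes)), 1e-8)
  # every internal metabolite is produced and consumed by some reaction
  # (reversible/uptake exchanges count with both effective signs)
  for (met in rownames(S)) {
    prod <- FALSE
    cons <- FALSE
    for (r in m$reactions$id) {
      coef <- S[met, r]
      if (coef == 0) next
      lb <- m$reactions$lb[m$reactions$id == r]
      ub <- m$reactions$ub[m$reactions$id == r]
      if ((coef > 0 && ub > 0) || (coef < 0 && lb < 0)) prod <- TRUE
      if ((coef < 0 && ub > 0) || (coef > 0 && lb < 0)) cons <- TRUE
    }
    expect_true(prod, label = paste(met, "produced"))
    expect_true(cons, label = paste(met, "consumed"))
  }
  # blocking O2 forces fermentation at any nonzero growth
  an <- fba(m, constraints = list(EX_glc = c(-1, 0), EX_o2 = c(0, 0)))
  expect_gt(an$objective_value, 0)
  expect_gt(an$fluxes[["EX_etoh"]], 0)
})
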