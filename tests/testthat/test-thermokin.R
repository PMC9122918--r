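make_problem <- function(seed = 1, I = 2, halfwidth = 0.02) {
  tk <- random_true_kinetics("R", I, paste0("c", 1:9), seed = seed)
  ds <- generate_kinetic_dataset(list(tk),
    fva_halfwidth = halfwidth,
    seed = seed + 1000
  )
  list(truth = tk, problem = thermo_problem_from_dataset(ds, "R"))
}

test_that("specific-flux prediction implements the loglinear model", {
  conds <- paste0("c", 1:5)
  x <- matrix(1, 1, 5, dimnames = list("M1", conds))
  x[1, 3] <- exp(1)
  e <- stats::setNames(rep(2, 5), conds)
  prob <- thermo_problem("R", e, J_obs = rep(2, 5), J_lower = rep(1.9, 5),
    J_upper = rep(2.1, 5), x_ratio = x
  )
  # all ratios 1 -> reference identity; ratio e with a = 2 -> j0 + 2
  pred <- predict_specific_flux(2, prob)
  expect_equal(unname(pred[1]), 1) # j0 = 2/2
  expect_equal(unname(pred[3]), 1 + 2)
  # independent re-evaluation of the sum on a random problem
  mk <- make_problem(21, I = 3)
  a <- c(0.3, -1.1, 0.7)
  oracle <- vapply(seq_len(mk$problem$n), function(c) {
    mk$problem$j0 + sum(a * mk$problem$lx[, c])
  }, 0)
  expect_equal(unname(predict_specific_flux(a, mk$problem)), oracle,
    tolerance = 1e-14
  )
  xbad <- x
  xbad[1, 2] <- 0
  expect_error(
    thermo_problem("R", e, rep(2, 5), rep(1.9, 5), rep(2.1, 5), xbad),
    "M1"
  )
})

test_that("residual variance divides by n minus I", {
  mk <- make_problem(22)
  expect_equal(residual_variance(mk$truth$a_true, mk$problem), 0,
    tolerance = 1e-25
  )
  # constructed residuals (1, -1) with n - I = 1
  conds <- c("c1", "c2", "c3")
  x <- matrix(1, 2, 3, dimnames = list(c("M1", "M2"), conds))
  e <- stats::setNames(rep(1, 3), conds)
  prob <- thermo_problem("R", e,
    J_obs = c(2, 3, 1), J_lower = c(2, 3, 1) - 0.1,
    J_upper = c(2, 3, 1) + 0.1, x_ratio = x
  )
  # predictions are all j0 = 2 -> residuals (0, -1, 1), dof = 1
  expect_equal(residual_variance(c(0, 0), prob), 2)
  # quadratic scaling
  prob2 <- thermo_problem("R", e,
    J_obs = c(2, 4, 0), J_lower = c(2, 4, 0) - 0.1,
    J_upper = c(2, 4, 0) + 0.1, x_ratio = x
  )
  expect_equal(residual_variance(c(0, 0), prob2), 8)
  expect_error(
    thermo_problem("R", e[1:2], c(2, 3), c(1, 2), c(3, 4),
      x_ratio = x[, 1:2]
    ),
    "n > I"
  )
})

test_that("interval likelihood matches closed form and quadrature", {
  mk <- make_problem(23)
  prob <- mk$problem
  # closed form for a symmetric interval centred at the prediction
  a <- mk$truth$a_true * 1.05
  pred <- predict_specific_flux(a, prob)
  d2 <- max(residual_variance(a, prob), 1e-12)
  w <- 0.3
  sym <- thermo_problem("R", prob$e,
    J_obs = pred * prob$e,
    J_lower = (pred - w / 2) * prob$e, J_upper = (pred + w / 2) * prob$e,
    x_ratio = exp(prob$lx)
  )
  ll <- log_likelihood(a, sym)
  d2s <- max(residual_variance(a, sym), 1e-12)
  closed <- sym$n * log((2 * stats::pnorm(w / 2 / sqrt(d2s)) - 1) / w)
  expect_equal(ll, closed, tolerance = 1e-9)
  # quadrature oracle over a grid of parameter values
  set.seed(7)
  for (k in 1:8) {
    ak <- mk$truth$a_true + stats::rnorm(length(mk$truth$a_true), 0, 0.5)
    predk <- predict_specific_flux(ak, prob)
    d2k <- max(residual_variance(ak, prob), 1e-12)
    oracle <- sum(vapply(seq_len(prob$n), function(c) {
      quadrature_interval_term(
        predk[c], sqrt(d2k), prob$j_lower[c], prob$j_upper[c]
      )
    }, 0))
    ll_k <- log_likelihood(ak, prob)
    expect_equal(ll_k, oracle, tolerance = 1e-6 * abs(oracle))
  }
  # far-tail terms are finite, very negative and monotone in the offset
  base <- interval_loglik_terms(0, 0.1, 5, 5.1)
  further <- interval_loglik_terms(0, 0.1, 8, 8.1)
  expect_true(is.finite(base) && is.finite(further))
  expect_lt(further, base)
})

test_that("zero-width intervals converge to the normal log-density", {
  for (w in 10^seq(-2, -8)) {
    term <- interval_loglik_terms(0.3, 0.5, 1 - w / 2, 1 + w / 2)
    expect_equal(term, stats::dnorm(1, 0.3, 0.5, log = TRUE),
      tolerance = 1e-3
    )
  }
  expect_equal(
    interval_loglik_terms(0.3, 0.5, 1, 1),
    stats::dnorm(1, 0.3, 0.5, log = TRUE)
  )
})

test_that("default prior summarizes the observed specific fluxes", {
  conds <- paste0("c", 1:4)
  x <- matrix(1, 1, 4, dimnames = list("M1", conds))
  e <- stats::setNames(rep(1, 4), conds)
  prob <- thermo_problem("R", e,
    J_obs = c(0, 2, 0, 2),
    J_lower = c(0, 2, 0, 2) - 0.1, J_upper = c(0, 2, 0, 2) + 0.1,
    x_ratio = x
  )
  pr <- default_prior(prob)
  expect_equal(pr$mean, 1)
  expect_equal(pr$variance, stats::var(c(0, 2, 0, 2)))
  # standard-error variant
  prse <- default_prior(prob, variance = "se")
  expect_equal(prse$variance, stats::var(c(0, 2, 0, 2)) / 4)
  # constant j_obs: mean k, floored variance with a warning
  probk <- thermo_problem("R", e,
    J_obs = rep(3, 4), J_lower = rep(2.9, 4),
    J_upper = rep(3.1, 4), x_ratio = x
  )
  expect_warning(prk <- default_prior(probk), "degenerate")
  expect_equal(prk$mean, 3)
})

test_that("gelman_rubin matches the between/within variance formula", {
  set.seed(8)
  chains <- matrix(stats::rnorm(400), 100, 4)
  n <- 100
  W <- mean(apply(chains, 2, stats::var))
  B <- n * stats::var(colMeans(chains))
  oracle <- sqrt(((n - 1) / n * W + B / n) / W)
  expect_equal(gelman_rubin(chains), oracle, tolerance = 1e-10)
  # identical chains
  expect_equal(gelman_rubin(cbind(1:50, 1:50)), sqrt(49 / 50))
  # disjoint supports diverge
  far <- cbind(stats::rnorm(100, 0, 1), stats::rnorm(100, 100, 1))
  expect_gt(gelman_rubin(far), 5)
  expect_error(gelman_rubin(matrix(1:100, 100, 1)), "2 chains")
  expect_error(gelman_rubin(matrix(1:8, 4, 2)), "short")
})

test_that("MCMC is deterministic and recovers a planted truth", {
  mk <- make_problem(24, I = 2)
  post <- mcmc_infer(mk$problem, n_samples = 800, thin = 2, seed = 99)
  post2 <- mcmc_infer(mk$problem, n_samples = 800, thin = 2, seed = 99)
  expect_identical(post$samples, post2$samples)
  expect_true(all(
    mk$truth$a_true >= post$ci[, "lower"] &
      mk$truth$a_true <= post$ci[, "upper"]
  ))
  expect_true(all(post$rhat < 1.1))
  # posterior means stable across seeds within Monte-Carlo error
  post3 <- mcmc_infer(mk$problem, n_samples = 800, thin = 2, seed = 100)
  mcse <- apply(post$samples, 3, stats::sd) / sqrt(400) # conservative ESS
  expect_true(all(abs(post$mean - post3$mean) < 30 * mcse))
  # credible intervals are ordered and contain the posterior mean's range
  expect_true(all(post$ci[, "lower"] <= post$ci[, "upper"]))
  expect_true(all(post$mean >= apply(post$samples, 3, min) &
    post$mean <= apply(post$samples, 3, max)))
})

test_that("classification follows the credible-interval sign", {
  mk <- make_problem(25, I = 2)
  post <- mcmc_infer(mk$problem, n_samples = 800, thin = 2, seed = 42)
  for (i in seq_along(mk$truth$a_true)) {
    expected <- if (post$ci[i, "lower"] > 0) {
      "activation"
    } else if (post$ci[i, "upper"] < 0) {
      "inhibition"
    } else {
      "none"
    }
    expect_equal(
      classify_effect(post, mk$problem$metabolites[i]), expected
    )
  }
  fake <- post
  fake$converged <- FALSE
  expect_error(classify_effect(fake, "M1"), "refused")
})
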