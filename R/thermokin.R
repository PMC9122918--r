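#' Thermokinetic inference problem
#'
#' Inputs of the loglinear thermokinetic model for one reaction: enzyme
#' levels, observed fluxes with flux-variability bounds, and metabolite
#' concentration ratios relative to a reference condition. All fluxes are
#' converted to enzymatic specific fluxes `j = J / e` on construction. The
#' model requires more conditions than metabolites (`n > I`) so the
#' residual variance has positive degrees of freedom.
#'
#' @param reaction reaction id.
#' @param e positive enzyme level per condition (named vector).
#' @param J_obs observed point flux per condition.
#' @param J_lower,J_upper flux-variability bounds per condition
#'   (`J_lower <= J_obs <= J_upper` elementwise).
#' @param x_ratio matrix metabolites x conditions of ratios X_c/X_0 (> 0);
#'   reference column exactly 1.
#' @param reference reference condition id (default first column).
#' @return a `thermo_problem` object with derived `j_obs`, `j_lower`,
#'   `j_upper`, `j0` (reference specific flux), `lx` (log-ratio matrix),
#'   `n`, `I`.
#' @export
thermo_problem <- function(reaction, e, J_obs, J_lower, J_upper, x_ratio,
                           reference = colnames(x_ratio)[1]) {
  x_ratio <- as.matrix(x_ratio)
  conds <- colnames(x_ratio)
  n <- length(conds)
  I <- nrow(x_ratio)
  if (n <= I) {
    stop("need more conditions than metabolites (n > I); got n = ", n,
      ", I = ", I)
  }
  if (any(e <= 0)) stop("enzyme levels must be positive")
  if (any(x_ratio <= 0)) {
    bad <- which(x_ratio <= 0, arr.ind = TRUE)[1, ]
    stop("non-positive metabolite ratio for ", rownames(x_ratio)[bad[1]])
  }
  if (!reference %in% conds) stop("reference condition not found")
  if (any(abs(x_ratio[, reference] - 1) > 1e-9)) {
    stop("reference-column metabolite ratios must be exactly 1")
  }
  if (any(J_upper < J_lower)) stop("FVA bounds must satisfy lower <= upper")
  e <- stats::setNames(as.numeric(e), conds)
  structure(
    list(
      reaction = reaction,
      conditions = conds,
      metabolites = rownames(x_ratio) %||% paste0("M", seq_len(I)),
      e = e,
      j_obs = as.numeric(J_obs) / e,
      j_lower = as.numeric(J_lower) / e,
      j_upper = as.numeric(J_upper) / e,
      j0 = as.numeric(J_obs)[match(reference, conds)] /
        e[match(reference, conds)],
      lx = log(x_ratio),
      reference = reference,
      n = n, I = I
    ),
    class = "thermo_problem"
  )
}

#' Build a thermo_problem from a generated kinetic dataset
#'
#' @param dataset a [generate_kinetic_dataset()] result.
#' @param reaction reaction id within the dataset.
#' @return a [thermo_problem()].
#' @export
thermo_problem_from_dataset <- function(dataset, reaction) {
  thermo_problem(
    reaction,
    e = dataset$enzyme[reaction, ],
    J_obs = dataset$flux[reaction, ],
    J_lower = dataset$flux_lower[reaction, ],
    J_upper = dataset$flux_upper[reaction, ],
    x_ratio = dataset$x_ratio[[reaction]],
    reference = dataset$reference[[reaction]]
  )
}

#' Predicted enzymatic specific flux
#'
#' The loglinear thermokinetic model: `j_pred_c = J0/e0 + sum_i a_i *
#' ln(X_ic / X_i0)`. With all ratios 1 this reduces to the reference
#' specific flux.
#'
#' @param a vector of intrinsic turnover numbers (length I).
#' @param problem a [thermo_problem()].
#' @param condition condition id or index; default all conditions.
#' @return predicted specific flux(es).
#' @export
predict_specific_flux <- function(a, problem, condition = NULL) {
  pred <- problem$j0 + drop(crossprod(problem$lx, a))
  names(pred) <- problem$conditions
  if (is.null(condition)) {
    return(pred)
  }
  pred[condition]
}

#' Residual variance of the specific-flux fit
#'
#' Sum of squared residuals between predicted and observed specific fluxes
#' over conditions, divided by `n - I`.
#'
#' @param a intrinsic turnover numbers.
#' @param problem a [thermo_problem()].
#' @return the residual variance (>= 0).
#' @export
residual_variance <- function(a, problem) {
  res <- predict_specific_flux(a, problem) - problem$j_obs
  sum(res^2) / (problem$n - problem$I)
}

# delta^2 floor guarding log(0) at exact fits
DELTA_FLOOR <- 1e-12

#' Interval log-likelihood of the thermokinetic model
#'
#' For each condition, the likelihood is the normal probability mass over
#' the flux-variability interval divided by the interval width, with mean
#' `j_pred_c` and variance equal to the residual variance of the fit; the
#' log terms are summed over conditions. A zero-width interval degenerates
#' continuously to the normal log-density at that point.
#'
#' @param a intrinsic turnover numbers.
#' @param problem a [thermo_problem()].
#' @return the log-likelihood (may be -Inf for hopeless parameter values).
#' @export
log_likelihood <- function(a, problem) {
  pred <- problem$j0 + drop(crossprod(problem$lx, a))
  d2 <- sum((pred - problem$j_obs)^2) / (problem$n - problem$I)
  d2 <- max(d2, DELTA_FLOOR)
  sum(interval_loglik_terms(pred, sqrt(d2), problem$j_lower, problem$j_upper))
}

# log[(Phi(u) - Phi(l)) / (u - l)] per condition, computed in log space so
# far-tail intervals do not underflow to log(0)
interval_loglik_terms <- function(mean, sd, lower, upper) {
  w <- upper - lower
  out <- numeric(length(mean))
  deg <- w <= 0
  if (any(deg)) {
    out[deg] <- stats::dnorm(lower[deg], mean[deg], sd, log = TRUE)
  }
  if (any(!deg)) {
    m <- mean[!deg]
    l <- lower[!deg]
    u <- upper[!deg]
    # evaluate on the side of the distribution where both CDF values are
    # small, so the subtraction stays accurate in the far tails
    hi <- m < (l + u) / 2
    la <- ifelse(hi,
      stats::pnorm(l, m, sd, lower.tail = FALSE, log.p = TRUE),
      stats::pnorm(u, m, sd, log.p = TRUE)
    )
    lb <- ifelse(hi,
      stats::pnorm(u, m, sd, lower.tail = FALSE, log.p = TRUE),
      stats::pnorm(l, m, sd, log.p = TRUE)
    )
    out[!deg] <- la + log1p(-pmin(exp(lb - la), 1)) - log(u - l)
  }
  out
}

#' Default prior for the intrinsic turnover numbers
#'
#' An identical normal prior for every parameter: mean equal to the mean of
#' the observed specific fluxes, variance equal to the square of their
#' dispersion - by default the standard deviation of `j_obs` (the
#' `"sd"` variant), optionally the standard error (`"se"`).
#'
#' @param problem a [thermo_problem()].
#' @param variance `"sd"` (default) or `"se"`.
#' @return list with `mean` and `variance` (floored at 1e-12 with a warning
#'   if degenerate).
#' @export
default_prior <- function(problem, variance = c("sd", "se")) {
  variance <- match.arg(variance)
  if (problem$n < 2) stop("prior needs at least 2 conditions")
  m <- mean(problem$j_obs)
  s <- stats::sd(problem$j_obs)
  if (variance == "se") s <- s / sqrt(problem$n)
  v <- s^2
  if (v < 1e-12) {
    warning("degenerate prior variance; floored at 1e-12")
    v <- 1e-12
  }
  list(mean = m, variance = v)
}

#' MCMC inference of intrinsic turnover numbers
#'
#' Random-walk Metropolis sampling of the posterior (interval likelihood
#' times normal prior) with per-parameter Gaussian proposals adapted toward
#' an acceptance rate of 0.234 during burn-in and frozen afterwards.
#' Multiple chains run from overdispersed prior draws; convergence is
#' diagnosed with the Gelman-Rubin statistic.
#'
#' @param problem a [thermo_problem()].
#' @param n_chains number of chains (default 4).
#' @param n_samples kept samples per chain after thinning (default 5000).
#' @param thin thinning interval (default 5).
#' @param burn_in adaptation/burn-in iterations per chain (default 1000).
#' @param seed integer seed; results are deterministic given (seed,
#'   n_chains).
#' @param prior optional list(mean, variance) overriding [default_prior()].
#' @param rhat_threshold convergence cutoff (default 1.1).
#' @return a `thermo_posterior`: list with `samples` (array kept x chains x
#'   parameters), `mean`, `ci` (95% credible intervals), `rhat`,
#'   `acceptance_rate`, `converged`, `prior`, `problem`.
#' @export
mcmc_infer <- function(problem, n_chains = 4, n_samples = 5000, thin = 5,
                       burn_in = 1000, seed = 1, prior = NULL,
                       rhat_threshold = 1.1) {
  stopifnot(n_chains >= 2, n_samples >= 10, thin >= 1)
  prior <- prior %||% default_prior(problem)
  I <- problem$I
  lx_t <- t(problem$lx) # n x I
  j_obs <- problem$j_obs
  j_lo <- problem$j_lower
  j_up <- problem$j_upper
  j0 <- problem$j0
  dof <- problem$n - I
  w <- j_up - j_lo
  deg <- w <= 0

  # joint log-posterior for a chains x I matrix of parameter states
  log_post <- function(A) {
    pred <- j0 + lx_t %*% t(A) # n x chains
    d2 <- pmax(colSums((pred - j_obs)^2) / dof, DELTA_FLOOR)
    sd_mat <- matrix(sqrt(d2), nrow(pred), ncol(pred), byrow = TRUE)
    ll <- numeric(ncol(pred))
    for (ch in seq_len(ncol(pred))) {
      ll[ch] <- sum(interval_loglik_terms(pred[, ch], sd_mat[1, ch], j_lo, j_up))
    }
    lp <- -rowSums((A - prior$mean)^2) / (2 * prior$variance)
    ll + lp
  }

  # chains start overdispersed around the least-squares estimate of a
  # (the model is linear in a, so this is an excellent mode guess); with an
  # uninformative design (all ratios 1) the start falls back to the prior
  a_ls <- tryCatch(
    drop(stats::lm.fit(lx_t, j_obs - j0)$coefficients),
    error = function(e) rep(prior$mean, I)
  )
  a_ls[!is.finite(a_ls)] <- prior$mean

  with_seed(seed, {
    A <- matrix(a_ls,
      n_chains, I,
      byrow = TRUE
    ) + matrix(
      stats::rnorm(n_chains * I, 0, 0.1 * sqrt(prior$variance)),
      n_chains, I
    )
    lp <- log_post(A)
    scale <- matrix(0.5 * sqrt(prior$variance), n_chains, I)
    n_iter <- burn_in + n_samples * thin
    kept <- array(NA_real_,
      dim = c(n_samples, n_chains, I),
      dimnames = list(NULL, NULL, problem$metabolites)
    )
    acc <- 0
    k_out <- 0L
    for (it in seq_len(n_iter)) {
      prop <- A + matrix(stats::rnorm(n_chains * I), n_chains, I) * scale
      lp_prop <- log_post(prop)
      u <- log(stats::runif(n_chains))
      take <- u < (lp_prop - lp)
      if (any(take)) {
        A[take, ] <- prop[take, , drop = FALSE]
        lp[take] <- lp_prop[take]
      }
      if (it <= burn_in) {
        # Robbins-Monro adaptation toward the 0.234 target, frozen afterwards
        scale <- scale * exp(0.05 * (take - 0.234))
      }
      if (it > burn_in) {
        acc <- acc + sum(take)
        if ((it - burn_in) %% thin == 0) {
          k_out <- k_out + 1L
          kept[k_out, , ] <- A
        }
      }
    }
    rhat <- vapply(seq_len(I), function(p) {
      gelman_rubin(kept[, , p, drop = FALSE][, , 1])
    }, 0)
    names(rhat) <- problem$metabolites
    flat <- apply(kept, 3, identity) # (samples*chains) x I
    post_mean <- colMeans(flat)
    ci <- t(apply(flat, 2, stats::quantile, probs = c(0.025, 0.975)))
    colnames(ci) <- c("lower", "upper")
    converged <- all(rhat < rhat_threshold)
    if (!converged) {
      warning(
        "chains not converged (max rhat = ", signif(max(rhat), 4), ")"
      )
    }
    structure(
      list(
        samples = kept, mean = post_mean, ci = ci, rhat = rhat,
        acceptance_rate = acc / (n_chains * (n_iter - burn_in)),
        converged = converged, prior = prior, problem = problem,
        n_chains = n_chains, n_samples = n_samples
      ),
      class = "thermo_posterior"
    )
  })
}

#' @export
print.thermo_posterior <- function(x, ...) {
  cat(
    "thermo_posterior for", x$problem$reaction, "-", x$n_chains, "chains x",
    x$n_samples, "samples; converged:", x$converged, "\n"
  )
  print(data.frame(
    mean = x$mean, lower = x$ci[, "lower"], upper = x$ci[, "upper"],
    rhat = x$rhat
  ))
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Between/within-chain variance diagnostic for one parameter.
#'
#' @param chains matrix iterations x chains (>= 2 chains, >= 10 iterations).
#' @return the rhat statistic.
#' @export
gelman_rubin <- function(chains) {
  chains <- as.matrix(chains)
  m <- ncol(chains)
  n <- nrow(chains)
  if (m < 2) stop("Gelman-Rubin needs at least 2 chains")
  if (n < 10) stop("chains too short (need >= 10 iterations)")
  means <- colMeans(chains)
  W <- mean(apply(chains, 2, stats::var))
  B <- n * stats::var(means)
  var_hat <- (n - 1) / n * W + B / n
  if (W == 0) {
    return(if (B == 0) 1 else Inf)
  }
  sqrt(var_hat / W)
}

#' Classify a metabolite's allosteric effect
#'
#' Activation if the credible interval of its intrinsic turnover number lies
#' entirely above zero, inhibition if entirely below, none otherwise.
#' Classification is refused on unconverged posteriors.
#'
#' @param posterior a `thermo_posterior`.
#' @param parameter metabolite name or index.
#' @param credibility credible-interval mass (default 0.95).
#' @return `"activation"`, `"inhibition"` or `"none"`.
#' @export
classify_effect <- function(posterior, parameter, credibility = 0.95) {
  if (!posterior$converged) {
    stop("posterior not converged: classification refused")
  }
  flat <- apply(posterior$samples, 3, identity)
  idx <- if (is.character(parameter)) {
    match(parameter, posterior$problem$metabolites)
  } else {
    parameter
  }
  if (is.na(idx)) stop("unknown parameter: ", parameter)
  alpha <- (1 - credibility) / 2
  ci <- stats::quantile(flat[, idx], probs = c(alpha, 1 - alpha))
  if (ci[1] > 0) {
    "activation"
  } else if (ci[2] < 0) {
    "inhibition"
  } else {
    "none"
  }
}
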