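#' Simulate a glucose-limited chemostat series
#'
#' Generates per-condition physiology for a series of steady states: specific
#' growth rates (equal to the dilution rate), glucose/ethanol/O2/CO2 specific
#' exchange rates, the respiratory quotient, and per-cell biomass constants.
#' The series switches from purely respiratory to respirofermentative
#' metabolism at `critical_rate` (the Crabtree switch): ethanol secretion is
#' zero strictly below the critical rate and turns on at and above it.
#' O2/CO2 decoupling (RQ rising above 1) starts at `decoupling_rate`, which
#' defaults to the critical rate but may be set earlier.
#'
#' The default growth-rate grid spans `mu_min`..`mu_max` uniformly, with the
#' interior point closest to `critical_rate` snapped onto it, mimicking an
#' experimental design that samples the switch point itself.
#'
#' Uptake fluxes are negative (mmol per gram dry weight per hour); secretion
#' positive. RQ is exactly `q_co2 / |q_o2|` by construction.
#'
#' @param n_conditions number of steady states (>= 3).
#' @param mu_min,mu_max range of dilution rates (1/h).
#' @param critical_rate growth rate at which aerobic ethanol formation starts
#'   (1/h).
#' @param decoupling_rate growth rate at which RQ rises above 1; defaults to
#'   `critical_rate`.
#' @param seed integer seed; identical seeds give identical series.
#' @param mu_grid optional explicit strictly increasing vector of growth
#'   rates, overriding the default grid (its length then defines
#'   `n_conditions`).
#' @param noise_cv coefficient of variation of the multiplicative measurement
#'   noise on glucose and O2 rates (default 0.01). RQ and ethanol structure
#'   are preserved exactly regardless of noise.
#' @param cell_mass dry mass per cell in pg (default 13).
#' @return a `chemostat_series` data frame with columns `condition`, `mu`,
#'   `q_gluc`, `q_etoh`, `q_o2`, `q_co2`, `rq`, `cell_mass`,
#'   `protein_content`, and attributes `critical_rate` / `decoupling_rate`.
#' @export
generate_chemostat_series <- function(n_conditions = 9,
                                      mu_min = 0.025,
                                      mu_max = 0.4,
                                      critical_rate = 0.28,
                                      decoupling_rate = critical_rate,
                                      seed = 1,
                                      mu_grid = NULL,
                                      noise_cv = 0.01,
                                      cell_mass = 13) {
  if (!(mu_min > 0)) stop("configuration error: mu_min must be > 0")
  if (!(mu_min < decoupling_rate)) {
    stop("configuration error: mu_min must be < decoupling_rate")
  }
  if (!(decoupling_rate <= critical_rate)) {
    stop("configuration error: decoupling_rate must be <= critical_rate")
  }
  if (!(critical_rate < mu_max)) {
    stop("configuration error: critical_rate must be < mu_max")
  }
  if (n_conditions < 3) stop("configuration error: n_conditions must be >= 3")

  if (is.null(mu_grid)) {
    mu <- seq(mu_min, mu_max, length.out = n_conditions)
    interior <- 2:(n_conditions - 1)
    snap <- interior[which.min(abs(mu[interior] - critical_rate))]
    mu[snap] <- critical_rate
    mu <- sort(mu)
  } else {
    mu <- mu_grid
    if (any(diff(mu) <= 0)) stop("mu_grid must be strictly increasing")
    n_conditions <- length(mu)
  }

  ferm <- mu >= critical_rate
  dec <- mu >= decoupling_rate

  with_seed(seed, {
    # Glucose uptake: respiratory demand (biomass yield ~0.5 g/g) plus
    # fermentative overflow above the critical rate.
    q_gluc_base <- -(mu / 0.5 / 0.180) - ifelse(ferm, 55 * (mu - critical_rate), 0)
    q_gluc <- q_gluc_base * lognormal_noise(n_conditions, noise_cv)

    # O2 uptake rises with respiration, then declines in overflow metabolism.
    q_o2_base <- -ifelse(ferm,
      22 * critical_rate - 10 * (mu - critical_rate),
      22 * mu
    )
    q_o2 <- q_o2_base * lognormal_noise(n_conditions, noise_cv)

    # Ethanol: zero below the switch, onset value plus linear rise above.
    q_etoh <- ifelse(ferm, 0.15 + 60 * (mu - critical_rate), 0)

    # RQ exactly 1 while coupled; jumps above 1 at decoupling.
    rq <- ifelse(dec, 1.05 + 4 * (mu - decoupling_rate), 1)
    q_co2 <- rq * abs(q_o2)

    protein_content <- cell_mass * (0.44 + 0.2 * mu)

    out <- data.frame(
      condition = sprintf("D%03.0f", 1000 * mu),
      mu = mu,
      q_gluc = q_gluc,
      q_etoh = q_etoh,
      q_o2 = q_o2,
      q_co2 = q_co2,
      rq = rq,
      cell_mass = cell_mass,
      protein_content = protein_content,
      stringsAsFactors = FALSE
    )
    attr(out, "critical_rate") <- critical_rate
    attr(out, "decoupling_rate") <- decoupling_rate
    class(out) <- c("chemostat_series", "data.frame")
    out
  })
}

#' Write / read a chemostat series as TSV
#'
#' @param x a `chemostat_series`.
#' @param path file path.
#' @export
write_chemostat_series <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# critical_rate: %.17g", attr(x, "critical_rate")), con)
  writeLines(sprintf("# decoupling_rate: %.17g", attr(x, "decoupling_rate")), con)
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], format_full)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chemostat_series
#' @export
read_chemostat_series <- function(path) {
  header <- grep("^# ", readLines(path, n = 5), value = TRUE)
  num_meta <- function(key) {
    hit <- grep(paste0("^# ", key, ": "), header, value = TRUE)
    if (!length(hit)) {
      return(NA_real_)
    }
    as.numeric(sub(paste0("^# ", key, ": "), "", hit[1]))
  }
  df <- utils::read.table(path,
    header = TRUE, sep = "\t", comment.char = "#",
    stringsAsFactors = FALSE
  )
  attr(df, "critical_rate") <- num_meta("critical_rate")
  attr(df, "decoupling_rate") <- num_meta("decoupling_rate")
  class(df) <- c("chemostat_series", "data.frame")
  df
}
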