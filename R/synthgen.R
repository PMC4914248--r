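#' Configuration for the synthetic expression / survival generator
#'
#' Bundles and validates the parameters of [simulate_expression()] and
#' [simulate_survival()]. The generator plants a subgroup of samples in which
#' the two reserved target probes (`"GENE_A"`, `"GENE_B"`; think TP73 and
#' POSTN) are correlated at `rho_in`, while the remaining samples have pair
#' correlation `rho_out`. Survival times are exponential with the planted
#' subgroup's hazard multiplied by `hazard_ratio`, under independent
#' exponential censoring.
#'
#' A single integer `seed` drives both stages through documented sub-streams:
#' expression uses `set.seed(seed)`, survival uses `set.seed(seed + 1)`.
#'
#' @param n_samples Number of samples (columns). At least 2.
#' @param n_probes Number of probes (rows), at least 2; the first two are the
#'   reserved target pair, the rest are i.i.d. standard-normal background.
#' @param planted_fraction Proportion of samples in the planted subgroup, in
#'   \[0, 1\]. Strictly between 0 and 1 both classes are guaranteed nonempty.
#' @param rho_in Pair correlation within the planted subgroup, in \[-1, 1\].
#' @param rho_out Pair correlation outside the planted subgroup, in \[-1, 1\].
#' @param hazard_ratio Positive multiplier on the event hazard of planted
#'   samples.
#' @param baseline_hazard Positive event hazard per unit time for non-planted
#'   samples.
#' @param censor_rate Non-negative censoring hazard per unit time; 0 disables
#'   censoring.
#' @param seed Integer seed (absolute value below 2^30 so stage sub-streams
#'   stay valid 32-bit seeds).
#'
#' @return A list of class `"simulation_config"`.
#' @examples
#' cfg <- simulation_config(n_samples = 50, n_probes = 20, seed = 7)
#' sim <- simulate_expression(cfg)
#' dim(sim$matrix)
#' @export
simulation_config <- function(n_samples,
                              n_probes = 100L,
                              planted_fraction = 0.5,
                              rho_in = 0.8,
                              rho_out = 0,
                              hazard_ratio = 2,
                              baseline_hazard = 0.1,
                              censor_rate = 0.02,
                              seed = 1L) {
  check_count <- function(x, nm, min) {
    if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min)
      stop("configuration error: '", nm, "' must be a single integer >= ", min,
           call. = FALSE)
  }
  check_count(n_samples, "n_samples", 2)
  check_count(n_probes, "n_probes", 2)
  if (length(planted_fraction) != 1L || !is.numeric(planted_fraction) ||
      is.na(planted_fraction) || planted_fraction < 0 || planted_fraction > 1)
    stop("configuration error: 'planted_fraction' must be in [0, 1]", call. = FALSE)
  for (nm in c("rho_in", "rho_out")) {
    rho <- get(nm)
    if (length(rho) != 1L || !is.numeric(rho) || is.na(rho) || abs(rho) > 1)
      stop("configuration error: '", nm, "' must be a correlation in [-1, 1]",
           call. = FALSE)
  }
  for (nm in c("hazard_ratio", "baseline_hazard")) {
    h <- get(nm)
    if (length(h) != 1L || !is.numeric(h) || is.na(h) || h <= 0)
      stop("configuration error: '", nm, "' must be a positive real", call. = FALSE)
  }
  if (length(censor_rate) != 1L || !is.numeric(censor_rate) ||
      is.na(censor_rate) || censor_rate < 0)
    stop("configuration error: 'censor_rate' must be >= 0 (0 disables censoring)",
         call. = FALSE)
  if (length(seed) != 1L || !is.numeric(seed) || is.na(seed) ||
      seed != round(seed) || abs(seed) >= 2^30)
    stop("configuration error: 'seed' must be an integer with |seed| < 2^30",
         call. = FALSE)
  structure(
    list(n_samples = as.integer(n_samples),
         n_probes = as.integer(n_probes),
         planted_fraction = planted_fraction,
         rho_in = rho_in, rho_out = rho_out,
         hazard_ratio = hazard_ratio,
         baseline_hazard = baseline_hazard,
         censor_rate = censor_rate,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Simulate an expression matrix with a planted correlated subgroup
#'
#' Draws a probes x samples matrix in which the reserved target pair
#' (`"GENE_A"`, `"GENE_B"`) follows a standard bivariate normal with
#' correlation `rho_in` for samples in the planted subgroup and `rho_out`
#' otherwise; all background probes are i.i.d. standard normal. Planted
#' membership is a random subset of size `round(planted_fraction * n_samples)`
#' (clamped so both classes are nonempty when the fraction is strictly
#' between 0 and 1). Fully reproducible: the same configuration yields an
#' identical matrix and labels.
#'
#' @param config A [simulation_config()] object.
#' @return A list with components `matrix` (numeric, probes x samples, with
#'   probe rownames and sample colnames) and `labels` (a data.frame with
#'   columns `sample_id` and logical `in_planted`).
#' @examples
#' sim <- simulate_expression(simulation_config(40, 10, seed = 3))
#' table(sim$labels$in_planted)
#' @export
simulate_expression <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop("configuration error: 'config' must come from simulation_config()",
         call. = FALSE)
  n <- config$n_samples
  p <- config$n_probes
  set.seed(config$seed)

  n_planted <- as.integer(round(config$planted_fraction * n))
  if (config$planted_fraction > 0 && config$planted_fraction < 1)
    n_planted <- min(max(n_planted, 1L), n - 1L)
  in_planted <- rep(FALSE, n)
  if (n_planted > 0L) in_planted[sample.int(n, n_planted)] <- TRUE

  sample_ids <- sprintf("S%0*d", nchar(n), seq_len(n))
  probe_ids <- c("GENE_A", "GENE_B",
                 if (p > 2L) sprintf("BG_%0*d", nchar(p), seq_len(p - 2L)))

  # target pair: b = rho*a + sqrt(1-rho^2)*eps gives exact marginal N(0,1)
  # and correlation rho
  a <- stats::rnorm(n)
  eps <- stats::rnorm(n)
  rho <- ifelse(in_planted, config$rho_in, config$rho_out)
  b <- rho * a + sqrt(1 - rho^2) * eps

  mat <- matrix(NA_real_, nrow = p, ncol = n,
                dimnames = list(probe_ids, sample_ids))
  mat[1L, ] <- a
  mat[2L, ] <- b
  if (p > 2L)
    mat[3:p, ] <- stats::rnorm((p - 2L) * n)

  labels <- data.frame(sample_id = sample_ids, in_planted = in_planted,
                       stringsAsFactors = FALSE)
  list(matrix = mat, labels = labels)
}

#' Simulate survival times whose hazard depends on planted membership
#'
#' Event times are exponential with rate `baseline_hazard` for non-planted
#' samples and `baseline_hazard * hazard_ratio` for planted samples.
#' Censoring times are independent exponentials at `censor_rate` (a rate of 0
#' disables censoring). The observed time is the minimum of the two and the
#' event indicator is 1 when the event precedes censoring.
#'
#' Uses the survival sub-stream `set.seed(config$seed + 1)` so that
#' expression and survival draws are independent but jointly reproducible.
#'
#' @param labels Data frame with columns `sample_id` and `in_planted`, as
#'   returned by [simulate_expression()].
#' @param config A [simulation_config()] object.
#' @return A data.frame with columns `sample_id`, `time` (non-negative) and
#'   `event` (integer 0/1).
#' @examples
#' cfg <- simulation_config(30, 5, hazard_ratio = 3, seed = 11)
#' sim <- simulate_expression(cfg)
#' surv <- simulate_survival(sim$labels, cfg)
#' head(surv)
#' @export
simulate_survival <- function(labels, config) {
  if (!inherits(config, "simulation_config"))
    stop("configuration error: 'config' must come from simulation_config()",
         call. = FALSE)
  if (!is.data.frame(labels) || nrow(labels) == 0L ||
      !all(c("sample_id", "in_planted") %in% names(labels)))
    stop("'labels' must be a nonempty data.frame with sample_id and in_planted",
         call. = FALSE)
  n <- nrow(labels)
  set.seed(config$seed + 1L)
  rate <- config$baseline_hazard *
    ifelse(labels$in_planted, config$hazard_ratio, 1)
  event_time <- stats::rexp(n, rate)
  if (config$censor_rate > 0) {
    censor_time <- stats::rexp(n, config$censor_rate)
    data.frame(sample_id = labels$sample_id,
               time = pmin(event_time, censor_time),
               event = as.integer(event_time <= censor_time),
               stringsAsFactors = FALSE)
  } else {
    data.frame(sample_id = labels$sample_id,
               time = event_time,
               event = 1L,
               stringsAsFactors = FALSE)
  }
}
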