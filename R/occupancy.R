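#' Assemble data for the multi-species occupancy model
#'
#' Bundles binary detection histories with the two detection covariates the
#' model uses: site canopy coverage (centered internally) and the survey
#' period within the morning (3-level factor, first level the reference).
#'
#' @param y Binary detection array, sites x occasions x species (dimnames
#'   optional but recommended).
#' @param canopy Canopy coverage fraction per site, in `[0, 1]`.
#' @param period Period label per survey occasion (length = number of
#'   occasions); the occasion-to-period map is shared by all sites.
#' @param periods Ordered period levels; the first is the reference.
#' @param native Optional logical vector per species.
#' @return Object of class `occupancy_data`.
#' @export
occupancy_data <- function(y, canopy, period,
                           periods = c("before_sunrise", "sunrise",
                                       "after_sunrise"),
                           native = NULL) {
  if (length(dim(y)) != 3L)
    stop("occupancy_data: y must be a 3-d array (sites x occasions x species)",
         call. = FALSE)
  if (!all(y %in% c(0L, 1L)))
    stop("occupancy_data: y must be binary", call. = FALSE)
  I <- dim(y)[1]; J <- dim(y)[2]; S <- dim(y)[3]
  if (length(canopy) != I)
    stop("occupancy_data: canopy must have one value per site", call. = FALSE)
  if (any(!is.finite(canopy)))
    stop("occupancy_data: canopy must be finite", call. = FALSE)
  if (length(period) != J)
    stop("occupancy_data: period must have one label per survey occasion",
         call. = FALSE)
  pidx <- match(period, periods)
  if (anyNA(pidx))
    stop("occupancy_data: unknown period label(s): ",
         paste(setdiff(period, periods), collapse = ", "), call. = FALSE)
  species <- dimnames(y)[[3]]
  if (is.null(species)) species <- paste0("sp", seq_len(S))
  if (!is.null(native) && length(native) != S)
    stop("occupancy_data: native flags must match the species dimension",
         call. = FALSE)
  structure(list(y = y, canopy = as.numeric(canopy),
                 canopy_centered = as.numeric(canopy - mean(canopy)),
                 period = period, period_idx = pidx, periods = periods,
                 species = species, native = native,
                 sites = dimnames(y)[[1]] %||% paste0("site", seq_len(I))),
            class = "occupancy_data")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.occupancy_data <- function(x, ...) {
  d <- dim(x$y)
  cat("Occupancy data: ", d[3], " species x ", d[1], " sites x ", d[2],
      " survey occasions\n", sep = "")
  invisible(x)
}

#' Build occupancy-model data from a simulation
#'
#' @param sim A [simulate_community()] bundle or a
#'   [simulate_detections()] history.
#' @return An [occupancy_data()] object.
#' @export
as_occupancy_data <- function(sim) {
  dh <- if (inherits(sim, "community_sim")) sim$detections else sim
  stopifnot(inherits(dh, "detection_history"))
  occupancy_data(dh$y, canopy = dh$frame$sites$canopy,
                 period = period_of_occasion(dh$frame$design),
                 periods = dh$frame$design$periods,
                 native = dh$native)
}

#' Read occupancy-model data from CSV files
#'
#' `detections_csv` needs columns `species,site,occasion,period,y`;
#' `sites_csv` needs `site` and either `canopy` (fraction) or
#' `canopy_class`.
#'
#' @param detections_csv,sites_csv File paths.
#' @param periods Ordered period levels.
#' @param canopy_levels Mapping from canopy classes to coverage fractions.
#' @return An [occupancy_data()] object.
#' @export
occupancy_data_from_csv <- function(detections_csv, sites_csv,
                                    periods = c("before_sunrise", "sunrise",
                                                "after_sunrise"),
                                    canopy_levels = c(open = 0,
                                                      open_moderate = 0.25,
                                                      moderate = 0.5,
                                                      moderate_covered = 0.75,
                                                      covered = 1)) {
  det <- utils::read.csv(detections_csv, stringsAsFactors = FALSE)
  sites <- utils::read.csv(sites_csv, stringsAsFactors = FALSE)
  need <- setdiff(c("species", "site", "occasion", "period", "y"), names(det))
  if (length(need))
    stop("detections CSV is missing columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(sites$canopy)) {
    if (is.null(sites$canopy_class))
      stop("sites CSV needs 'canopy' or 'canopy_class'", call. = FALSE)
    sites$canopy <- unname(canopy_levels[sites$canopy_class])
  }
  sp <- unique(det$species); st <- sites$site; occ <- sort(unique(det$occasion))
  y <- array(0L, c(length(st), length(occ), length(sp)),
             dimnames = list(st, occ, sp))
  y[cbind(match(det$site, st), match(det$occasion, occ),
          match(det$species, sp))] <- as.integer(det$y)
  per <- det$period[match(occ, det$occasion)]
  occupancy_data(y, sites$canopy, per, periods = periods)
}

params_template <- function(data) {
  S <- dim(data$y)[3]
  list(psi = rep(0.5, S), alpha = rep(0, S), beta_canopy = rep(0, S),
       beta_period = matrix(0, S, 2))
}

species_eta <- function(data, s, params) {
  bp <- c(0, params$beta_period[s, 1], params$beta_period[s, 2])
  outer(params$alpha[s] + params$beta_canopy[s] * data$canopy_centered,
        bp[data$period_idx], "+")
}

#' Marginal log-likelihood of the occupancy model
#'
#' The latent occupancy state is summed out analytically: each site-species
#' cell contributes `log(psi * prod_j p^y (1-p)^(1-y) + (1-psi) * I(all y = 0))`
#' with `p` from the logit-linear detection predictor.
#'
#' @param data An [occupancy_data()].
#' @param params List with `psi` (length S), `alpha` (length S),
#'   `beta_canopy` (length S) and `beta_period` (S x 2 matrix of the
#'   sunrise and after-sunrise contrasts).
#' @return Scalar log-likelihood.
#' @export
marginal_log_likelihood <- function(data, params) {
  stopifnot(inherits(data, "occupancy_data"))
  if (any(!is.finite(unlist(params))))
    stop("marginal_log_likelihood: parameters must be finite", call. = FALSE)
  S <- dim(data$y)[3]
  I <- dim(data$y)[1]; J <- dim(data$y)[2]
  total <- 0
  for (s in seq_len(S)) {
    eta <- species_eta(data, s, params)
    ys <- matrix(data$y[, , s], I, J)
    # log prod_j p^y (1-p)^(1-y), numerically via plogis on the log scale
    lp <- stats::plogis(eta, log.p = TRUE)
    lq <- stats::plogis(-eta, log.p = TRUE)
    site_ll <- rowSums(ys * lp + (1 - ys) * lq)
    none <- rowSums(ys) == 0
    psi <- params$psi[s]
    total <- total + sum(log(psi * exp(site_ll) + (1 - psi) * none))
  }
  total
}

#' Full conditional of the latent occupancy state
#'
#' `P(z = 1 | y, psi, p)` per site and species: 1 wherever the species was
#' detected; otherwise `psi q / (psi q + 1 - psi)` with
#' `q = prod_j (1 - p_ij)`.
#'
#' @inheritParams marginal_log_likelihood
#' @return Matrix (sites x species) of conditional occupancy probabilities.
#' @export
z_conditional <- function(data, params) {
  stopifnot(inherits(data, "occupancy_data"))
  S <- dim(data$y)[3]; I <- dim(data$y)[1]
  out <- matrix(NA_real_, I, S, dimnames = list(data$sites, data$species))
  J <- dim(data$y)[2]
  for (s in seq_len(S)) {
    eta <- species_eta(data, s, params)
    q <- exp(rowSums(stats::plogis(-eta, log.p = TRUE)))
    psi <- params$psi[s]
    pz <- psi * q / (psi * q + 1 - psi)
    pz[rowSums(matrix(data$y[, , s], I, J)) > 0] <- 1
    out[, s] <- pz
  }
  out
}

#' @rdname z_conditional
#' @param seed Integer seed for the Bernoulli draw.
#' @return `update_z` returns a sampled binary matrix (sites x species).
#' @export
update_z <- function(data, params, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  pz <- z_conditional(data, params)
  matrix(stats::rbinom(length(pz), 1L, pz), nrow(pz), ncol(pz),
         dimnames = dimnames(pz))
}

#' MCMC settings for the occupancy sampler
#'
#' Defaults follow the survey's fitting protocol: three independent chains
#' of 10,000 iterations, a burn-in of 5,000, and a thinning rate of three.
#'
#' @param n_chains Number of independent chains.
#' @param n_iter Iterations per chain.
#' @param burn_in Burn-in iterations (must be `< n_iter`); proposal scales
#'   adapt only during burn-in.
#' @param thin Thinning rate (`>= 1`).
#' @param n_sweeps Number of full update sweeps composing one transition-
#'   kernel application (iteration).  Burn-in, thinning and the retained
#'   sample count are in iterations; extra sweeps only sharpen mixing.
#' @param seed Integer master seed.
#' @param hyper_mu_sd Prior sd of the community means (Normal(0, .)).
#' @param hyper_sd_max Upper bound of the Uniform prior on community sds.
#' @param fix_hypers If `TRUE`, hold the community hyperparameters fixed at
#'   `fixed_mu` / `fixed_sd` instead of sampling them (used for single-
#'   species fits against reference posteriors).
#' @param fixed_mu,fixed_sd Length-4 values (intercept, canopy, sunrise,
#'   after-sunrise families) used when `fix_hypers = TRUE`, and as initial
#'   hyper values otherwise.
#' @param use_canopy,use_period Include the covariate families?  When off,
#'   the corresponding slopes are pinned at zero.
#' @return List of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3L, n_iter = 10000L, burn_in = 5000L,
                        thin = 3L, n_sweeps = 3L, seed = 1L,
                        hyper_mu_sd = 10, hyper_sd_max = 10,
                        fix_hypers = FALSE,
                        fixed_mu = rep(0, 4), fixed_sd = rep(10, 4),
                        use_canopy = TRUE, use_period = TRUE) {
  if (burn_in >= n_iter) stop("mcmc_config: burn_in must be < n_iter",
                              call. = FALSE)
  if (thin < 1L) stop("mcmc_config: thin must be >= 1", call. = FALSE)
  if (n_chains < 1L) stop("mcmc_config: need at least one chain",
                          call. = FALSE)
  if (n_sweeps < 1L) stop("mcmc_config: n_sweeps must be >= 1", call. = FALSE)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 n_sweeps = as.integer(n_sweeps),
                 seed = as.integer(seed), hyper_mu_sd = hyper_mu_sd,
                 hyper_sd_max = hyper_sd_max, fix_hypers = fix_hypers,
                 fixed_mu = fixed_mu, fixed_sd = fixed_sd,
                 use_canopy = use_canopy, use_period = use_period),
            class = "mcmc_config")
}

mcmc_param_names <- function(data, config) {
  sp <- data$species
  nm <- c(sprintf("psi[%s]", sp), sprintf("alpha[%s]", sp))
  if (config$use_canopy) nm <- c(nm, sprintf("beta_canopy[%s]", sp))
  if (config$use_period)
    nm <- c(nm, sprintf("beta_sunrise[%s]", sp),
            sprintf("beta_after_sunrise[%s]", sp))
  if (!config$fix_hypers) {
    fams <- c("alpha", if (config$use_canopy) "beta_canopy",
              if (config$use_period) c("beta_sunrise", "beta_after_sunrise"))
    for (f in fams) nm <- c(nm, paste0("mu_", f), paste0("sd_", f))
  }
  c(nm, sprintf("zprop[%s]", sp))
}

#' Fit the multi-species occupancy model by MCMC
#'
#' Metropolis-within-Gibbs: exact Gibbs updates for the latent occupancy
#' state and (via the conjugate Beta full conditional under the uniform
#' prior) for each species' occupancy probability; random-walk Metropolis
#' for the detection intercepts and slopes with normally distributed
#' community priors; conjugate updates for the community means and
#' Metropolis updates for the community standard deviations (Uniform(0, 10)
#' priors).  Proposal scales adapt towards a 20-40% acceptance rate during
#' burn-in only.  Fully reproducible given the seed.
#'
#' @param data An [occupancy_data()].
#' @param config An [mcmc_config()].
#' @return Object of class `occupancy_chains`: `draws` (list of per-chain
#'   matrices of retained draws, columns named), `params` (monitored model
#'   parameters), `derived` (derived columns: realized occupancy
#'   proportions), `config`, `data`.
#' @export
run_mcmc <- function(data, config = mcmc_config()) {
  stopifnot(inherits(data, "occupancy_data"), inherits(config, "mcmc_config"))
  S <- dim(data$y)[3]
  y_list <- lapply(seq_len(S), function(s)
    matrix(as.integer(data$y[, , s]), dim(data$y)[1], dim(data$y)[2]))

  nm <- mcmc_param_names(data, config)
  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max, config$n_chains)

  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(chain_seeds[ch])
    # overdispersed starting points so the Gelman-Rubin diagnostic is honest
    init_psi <- stats::rbeta(S, 2, 2)
    init_alpha <- stats::rnorm(S, 0, 1)
    init_bC <- if (config$use_canopy) stats::rnorm(S, 0, 1) else rep(0, S)
    init_b2 <- if (config$use_period) stats::rnorm(S, 0, 1) else rep(0, S)
    init_b3 <- if (config$use_period) stats::rnorm(S, 0, 1) else rep(0, S)
    if (config$fix_hypers) {
      mu0 <- config$fixed_mu; sd0 <- config$fixed_sd
    } else {
      mu0 <- stats::rnorm(4, 0, 1)
      sd0 <- stats::runif(4, 0.5, 2)
    }
    res <- occ_chain_cpp(y_list, data$canopy_centered, data$period_idx,
                         config$n_iter, config$burn_in, config$thin,
                         config$n_sweeps,
                         config$use_canopy, config$use_period,
                         !config$fix_hypers, mu0, sd0,
                         config$hyper_mu_sd, config$hyper_sd_max,
                         init_psi, init_alpha, init_bC, init_b2, init_b3)
    draws <- res$draws
    colnames(draws) <- nm
    chains[[ch]] <- draws
  }
  structure(list(draws = chains,
                 params = nm[!startsWith(nm, "zprop[")],
                 derived = nm[startsWith(nm, "zprop[")],
                 config = config, data = data),
            class = "occupancy_chains")
}

#' @export
print.occupancy_chains <- function(x, ...) {
  cat("Occupancy MCMC: ", length(x$draws), " chains x ",
      nrow(x$draws[[1]]), " retained draws, ", length(x$params),
      " model parameters\n", sep = "")
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic between/within-chain variance diagnostic,
#' `sqrt(((n-1)/n W + B/n) / W)`.  With `split = TRUE` each chain is halved
#' first (the split-chain variant, sensitive to within-chain trends).
#' Chains with zero total variance return 1 by convention, with a warning.
#'
#' @param chains An `occupancy_chains` object or a list of draw matrices
#'   with identical column names.
#' @param parameter Parameter name(s); default all columns.
#' @param split Use the split-chain variant?
#' @return Named numeric vector of R-hat values.
#' @export
gelman_rubin <- function(chains, parameter = NULL, split = FALSE) {
  draws <- if (inherits(chains, "occupancy_chains")) chains$draws else chains
  stopifnot(is.list(draws), length(draws) >= 2L)
  if (is.null(parameter)) parameter <- colnames(draws[[1]])
  vapply(parameter, function(par) {
    m <- lapply(draws, function(d) as.numeric(d[, par]))
    if (split) {
      m <- unlist(lapply(m, function(v) {
        h <- floor(length(v) / 2)
        list(v[seq_len(h)], v[(h + 1):(2 * h)])
      }), recursive = FALSE)
    }
    n <- length(m[[1]])
    if (n < 2L) stop("gelman_rubin: need at least 2 retained draws",
                     call. = FALSE)
    W <- mean(vapply(m, stats::var, numeric(1)))
    B <- n * stats::var(vapply(m, mean, numeric(1)))
    if (W == 0) {
      if (B == 0) {
        warning("gelman_rubin: zero variance for '", par,
                "'; R-hat = 1 by convention")
        return(1)
      }
      return(Inf)
    }
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
}

#' Naive occupancy
#'
#' Proportion of survey sites at which a species was detected at least
#' once — the detection-uncorrected lower bound on occupancy.
#'
#' @param data An [occupancy_data()].
#' @param species Species name(s); default all.
#' @return Named numeric vector of proportions.
#' @export
naive_occupancy <- function(data, species = NULL) {
  stopifnot(inherits(data, "occupancy_data"))
  if (dim(data$y)[1] < 1L) stop("naive_occupancy: need at least one site",
                                call. = FALSE)
  if (is.null(species)) species <- data$species
  vapply(species, function(sp) {
    s <- match(sp, data$species)
    mean(rowSums(data$y[, , s, drop = FALSE]) > 0)
  }, numeric(1))
}

#' Summarize the posterior
#'
#' Pools retained draws across chains and reports, per parameter, the
#' posterior mean, sd, equal-tail 95% credible interval and R-hat; per
#' species, the estimated occupancy (posterior mean of psi), the posterior
#' realized occupancy proportion, naive occupancy, the mean survey-level
#' detection probability (posterior mean of the inverse-logit predictor at
#' the average canopy, averaged over the three periods), and covariate
#' association flags set when the 95% credible interval excludes zero.
#' A detection-by-period table gives each species' detection probability in
#' each period at average canopy.
#'
#' @param chains An `occupancy_chains` fit.
#' @param data The [occupancy_data()] used (defaults to the one stored in
#'   the fit).
#' @return List of class `occupancy_summary`: `parameters`, `species`,
#'   `detection_by_period`.
#' @export
summarize_posterior <- function(chains, data = chains$data) {
  stopifnot(inherits(chains, "occupancy_chains"))
  pooled <- do.call(rbind, chains$draws)
  all_cols <- colnames(pooled)
  rhat <- if (length(chains$draws) >= 2L) suppressWarnings(gelman_rubin(chains)) else
    stats::setNames(rep(NA_real_, length(all_cols)), all_cols)

  parameters <- data.frame(
    parameter = all_cols,
    mean = colMeans(pooled),
    sd = apply(pooled, 2, stats::sd),
    q2.5 = apply(pooled, 2, stats::quantile, probs = 0.025),
    q97.5 = apply(pooled, 2, stats::quantile, probs = 0.975),
    rhat = unname(rhat[all_cols]),
    derived = all_cols %in% chains$derived,
    row.names = NULL, stringsAsFactors = FALSE)

  sp <- data$species
  cfg <- chains$config
  get <- function(par) pooled[, par]
  periods <- data$periods
  det_period <- matrix(NA_real_, length(sp), length(periods),
                       dimnames = list(sp, periods))
  for (s in seq_along(sp)) {
    a <- get(sprintf("alpha[%s]", sp[s]))
    b2 <- if (cfg$use_period) get(sprintf("beta_sunrise[%s]", sp[s])) else 0
    b3 <- if (cfg$use_period)
      get(sprintf("beta_after_sunrise[%s]", sp[s])) else 0
    det_period[s, ] <- c(mean(stats::plogis(a)),
                         mean(stats::plogis(a + b2)),
                         mean(stats::plogis(a + b3)))[seq_along(periods)]
  }

  ci_excludes_zero <- function(par) {
    r <- parameters[parameters$parameter == par, ]
    r$q2.5 > 0 || r$q97.5 < 0
  }
  species <- data.frame(
    species = sp,
    occupancy = vapply(sprintf("psi[%s]", sp),
                       function(p) mean(get(p)), numeric(1)),
    occupancy_q2.5 = vapply(sprintf("psi[%s]", sp), function(p)
      unname(stats::quantile(get(p), 0.025)), numeric(1)),
    occupancy_q97.5 = vapply(sprintf("psi[%s]", sp), function(p)
      unname(stats::quantile(get(p), 0.975)), numeric(1)),
    zprop = vapply(sprintf("zprop[%s]", sp),
                   function(p) mean(get(p)), numeric(1)),
    naive_occupancy = unname(naive_occupancy(data)),
    mean_detection = rowMeans(det_period),
    canopy_association = if (cfg$use_canopy)
      vapply(sprintf("beta_canopy[%s]", sp), ci_excludes_zero, logical(1))
      else NA,
    period_association = if (cfg$use_period)
      vapply(seq_along(sp), function(s)
        ci_excludes_zero(sprintf("beta_sunrise[%s]", sp[s])) ||
        ci_excludes_zero(sprintf("beta_after_sunrise[%s]", sp[s])),
        logical(1)) else NA,
    row.names = NULL, stringsAsFactors = FALSE)

  structure(list(parameters = parameters, species = species,
                 detection_by_period = as.data.frame(det_period)),
            class = "occupancy_summary")
}

#' @export
print.occupancy_summary <- function(x, digits = 3, ...) {
  cat("Posterior summary (", nrow(x$parameters), " monitored quantities, ",
      "max R-hat = ",
      format(max(x$parameters$rhat[!x$parameters$derived], na.rm = TRUE),
             digits = digits), ")\n", sep = "")
  print(x$species, digits = digits)
  invisible(x)
}
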