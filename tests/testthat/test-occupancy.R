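test_that("marginal likelihood matches the closed forms", {
  y <- array(1L, c(1, 1, 1), dimnames = list("s1", 1, "spA"))
  d <- occupancy_data(y, canopy = 0.5, period = "before_sunrise")
  pars <- list(psi = 0.5, alpha = 0, beta_canopy = 0,
               beta_period = matrix(0, 1, 2))
  expect_equal(marginal_log_likelihood(d, pars), log(0.25), tolerance = 1e-12)

  y0 <- array(0L, c(1, 3, 1), dimnames = list("s1", 1:3, "spA"))
  d0 <- occupancy_data(y0, canopy = 0.5, period = rep("before_sunrise", 3))
  expect_equal(marginal_log_likelihood(d0, pars), log(0.5625),
               tolerance = 1e-12)

  ybad <- array(2L, c(1, 1, 1))
  expect_error(occupancy_data(ybad, 0.5, "before_sunrise"), "binary")
})

test_that("marginal likelihood equals exhaustive latent-state enumeration", {
  set.seed(61)
  for (i in 1:200) {
    inst <- random_occ_instance()
    expect_equal(marginal_log_likelihood(inst$data, inst$params),
                 oracle_enum_loglik(inst$y, inst$params$psi, inst$p),
                 tolerance = 1e-10)
  }
})

test_that("the latent-state full conditional is exact", {
  # detection forces z = 1
  y <- array(c(1L, 0L), c(2, 1, 1), dimnames = list(c("s1", "s2"), 1, "spA"))
  d <- occupancy_data(y, canopy = c(0, 0), period = "before_sunrise")
  # site 2 undetected: psi = 0.8, single survey with p = 0.75 -> 0.5
  pars <- list(psi = 0.8, alpha = qlogis(0.75), beta_canopy = 0,
               beta_period = matrix(0, 1, 2))
  pz <- z_conditional(d, pars)
  expect_equal(unname(pz["s1", 1]), 1)
  expect_equal(unname(pz["s2", 1]), 0.5, tolerance = 1e-12)
  # p = 0 on all surveys leaves the prior psi untouched
  pars0 <- list(psi = 0.5, alpha = -50, beta_canopy = 0,
                beta_period = matrix(0, 1, 2))
  expect_equal(unname(z_conditional(d, pars0)["s2", 1]), 0.5,
               tolerance = 1e-9)
  set.seed(1)
  z <- update_z(d, pars)
  expect_equal(unname(z["s1", 1]), 1L)
})

test_that("Gelman-Rubin follows its defining formula and conventions", {
  const <- list(matrix(rep(1, 100), ncol = 1, dimnames = list(NULL, "a")),
                matrix(rep(1, 100), ncol = 1, dimnames = list(NULL, "a")))
  expect_warning(r <- gelman_rubin(const, "a"), "convention")
  expect_equal(unname(r), 1)

  set.seed(62)
  iid <- list(matrix(rnorm(10000), ncol = 1, dimnames = list(NULL, "a")),
              matrix(rnorm(10000), ncol = 1, dimnames = list(NULL, "a")))
  r2 <- gelman_rubin(iid, "a")
  expect_gt(r2, 0.999); expect_lt(r2, 1.005)

  set.seed(63)
  far <- list(matrix(rnorm(1000, 0), ncol = 1, dimnames = list(NULL, "a")),
              matrix(rnorm(1000, 5), ncol = 1, dimnames = list(NULL, "a")))
  r3 <- gelman_rubin(far, "a")
  expect_gt(r3, 2)
  # direct evaluation of the defining formula
  n <- 1000
  W <- mean(c(var(far[[1]][, 1]), var(far[[2]][, 1])))
  B <- n * var(c(mean(far[[1]][, 1]), mean(far[[2]][, 1])))
  expect_equal(unname(r3), sqrt(((n - 1) / n * W + B / n) / W),
               tolerance = 1e-12)
  # split variant detects a within-chain trend
  trend <- list(matrix(seq(0, 5, length.out = 1000) + rnorm(1000, 0, .1),
                       ncol = 1, dimnames = list(NULL, "a")),
                matrix(seq(0, 5, length.out = 1000) + rnorm(1000, 0, .1),
                       ncol = 1, dimnames = list(NULL, "a")))
  expect_gt(gelman_rubin(trend, "a", split = TRUE), 1.1)
})

test_that("naive occupancy is the detected-site proportion", {
  y <- array(0L, c(15, 2, 1), dimnames = list(paste0("s", 1:15), 1:2, "spA"))
  y[1:12, 1, 1] <- 1L
  d <- occupancy_data(y, canopy = runif(15), period = rep("sunrise", 2),
                      periods = c("before_sunrise", "sunrise"))
  expect_equal(unname(naive_occupancy(d, "spA")), 0.8)
  y[] <- 0L
  d0 <- occupancy_data(y, canopy = runif(15), period = rep("sunrise", 2),
                       periods = c("before_sunrise", "sunrise"))
  expect_equal(unname(naive_occupancy(d0, "spA")), 0)
  y[] <- 1L
  d1 <- occupancy_data(y, canopy = runif(15), period = rep("sunrise", 2),
                       periods = c("before_sunrise", "sunrise"))
  expect_equal(unname(naive_occupancy(d1, "spA")), 1)
})

test_that("the sampler is reproducible and concentrates where it must", {
  sim <- simulate_community(study_design(n_sites_per_stratum = 2,
                                         n_mornings = 2), seed = 64)
  od <- as_occupancy_data(sim)
  cfg <- mcmc_config(n_chains = 2, n_iter = 400, burn_in = 200, thin = 2,
                     seed = 9)
  f1 <- run_mcmc(od, cfg)
  f2 <- run_mcmc(od, cfg)
  expect_identical(f1$draws, f2$draws)

  # a species detected at every survey of every site: psi posterior is
  # Beta(1 + I, 1), so the 2.5% quantile must respect that lower bound
  I <- 12
  yall <- array(1L, c(I, 4, 1), dimnames = list(paste0("s", 1:I), 1:4, "spA"))
  dall <- occupancy_data(yall, canopy = rep(0.5, I),
                         period = rep("before_sunrise", 4),
                         periods = "before_sunrise")
  fit <- run_mcmc(dall, mcmc_config(n_chains = 2, n_iter = 3000,
                                    burn_in = 1000, thin = 1, seed = 10,
                                    use_canopy = FALSE, use_period = FALSE,
                                    fix_hypers = TRUE))
  q <- quantile(do.call(rbind, fit$draws)[, "psi[spA]"], 0.025)
  expect_gt(unname(q), qbeta(0.025, 1 + I, 1) - 0.02)
})

test_that("posterior summary flags associations by CrI-excludes-zero", {
  sim <- simulate_community(study_design(n_sites_per_stratum = 2,
                                         n_mornings = 2), seed = 65)
  od <- as_occupancy_data(sim)
  fit <- run_mcmc(od, mcmc_config(n_chains = 2, n_iter = 300, burn_in = 100,
                                  thin = 1, seed = 11))
  # doctor the draws to known patterns and check the flag logic
  for (ch in seq_along(fit$draws)) {
    fit$draws[[ch]][, "beta_canopy[myna]"] <-
      abs(fit$draws[[ch]][, "beta_canopy[myna]"]) + 0.1
    fit$draws[[ch]][, "beta_canopy[bulbul]"] <-
      seq(-1, 1, length.out = nrow(fit$draws[[ch]]))
  }
  s <- summarize_posterior(fit)
  sp <- s$species
  expect_true(sp$canopy_association[sp$species == "myna"])
  expect_false(sp$canopy_association[sp$species == "bulbul"])
  expect_equal(sp$naive_occupancy, unname(naive_occupancy(od)))
  # monotone link: detection by period respects the sign of the contrasts
  expect_equal(dim(s$detection_by_period), c(9L, 3L))

  # posterior summary keys cover every generating-truth key
  expect_true(all(names(sim$truth) %in% s$parameters$parameter))
})

test_that("malformed model inputs are rejected", {
  y <- array(0L, c(2, 2, 1))
  expect_error(occupancy_data(y, canopy = c(0, 1), period = c("x", "y")),
               "unknown period")
  expect_error(occupancy_data(y, canopy = 1, period = rep("sunrise", 2)),
               "one value per site")
  expect_error(mcmc_config(burn_in = 10, n_iter = 10), "burn_in")
  expect_error(mcmc_config(thin = 0), "thin")
})
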