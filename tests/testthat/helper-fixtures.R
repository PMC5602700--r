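# Shared fixture builders; everything is generated in code at test time.

# minimal three-species profile table with simple per-element emission
make_profiles3 <- function(psi = c(0.3, 0.6, 0.9), alpha = c(0, 0, 0),
                           beta_canopy = c(0, -1.5, 0)) {
  data.frame(name = c("spA", "spB", "spC"), native = FALSE,
             psi = psi, alpha = alpha, beta_canopy = beta_canopy,
             beta_sunrise = 0, beta_after = 0,
             rate_agriculture = 2, rate_mixed = 2, rate_forest = 2,
             stringsAsFactors = FALSE)
}

# one-species profile with everything flat, handy for saturation tests
make_profile1 <- function(psi = 1, alpha = 0) {
  data.frame(name = "spA", native = FALSE, psi = psi, alpha = alpha,
             beta_canopy = 0, beta_sunrise = 0, beta_after = 0,
             rate_agriculture = 2, rate_mixed = 2, rate_forest = 2,
             stringsAsFactors = FALSE)
}

# small call-count table over three strata from explicit vectors
counts_from_vectors <- function(ag, mx, fo, species = "sp") {
  n <- c(length(ag), length(mx), length(fo))
  data.frame(
    survey_id = paste0("sv", seq_len(sum(n))),
    site = rep(c("ag01", "mi01", "fo01"), n),
    stratum = rep(c("agriculture", "mixed", "forest"), n),
    morning = 1L, period = "sunrise", species = species,
    call_count = c(ag, mx, fo), stringsAsFactors = FALSE)
}

# detection matrix object from a plain binary matrix
dm_from_matrix <- function(x, site = rep("s1", nrow(x))) {
  ids <- paste0("sv", seq_len(nrow(x)))
  rownames(x) <- ids
  structure(list(x = x,
                 info = data.frame(survey_id = ids, site = site,
                                   stratum = "mixed", morning = 1L,
                                   period = "sunrise",
                                   stringsAsFactors = FALSE),
                 species = colnames(x)),
            class = "detection_matrix")
}

# tiny random occupancy_data instance (a few cells) plus its parameters
random_occ_instance <- function(max_sites = 4, max_species = 2, J = 2) {
  repeat {
    I <- sample.int(max_sites, 1)
    S <- sample.int(max_species, 1)
    if (I * S <= 8) break
  }
  psi <- stats::runif(S, 0.1, 0.9)
  alpha <- stats::rnorm(S, 0, 1)
  bC <- stats::rnorm(S, 0, 0.5)
  b2 <- stats::rnorm(S, 0, 0.5)
  canopy <- stats::runif(I)
  period <- rep(c("before_sunrise", "sunrise"), length.out = J)
  p <- array(0, c(I, J, S))
  y <- array(0L, c(I, J, S),
             dimnames = list(paste0("s", 1:I), 1:J, paste0("sp", 1:S)))
  cc <- canopy - mean(canopy)
  pidx <- match(period, c("before_sunrise", "sunrise", "after_sunrise"))
  for (s in 1:S) {
    z <- stats::rbinom(I, 1, psi[s])
    for (j in 1:J) {
      eta <- alpha[s] + bC[s] * cc + (if (pidx[j] == 2) b2[s] else 0)
      p[, j, s] <- stats::plogis(eta)
      y[, j, s] <- stats::rbinom(I, 1, p[, j, s]) * z
    }
  }
  data <- occupancy_data(y, canopy, period)
  params <- list(psi = psi, alpha = alpha, beta_canopy = bC,
                 beta_period = cbind(b2, rep(0, S)))
  list(data = data, params = params, p = p, y = y)
}
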