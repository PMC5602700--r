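# Independent reference implementations used to check package results.
# These are deliberately naive (explicit loops, full enumeration, dense
# grids) and share no code with the package internals.

# gap-rule call counting by explicit run construction over sorted gaps
oracle_gap_count <- function(times, threshold, boundary = "ge") {
  t <- sort(times)
  if (length(t) == 0L) return(0L)
  runs <- 1L
  for (i in seq_along(t)[-1]) {
    gap <- t[i] - t[i - 1]
    split <- if (boundary == "ge") gap >= threshold else gap > threshold
    if (split) runs <- runs + 1L
  }
  runs
}

# one-way ANOVA by direct grand-mean / group-mean sum-of-squares summation
oracle_anova <- function(values, groups) {
  groups <- as.character(groups)
  gm <- mean(values)
  ss_total <- sum((values - gm)^2)
  ss_between <- 0
  ss_within <- 0
  for (g in unique(groups)) {
    v <- values[groups == g]
    ss_between <- ss_between + length(v) * (mean(v) - gm)^2
    ss_within <- ss_within + sum((v - mean(v))^2)
  }
  df_f <- length(unique(groups)) - 1L
  df_e <- length(values) - length(unique(groups))
  Fv <- (ss_between / df_f) / (ss_within / df_e)
  list(ss_total = ss_total, ss_between = ss_between, ss_within = ss_within,
       df_factor = df_f, df_error = df_e, F = Fv,
       p = stats::pf(Fv, df_f, df_e, lower.tail = FALSE))
}

# marginal occupancy likelihood by exhaustive enumeration of every latent
# configuration z in {0,1}^(sites x species)
oracle_enum_loglik <- function(y, psi, p) {
  I <- dim(y)[1]; J <- dim(y)[2]; S <- dim(y)[3]
  ncell <- I * S
  total <- 0
  for (code in 0:(2^ncell - 1)) {
    zbits <- as.integer(intToBits(code))[seq_len(ncell)]
    z <- matrix(zbits, I, S)
    prob <- 1
    for (s in seq_len(S)) for (i in seq_len(I)) {
      if (z[i, s] == 1L) {
        cell <- psi[s]
        for (j in seq_len(J))
          cell <- cell * (if (y[i, j, s] == 1L) p[i, j, s] else 1 - p[i, j, s])
      } else {
        cell <- if (all(y[i, , s] == 0L)) 1 - psi[s] else 0
      }
      prob <- prob * cell
      if (prob == 0) break
    }
    total <- total + prob
  }
  log(total)
}

# dense-grid posterior for the single-species, intercept-only occupancy
# model: psi ~ Uniform(0,1), alpha ~ Normal(0, alpha_sd) on the logit scale
oracle_grid_posterior <- function(y, alpha_sd = 10,
                                  psi_grid = seq(0.0025, 0.9975,
                                                 length.out = 200),
                                  alpha_grid = seq(-12, 12,
                                                   length.out = 401)) {
  k <- rowSums(y); J <- ncol(y); none <- k == 0
  post <- matrix(0, length(psi_grid), length(alpha_grid))
  for (b in seq_along(alpha_grid)) {
    p <- stats::plogis(alpha_grid[b])
    site_l <- p^k * (1 - p)^(J - k)
    for (a in seq_along(psi_grid)) {
      psi <- psi_grid[a]
      post[a, b] <- prod(psi * site_l + (1 - psi) * none) *
        stats::dnorm(alpha_grid[b], 0, alpha_sd)
    }
  }
  post <- post / sum(post)
  wpsi <- rowSums(post); walpha <- colSums(post)
  m_psi <- sum(psi_grid * wpsi)
  m_alpha <- sum(alpha_grid * walpha)
  list(mean_psi = m_psi,
       sd_psi = sqrt(sum((psi_grid - m_psi)^2 * wpsi)),
       mean_alpha = m_alpha,
       sd_alpha = sqrt(sum((alpha_grid - m_alpha)^2 * walpha)))
}

# naive UPGMA agglomeration: cluster distance recomputed at every merge as
# the plain average over all original pairwise distances
oracle_upgma_heights <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      d <- mean(D[clusters[[a]], clusters[[b]]])
      if (d < bestd) { bestd <- d; best <- c(a, b) }
    }
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# random small element stream for one gap-ruled species
random_gap_stream <- function(n_max = 12, t_max = 30) {
  n <- sample.int(n_max, 1)
  data.frame(element_type = "klew",
             time_s = round(stats::runif(n, 0, t_max), 3))
}
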