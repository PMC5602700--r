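test_that("mean/SE table does direct arithmetic and flags degenerate cells", {
  cts <- counts_from_vectors(c(2, 4, 6), c(1, 1), 5)
  tab <- mean_se_table(cts)
  ag <- tab[tab$stratum == "agriculture", ]
  expect_equal(ag$mean, 4)
  expect_equal(ag$se, 2 / sqrt(3))
  fo <- tab[tab$stratum == "forest", ]
  expect_true(is.na(fo$se))
  expect_equal(fo$flag, "single_observation")
})

test_that("stratum means of Poisson counts concentrate at the rate", {
  set.seed(41)
  cts <- counts_from_vectors(rpois(36, 40), rpois(36, 40), rpois(36, 40))
  tab <- mean_se_table(cts)
  expect_true(all(abs(tab$mean - 40) < 3 * sqrt(40 / 36)))
})

test_that("one-way ANOVA reproduces the published df convention", {
  set.seed(42)
  cts <- counts_from_vectors(rpois(35, 5), rpois(35, 5), rpois(34, 5))
  a <- anova_by_habitat(cts, "sp")
  expect_equal(a$df_factor, 2L)
  expect_equal(a$df_error, 101L)
  expect_equal(a$df_total, 103L)
  expect_true(a$p_overall >= 0 && a$p_overall <= 1)
})

test_that("ANOVA F agrees with the direct sum-of-squares oracle", {
  cts <- counts_from_vectors(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))
  a <- anova_by_habitat(cts, "sp")
  o <- oracle_anova(cts$call_count, cts$stratum)
  expect_equal(a$F, o$F, tolerance = 1e-12)
  expect_equal(a$p_overall, o$p, tolerance = 1e-12)
  # sum-of-squares conservation on random data
  set.seed(43)
  v <- rnorm(60); g <- sample(letters[1:3], 60, TRUE)
  oo <- oracle_anova(v, g)
  expect_equal(oo$ss_total, oo$ss_between + oo$ss_within, tolerance = 1e-9)
  cts2 <- counts_from_vectors(v[g == "a"], v[g == "b"], v[g == "c"])
  cts2$call_count <- round(abs(cts2$call_count) * 10)
  a2 <- anova_by_habitat(cts2, "sp")
  o2 <- oracle_anova(cts2$call_count, cts2$stratum)
  expect_equal(a2$F, o2$F, tolerance = 1e-10)
})

test_that("degenerate variance patterns are flagged, not mangled", {
  same <- counts_from_vectors(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  a <- anova_by_habitat(same, "sp")
  expect_equal(a$F, 0)
  expect_equal(a$p_overall, 1)

  flat <- counts_from_vectors(c(1, 1), c(2, 2), c(3, 3))
  af <- suppressWarnings(anova_by_habitat(flat, "sp"))  # perfect-fit warning
  expect_true(is.infinite(af$F))
  expect_equal(af$p_overall, 0)
  expect_equal(af$flag, "zero_within_variance")

  const <- counts_from_vectors(c(5, 5), c(5, 5), c(5, 5))
  ac <- suppressWarnings(anova_by_habitat(const, "sp"))
  expect_equal(ac$F, 0)
  expect_equal(ac$flag, "zero_variance")

  one <- counts_from_vectors(c(1, 2), c(3, 4), 5)
  expect_error(anova_by_habitat(one, "sp"), "fewer than 2")
})

test_that("nested ANOVA tests stratum against site-within-stratum", {
  set.seed(44)
  d <- expand.grid(site = paste0("s", 1:6), rep = 1:4)
  d$stratum <- rep(c("agriculture", "mixed", "forest"), each = 2)[
    match(d$site, paste0("s", 1:6))]
  d$survey_id <- paste0("sv", seq_len(nrow(d)))
  d$morning <- 1L; d$period <- "sunrise"; d$species <- "sp"
  d$call_count <- rpois(nrow(d), 8) + rep(rpois(6, 3), 4)
  a <- anova_by_habitat(d, "sp", nested = TRUE)
  expect_equal(a$df_factor, 2L)
  expect_equal(a$df_error, 3L)          # 6 sites - 3 strata
  at <- anova(lm(call_count ~ factor(stratum) + factor(site), data = d))
  expect_equal(a$F, at$`Mean Sq`[1] / at$`Mean Sq`[2], tolerance = 1e-12)
})

test_that("pairwise habitat p-values behave and match direct formulas", {
  same <- counts_from_vectors(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  pw <- pairwise_habitats(same, "sp")
  expect_true(all(pw > 0.999))
  expect_setequal(names(pw), c("agriculture-forest", "agriculture-mixed",
                               "forest-mixed"))

  # two far-apart groups with one in between: extreme pair has smallest p
  cts <- counts_from_vectors(c(1, 2, 1, 2), c(10, 11, 10, 11),
                             c(25, 24, 25, 26))
  pw2 <- pairwise_habitats(cts, "sp")
  expect_equal(names(which.min(pw2)), "agriculture-forest")

  # Tukey p equals the studentized-range formula computed directly
  set.seed(45)
  cts3 <- counts_from_vectors(rpois(8, 6), rpois(8, 9), rpois(8, 7))
  pw3 <- pairwise_habitats(cts3, "sp")
  o <- oracle_anova(cts3$call_count, cts3$stratum)
  mse <- o$ss_within / o$df_error
  m <- tapply(cts3$call_count, cts3$stratum, mean)
  q_af <- unname(abs(m["agriculture"] - m["forest"]) / sqrt(mse / 8))
  expect_equal(unname(pw3["agriculture-forest"]),
               ptukey(q_af, 3, o$df_error, lower.tail = FALSE),
               tolerance = 1e-6)
  # Bonferroni route equals a hand-computed pooled-SD t test
  pb <- pairwise_habitats(cts3, "sp", method = "bonferroni")
  tstat <- unname((m["agriculture"] - m["forest"]) /
                    sqrt(mse * (1 / 8 + 1 / 8)))
  expect_equal(unname(pb["agriculture-forest"]),
               min(1, 3 * 2 * pt(-abs(tstat), o$df_error)),
               tolerance = 1e-6)
})

test_that("overall p is invariant to count shifts and stratum relabeling", {
  set.seed(46)
  cts <- counts_from_vectors(rpois(10, 4), rpois(10, 6), rpois(10, 5))
  p0 <- anova_by_habitat(cts, "sp")$p_overall
  shifted <- cts; shifted$call_count <- shifted$call_count + 7
  expect_equal(anova_by_habitat(shifted, "sp")$p_overall, p0,
               tolerance = 1e-12)
  relab <- cts
  relab$stratum <- c(agriculture = "zzz", mixed = "aaa",
                     forest = "mmm")[relab$stratum]
  expect_equal(anova_by_habitat(relab, "sp")$p_overall, p0,
               tolerance = 1e-12)
})

test_that("the habitat table has one row per species with all columns", {
  set.seed(47)
  cts <- rbind(counts_from_vectors(rpois(6, 4), rpois(6, 6), rpois(6, 5),
                                   species = "spA"),
               counts_from_vectors(rpois(6, 9), rpois(6, 2), rpois(6, 5),
                                   species = "spB"))
  tab <- habitat_table(cts)
  expect_equal(nrow(tab), 2L)
  expect_true(all(c("mean_agriculture", "se_forest", "F", "p_overall",
                    "p_agriculture-forest", "p_forest-mixed") %in%
                  names(tab)))
})
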