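test_that("survey frame matches the stratified design arithmetic", {
  fr <- generate_design(study_design(), seed = 1)
  expect_equal(nrow(fr$sites), 15L)
  expect_equal(nrow(unique(fr$surveys[, c("site", "morning")])), 45L)
  expect_equal(nrow(fr$surveys) * fr$design$survey_length / 60, 675)
  # every site-morning runs the period sequence once, in order
  one <- fr$surveys[fr$surveys$site == fr$sites$site[1] &
                    fr$surveys$morning == 1, ]
  expect_equal(one$period[order(one$occasion)],
               c("before_sunrise", "sunrise", "after_sunrise"))
  # canopy classes are drawn from the stratum-specific distributions
  expect_true(all(fr$sites$canopy[fr$sites$stratum == "forest"] >= 0.5))

  tiny <- generate_design(study_design(n_sites_per_stratum = 1,
                                       n_mornings = 1,
                                       surveys_per_morning = 1,
                                       periods = "before_sunrise"), seed = 2)
  expect_equal(nrow(tiny$surveys), 3L)   # one survey at each of three sites
})

test_that("design generation is deterministic and rejects bad dimensions", {
  expect_identical(generate_design(study_design(), seed = 9),
                   generate_design(study_design(), seed = 9))
  expect_error(study_design(n_mornings = 0), "n_mornings")
  expect_error(study_design(n_sites_per_stratum = -1), "n_sites_per_stratum")
  expect_error(study_design(surveys_per_morning = 2), "period")
})

test_that("latent occupancy respects psi marginally and at the extremes", {
  fr <- generate_design(study_design(n_sites_per_stratum = 167), seed = 3)
  prof1 <- make_profile1(psi = 1)
  expect_true(all(simulate_occupancy(fr, prof1, seed = 1) == 1L))
  prof0 <- make_profile1(psi = 0)
  expect_true(all(simulate_occupancy(fr, prof0, seed = 1) == 0L))

  prof <- make_profile1(psi = 0.6)
  z <- simulate_occupancy(fr, prof, seed = 4)
  se <- sqrt(0.6 * 0.4 / nrow(fr$sites))
  expect_lt(abs(mean(z) - 0.6), 3 * se)

  bad <- make_profile1(); bad$psi <- 1.2
  expect_error(simulate_occupancy(fr, bad, seed = 1), "psi")
})

test_that("detection saturates, vanishes, and converges to the logit rate", {
  fr <- generate_design(study_design(n_sites_per_stratum = 371), seed = 5)
  I <- nrow(fr$sites)
  z1 <- matrix(1L, I, 1, dimnames = list(fr$sites$site, "spA"))

  sat <- simulate_detections(z1, fr, make_profile1(alpha = 20), seed = 1,
                             coupling = 0)
  expect_true(all(sat$y == 1L))

  z0 <- matrix(0L, I, 1, dimnames = list(fr$sites$site, "spA"))
  none <- simulate_detections(z0, fr, make_profile1(alpha = 0), seed = 1,
                              coupling = 0)
  expect_true(all(none$y == 0L))

  mid <- simulate_detections(z1, fr, make_profile1(alpha = 0), seed = 6,
                             coupling = 0)
  n <- length(mid$y)
  expect_gt(n, 10000)
  expect_lt(abs(mean(mid$y) - 0.5), 3 * sqrt(0.25 / n))

  expect_error(simulate_detections(z1[1:5, , drop = FALSE], fr,
                                   make_profile1(), seed = 1),
               "matrix matching")
})

test_that("call streams are consistent with detections and seeds", {
  prof <- species_profiles()
  sim <- simulate_community(seed = 11)
  # a species undetected in a survey contributes no elements there
  det_keys <- with(sim$counts[sim$counts$call_count > 0, ],
                   paste(survey_id, species))
  stream_keys <- unique(with(sim$streams, paste(survey_id, species)))
  expect_setequal(stream_keys, det_keys)
  # counts >= 1 exactly where detected
  i_idx <- match(sim$counts$site, sim$frame$sites$site)
  occ <- sim$frame$surveys$occasion[match(sim$counts$survey_id,
                                          sim$frame$surveys$survey_id)]
  yv <- sim$detections$y[cbind(i_idx, occ, match(sim$counts$species,
                                                 prof$name))]
  expect_identical(sim$counts$call_count >= 1L, yv == 1L)
  # bit-reproducible
  sim2 <- simulate_community(seed = 11)
  expect_identical(sim$streams, sim2$streams)
  expect_identical(sim$counts, sim2$counts)
})

test_that("zero coupling gives uncorrelated guild call totals", {
  prof <- species_profiles()
  des <- study_design(n_sites_per_stratum = 38)  # 114 sites x 9 > 1000 surveys
  set.seed(21)
  ss <- sample.int(.Machine$integer.max, 3)
  fr <- generate_design(des, seed = ss[1])
  z <- matrix(1L, nrow(fr$sites), nrow(prof),
              dimnames = list(fr$sites$site, prof$name))
  dh <- simulate_detections(z, fr, prof, seed = ss[2], coupling = 0)
  cts <- simulate_call_counts(dh, prof, seed = ss[3], coupling = 0)
  nat <- tapply(cts$call_count[cts$species %in% prof$name[prof$native]],
                cts$survey_id[cts$species %in% prof$name[prof$native]], sum)
  non <- tapply(cts$call_count[!cts$species %in% prof$name[prof$native]],
                cts$survey_id[!cts$species %in% prof$name[prof$native]], sum)
  r <- cor(as.numeric(nat), as.numeric(non[names(nat)]))
  expect_lt(abs(r), 3 / sqrt(length(nat)))
})

test_that("full coupling yields negative cross-guild call correlation", {
  prof <- species_profiles()
  neg <- logical(20)
  for (k in 1:20) {
    set.seed(k)
    ss <- sample.int(.Machine$integer.max, 3)
    fr <- generate_design(study_design(), seed = ss[1])
    z <- matrix(1L, nrow(fr$sites), nrow(prof),
                dimnames = list(fr$sites$site, prof$name))
    dh <- simulate_detections(z, fr, prof, seed = ss[2], coupling = 1)
    cts <- simulate_call_counts(dh, prof, seed = ss[3])
    isnat <- cts$species %in% prof$name[prof$native]
    nat <- tapply(cts$call_count[isnat], cts$survey_id[isnat], sum)
    non <- tapply(cts$call_count[!isnat], cts$survey_id[!isnat], sum)
    neg[k] <- cor(as.numeric(nat), as.numeric(non[names(nat)])) < 0
  }
  expect_gte(mean(neg), 0.95)
})

test_that("profile validation enforces the gap-model invariants", {
  prof <- make_profile1()
  attr(prof, "element_models") <- list(
    spA = list(kind = "gap", type = "spA_element", epc_lambda = 1,
               intra = c(0.5, 2.5), inter = c(3, 5), threshold = 2))
  expect_error(validate_profiles(prof), "strictly below")
  attr(prof, "element_models") <- list(
    spA = list(kind = "gap", type = "spA_element", epc_lambda = 1,
               intra = c(0.2, 0.5), inter = c(1, 5), threshold = 2))
  expect_error(validate_profiles(prof), "strictly above")
  expect_silent(validate_profiles(species_profiles()))
})

test_that("truth bundle round-trips and holds the generating values", {
  prof <- species_profiles()
  fr <- generate_design(study_design(), seed = 2)
  z <- simulate_occupancy(fr, prof, seed = 2)
  tb <- truth_bundle(prof, z)
  expect_equal(tb[["psi[kingfisher]"]],
               prof$psi[prof$name == "kingfisher"])
  expect_equal(tb[["zprop[myna]"]], mean(z[, "myna"]))
  f <- tempfile(fileext = ".json")
  write_truth_bundle(tb, f)
  back <- read_truth_bundle(f)
  expect_equal(unclass(back), unclass(tb))
})
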