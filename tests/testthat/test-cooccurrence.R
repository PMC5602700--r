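test_that("detection matrix binarizes counts and keeps annotations", {
  cts <- rbind(counts_from_vectors(c(17, 1, 0), c(0, 0), 2, species = "spA"),
               counts_from_vectors(c(0, 0, 0), c(3, 0), 0, species = "spB"))
  dm <- detection_matrix(cts)
  expect_equal(nrow(dm$x), length(unique(cts$survey_id)))
  expect_equal(unname(dm$x[1:3, "spA"]), c(1L, 1L, 0L))
  expect_equal(unname(dm$x[4, "spB"]), 1L)
  expect_true(all(dm$x %in% 0:1))

  zero <- counts_from_vectors(c(0, 0), c(0, 0), c(0, 0))
  expect_true(all(detection_matrix(zero)$x == 0L))
})

test_that("complete-site restriction drops sites missing any species", {
  x <- rbind(c(1, 1), c(1, 0),   # site A: both species seen
             c(1, 0), c(1, 0))   # site B: spB never seen
  colnames(x) <- c("spA", "spB")
  dm <- dm_from_matrix(x, site = c("A", "A", "B", "B"))
  res <- restrict_to_complete_sites(dm)
  expect_equal(attr(res, "complete_sites"), "A")
  expect_equal(nrow(res$x), 2L)

  all_ok <- dm_from_matrix(rbind(c(1, 1), c(1, 1)), site = c("A", "A"))
  expect_equal(restrict_to_complete_sites(all_ok)$x, all_ok$x)

  none <- dm_from_matrix(rbind(c(1, 0), c(1, 0)), site = c("A", "A"))
  expect_warning(out <- restrict_to_complete_sites(none), "no site")
  expect_equal(nrow(out$x), 0L)
})

test_that("default synthetic fixture retains at least one complete site", {
  sim <- simulate_community(seed = 3)
  dm <- restrict_to_complete_sites(detection_matrix(sim$counts))
  expect_gte(length(attr(dm, "complete_sites")), 1L)
})

test_that("clustering merges identical columns first, splits opposed blocks", {
  set.seed(51)
  a <- rbinom(40, 1, 0.5)
  x <- cbind(spA = a, spB = a, spC = 1L - a, spD = 1L - a)
  # perturb one entry so spA/spB stay identical but others vary
  dm <- dm_from_matrix(x)
  cl <- hierarchical_cluster(dm)
  expect_equal(cl$hclust$height[1], 0, tolerance = 1e-12)
  first <- sort(colnames(x)[-cl$hclust$merge[1, ]])
  expect_true(identical(first, c("spA", "spB")) ||
              identical(first, c("spC", "spD")))
  part <- cl$partition
  expect_equal(part[["spA"]], part[["spB"]])
  expect_equal(part[["spC"]], part[["spD"]])
  expect_false(part[["spA"]] == part[["spC"]])
  # merge heights never decrease
  expect_true(all(diff(cl$hclust$height) >= -1e-12))
})

test_that("average-linkage heights match a naive agglomeration oracle", {
  set.seed(52)
  x <- matrix(rbinom(5 * 60, 1, 0.5), 60, 5,
              dimnames = list(NULL, paste0("sp", 1:5)))
  dm <- dm_from_matrix(x)
  cl <- hierarchical_cluster(dm)
  D <- 1 - cor(x)
  expect_equal(cl$hclust$height, oracle_upgma_heights(as.dist(D)),
               tolerance = 1e-10)
})

test_that("constant detection columns are rejected towards Jaccard", {
  x <- cbind(spA = rep(1L, 10), spB = rbinom(10, 1, 0.5))
  dm <- dm_from_matrix(x)
  expect_error(hierarchical_cluster(dm), "jaccard")
  expect_s3_class(hierarchical_cluster(dm, distance = "jaccard")$hclust,
                  "hclust")
})

test_that("correlation distance is invariant to joint bit flips", {
  set.seed(53)
  x <- matrix(rbinom(3 * 50, 1, 0.4), 50, 3,
              dimnames = list(NULL, paste0("sp", 1:3)))
  d1 <- as.dist(1 - cor(x))
  d2 <- as.dist(1 - cor(1L - x))
  expect_equal(as.numeric(d1), as.numeric(d2), tolerance = 1e-12)
})

test_that("IRLS logistic regression matches glm and its identities", {
  set.seed(54)
  n <- 300
  x <- rpois(n, 2)
  y <- rbinom(n, 1, plogis(-0.5 + 0.4 * x))
  fit <- logistic_irls(cbind(1, x), y)
  ref <- glm(y ~ x, family = binomial())
  expect_true(fit$converged)
  expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se),
               unname(summary(ref)$coefficients[, "Std. Error"]),
               tolerance = 1e-5)
  # log-likelihood never decreases across iterations
  expect_true(all(diff(fit$loglik) >= -1e-10))
  # score identity: average fitted probability equals detection frequency
  expect_equal(mean(fit$fitted), mean(y), tolerance = 1e-8)
})

test_that("a null predictor gives a slope within noise of zero", {
  set.seed(55)
  n <- 2000
  x <- rbinom(n, 7, 0.4)
  y <- rbinom(n, 1, 0.3)                 # independent of x
  dm <- dm_from_matrix(cbind(target = y, sapply(1:7, function(i)
    as.integer(x >= i))))
  colnames(dm$x) <- c("target", paste0("nn", 1:7))
  dm$species <- colnames(dm$x)
  fit <- logistic_native_vs_nonnative(dm, "target", paste0("nn", 1:7))
  expect_true(fit$converged)
  expect_lt(abs(fit$slope), 3 * fit$se)
})

test_that("the 2x2 logistic slope equals the log odds ratio", {
  x <- c(rep(0, 15), rep(1, 15))
  y <- c(rep(1, 10), rep(0, 5), rep(1, 5), rep(0, 10))
  fit <- logistic_irls(cbind(1, x), y)
  expect_equal(unname(fit$coef[2]), log((5 * 5) / (10 * 10)),
               tolerance = 1e-8)
})

test_that("perfect separation is flagged instead of reported", {
  x <- c(0, 0, 0, 1, 1, 1)
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- logistic_irls(cbind(1, x), y)
  expect_false(fit$converged)
  expect_true(is.na(fit$p[2]))
})

test_that("guild interfaces reject malformed species sets", {
  dm <- dm_from_matrix(cbind(spA = c(1L, 0L), spB = c(0L, 1L)))
  expect_error(logistic_native_vs_nonnative(dm, "spA", c("spA", "spB")),
               "must not be in")
  expect_error(logistic_native_vs_nonnative(dm, "spZ", "spB"),
               "not in detection matrix")
})
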