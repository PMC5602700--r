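#' Survey x species detection matrix
#'
#' Binarizes a call-count table: entry 1 iff the species had at least one
#' unique call in that 5-minute survey.  Row annotations (site, morning,
#' period) are carried alongside; column (species) order follows first
#' appearance in the counts table and is recorded.
#'
#' @param counts Call-count table.
#' @return Object of class `detection_matrix`: list with `x` (binary
#'   matrix, rownames = survey ids), `info` (per-row annotations), `species`.
#' @export
detection_matrix <- function(counts) {
  species <- unique(counts$species)
  ids <- unique(counts$survey_id)
  x <- matrix(0L, length(ids), length(species),
              dimnames = list(ids, species))
  x[cbind(match(counts$survey_id, ids), match(counts$species, species))] <-
    as.integer(counts$call_count >= 1)
  info <- unique(counts[, c("survey_id", "site", "stratum", "morning",
                            "period")])
  info <- info[match(ids, info$survey_id), ]
  rownames(info) <- NULL
  structure(list(x = x, info = info, species = species),
            class = "detection_matrix")
}

#' Restrict to sites where every species was detected
#'
#' Keeps only surveys from "complete" sites — sites at which each species
#' was detected at least once across that site's surveys.  This is the
#' subset on which temporal co-detection patterns are interpretable as
#' behavior rather than absence.
#'
#' @param dm A [detection_matrix()].
#' @return A `detection_matrix` restricted to complete sites (with a
#'   `complete_sites` attribute); warns and returns an empty matrix if no
#'   site qualifies.
#' @export
restrict_to_complete_sites <- function(dm) {
  stopifnot(inherits(dm, "detection_matrix"))
  by_site <- split(seq_len(nrow(dm$x)), dm$info$site)
  complete <- names(by_site)[vapply(by_site, function(rows) {
    all(colSums(dm$x[rows, , drop = FALSE]) >= 1)
  }, logical(1))]
  if (length(complete) == 0L)
    warning("restrict_to_complete_sites: no site has all species detected")
  keep <- dm$info$site %in% complete
  out <- structure(list(x = dm$x[keep, , drop = FALSE],
                        info = dm$info[keep, , drop = FALSE],
                        species = dm$species),
                   class = "detection_matrix")
  attr(out, "complete_sites") <- complete
  out
}

#' Hierarchical clustering of species co-detection profiles
#'
#' Clusters species by the similarity of their detection columns across
#' surveys.  The default dissimilarity is `1 - Pearson correlation` of the
#' binary detection columns with average-linkage agglomeration; Jaccard
#' (binary) distance and other linkages are available.  A constant
#' detection column has no defined correlation and is rejected with a
#' pointer to the Jaccard option.
#'
#' @param dm A [detection_matrix()] (typically after
#'   [restrict_to_complete_sites()]).
#' @param distance `"correlation"` or `"jaccard"`.
#' @param linkage Agglomeration method for [stats::hclust()].
#' @param k Number of groups for the reported partition.
#' @return List of class `cooccurrence_clust`: `hclust` (the full linkage
#'   record: merge order and heights), `partition` (named group membership
#'   at `k`), `cophenetic` (cophenetic distances), `distance`, `linkage`.
#' @export
hierarchical_cluster <- function(dm, distance = c("correlation", "jaccard"),
                                 linkage = "average", k = 2) {
  stopifnot(inherits(dm, "detection_matrix"))
  distance <- match.arg(distance)
  x <- dm$x
  if (ncol(x) < 2L)
    stop("hierarchical_cluster: need at least two species columns",
         call. = FALSE)
  if (distance == "correlation") {
    const <- apply(x, 2, function(v) stats::var(v) == 0)
    if (any(const))
      stop("hierarchical_cluster: constant detection column(s) ",
           paste(colnames(x)[const], collapse = ", "),
           "; correlation distance is undefined - use distance = \"jaccard\"",
           call. = FALSE)
    d <- stats::as.dist(1 - stats::cor(x))
  } else {
    d <- stats::dist(t(x), method = "binary")
  }
  hc <- stats::hclust(d, method = linkage)
  structure(list(hclust = hc,
                 partition = stats::cutree(hc, k = k),
                 cophenetic = stats::cophenetic(hc),
                 distance = distance, linkage = linkage),
            class = "cooccurrence_clust")
}

#' @export
print.cooccurrence_clust <- function(x, ...) {
  cat("Co-detection clustering (", x$distance, " distance, ", x$linkage,
      " linkage)\n", sep = "")
  for (g in sort(unique(x$partition)))
    cat("  group ", g, ": ",
        paste(names(x$partition)[x$partition == g], collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Fits a binomial GLM with logit link by Fisher scoring (equivalently
#' Newton-Raphson on the log-likelihood, with step-halving so the
#' log-likelihood never decreases).  Perfect separation is flagged as
#' non-convergence: coefficients diverge and no Wald p-value is reported.
#'
#' @param X Design matrix (including the intercept column).
#' @param y Binary response vector.
#' @param max_iter Maximum Fisher-scoring iterations.
#' @param tol Convergence tolerance on the coefficient step.
#' @return List: `coef`, `se`, `z`, `p`, `converged`, `loglik` (per-iteration
#'   trace), `n_iter`, `fitted`.
#' @export
logistic_irls <- function(X, y, max_iter = 50L, tol = 1e-10) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  beta <- rep(0, ncol(X))
  ll <- function(b) sum(stats::dbinom(y, 1, stats::plogis(X %*% b), log = TRUE))
  trace <- ll(beta)
  converged <- FALSE
  XtWX <- NULL
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    XtWX <- crossprod(X, X * w)
    score <- crossprod(X, y - p)
    delta <- tryCatch(drop(solve(XtWX, score)), error = function(e) NULL)
    if (is.null(delta)) break
    step <- 1
    cur <- trace[length(trace)]
    repeat {                      # halve until the log-likelihood improves
      cand <- beta + step * delta
      if (ll(cand) >= cur - 1e-12 || step < 1e-8) break
      step <- step / 2
    }
    beta <- beta + step * delta
    trace <- c(trace, ll(beta))
    if (max(abs(step * delta)) < tol) { converged <- TRUE; break }
  }
  if (max(abs(beta)) > 30) converged <- FALSE   # separation: drifting to +-Inf
  se <- rep(NA_real_, length(beta))
  if (!is.null(XtWX))
    se <- tryCatch(sqrt(diag(solve(XtWX))), error = function(e) se)
  z <- if (converged) beta / se else rep(NA_real_, length(beta))
  list(coef = beta, se = se, z = z,
       p = if (converged) 2 * stats::pnorm(-abs(z)) else rep(NA_real_,
                                                             length(beta)),
       converged = converged, loglik = trace, n_iter = length(trace) - 1L,
       fitted = stats::plogis(drop(X %*% beta)))
}

#' Native detection versus concurrent non-native activity
#'
#' Tests temporal partitioning: regresses detection of a (native) target
#' species in a 5-minute survey on the number of non-native species detected
#' in the same survey (`predictor = "richness"`, 0-7) or on their total call
#' count (`predictor = "calls"`, requires `counts`).  A negative slope means
#' the target calls less when non-natives are active.
#'
#' @param dm A [detection_matrix()].
#' @param target_species Species whose detection is the response; must not
#'   be in `nonnative_set`.
#' @param nonnative_set Character vector of non-native species columns.
#' @param predictor `"richness"` or `"calls"`.
#' @param counts Call-count table, needed for `predictor = "calls"`.
#' @return List of class `logistic_fit`: `target`, `predictor`, `intercept`,
#'   `slope`, `se`, `z`, `p` (two-sided Wald p for the slope), `converged`,
#'   `fit` (full [logistic_irls()] output), `n`.
#' @export
logistic_native_vs_nonnative <- function(dm, target_species, nonnative_set,
                                         predictor = c("richness", "calls"),
                                         counts = NULL) {
  stopifnot(inherits(dm, "detection_matrix"))
  predictor <- match.arg(predictor)
  if (target_species %in% nonnative_set)
    stop("target species must not be in the non-native set", call. = FALSE)
  missing_sp <- setdiff(c(target_species, nonnative_set), colnames(dm$x))
  if (length(missing_sp))
    stop("species not in detection matrix: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  if (nrow(dm$x) < 1L) stop("empty detection matrix", call. = FALSE)

  yy <- dm$x[, target_species]
  if (predictor == "richness") {
    x <- rowSums(dm$x[, nonnative_set, drop = FALSE])
  } else {
    if (is.null(counts))
      stop("predictor = \"calls\" needs the call-count table", call. = FALSE)
    sub <- counts[counts$species %in% nonnative_set &
                  counts$survey_id %in% rownames(dm$x), ]
    tot <- tapply(sub$call_count, sub$survey_id, sum)
    x <- as.numeric(tot[rownames(dm$x)])
    x[is.na(x)] <- 0
  }
  fit <- logistic_irls(cbind(intercept = 1, nonnative = x), yy)
  structure(list(target = target_species, predictor = predictor,
                 intercept = fit$coef[1], slope = fit$coef[2],
                 se = fit$se[2], z = fit$z[2], p = fit$p[2],
                 converged = fit$converged, fit = fit, n = length(yy)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic regression: detection of '", x$target, "' ~ non-native ",
      x$predictor, " (n = ", x$n, ")\n", sep = "")
  if (x$converged)
    cat(sprintf("  slope = %.4g (SE %.4g), z = %.3g, p = %.4g\n",
                x$slope, x$se, x$z, x$p))
  else
    cat("  did not converge (possible separation); no p-value reported\n")
  invisible(x)
}
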