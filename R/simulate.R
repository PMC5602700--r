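#' Simulate latent occupancy states
#'
#' Draws the site x species latent occupancy matrix `z` with independent
#' Bernoulli(`psi_s`) entries.
#'
#' @param frame A [generate_design()] survey frame.
#' @param profiles A [species_profiles()] table.
#' @param seed Integer seed.
#' @return Integer matrix (sites x species) with dimnames, class `occupancy_truth`.
#' @export
simulate_occupancy <- function(frame, profiles = species_profiles(),
                               seed = 1L) {
  stopifnot(inherits(frame, "survey_frame"))
  validate_profiles(profiles, frame$design$strata)
  set.seed(as.integer(seed))
  I <- nrow(frame$sites)
  S <- nrow(profiles)
  z <- matrix(stats::rbinom(I * S, 1L, rep(profiles$psi, each = I)),
              nrow = I, ncol = S,
              dimnames = list(frame$sites$site, profiles$name))
  z
}

period_of_occasion <- function(design) {
  # period label for each within-site survey occasion, chronological order
  rep(design$periods, design$n_mornings)
}

guild_sign <- function(profiles) ifelse(profiles$native, -1, 1)

#' Simulate detection histories with guild-coupled survey activity
#'
#' For each species, site and survey occasion, detection is Bernoulli with
#' `logit(p) = alpha_s + beta_canopy_s * canopy_i + beta_period_s[period_j]
#' + coupling * g_s * u_{ij}`, multiplied by the latent occupancy `z`;
#' unoccupied sites yield all-zero histories.  `u_{ij}` is a shared
#' per-survey activity variable (normal on the logit scale, sd
#' `activity_sd`) and `g_s` is +1 for non-native and -1 for native species,
#' so a busy non-native survey is simultaneously a quiet native one.  The
#' same `u` later scales call rates, producing negative cross-guild
#' correlation in both detections and call counts.  Canopy enters centered
#' (site coverage fraction minus its mean across sites), matching the
#' parameterization of the occupancy model.
#'
#' @param z Latent occupancy matrix from [simulate_occupancy()].
#' @param frame The survey frame used to generate `z`.
#' @param profiles Species profiles.
#' @param seed Integer seed.
#' @param coupling Native/non-native coupling strength in `[0, 1]`; 0 turns
#'   the activity variable off.
#' @param activity_sd Standard deviation of the shared activity variable on
#'   the logit / log-rate scale.
#' @return An object of class `detection_history`: list with `y` (array
#'   sites x occasions x species), `frame`, `u` (activity matrix), `coupling`,
#'   `activity_sd`, `species`, `native`.
#' @export
simulate_detections <- function(z, frame, profiles = species_profiles(),
                                seed = 1L, coupling = 1, activity_sd = 2) {
  stopifnot(inherits(frame, "survey_frame"))
  validate_profiles(profiles, frame$design$strata)
  if (coupling < 0 || coupling > 1)
    stop("simulate_detections: 'coupling' must lie in [0, 1]", call. = FALSE)
  I <- nrow(frame$sites)
  S <- nrow(profiles)
  J <- frame$design$n_mornings * frame$design$surveys_per_morning
  if (!is.matrix(z) || nrow(z) != I || ncol(z) != S)
    stop("simulate_detections: z must be a ", I, " x ", S,
         " matrix matching the frame and profiles", call. = FALSE)

  set.seed(as.integer(seed))
  cc <- frame$sites$canopy - mean(frame$sites$canopy)
  per <- period_of_occasion(frame$design)
  pidx <- match(per, frame$design$periods)        # 1 = reference
  u <- matrix(stats::rnorm(I * J, 0, activity_sd), I, J)
  g <- guild_sign(profiles)

  y <- array(0L, dim = c(I, J, S),
             dimnames = list(frame$sites$site, seq_len(J), profiles$name))
  for (s in seq_len(S)) {
    bp <- c(0, profiles$beta_sunrise[s], profiles$beta_after[s])
    eta <- outer(profiles$alpha[s] + profiles$beta_canopy[s] * cc, bp[pidx],
                 "+") + coupling * g[s] * u
    p <- stats::plogis(eta)
    y[, , s] <- matrix(stats::rbinom(I * J, 1L, as.vector(p)), I, J) * z[, s]
  }
  structure(list(y = y, frame = frame, u = u, coupling = coupling,
                 activity_sd = activity_sd, species = profiles$name,
                 native = profiles$native),
            class = "detection_history")
}

# zero-truncated Poisson draw; rate 0 degenerates to the forced minimum of 1
rztpois <- function(n, lambda) {
  lambda <- rep_len(lambda, n)
  out <- integer(n)
  pos <- lambda > 0
  if (any(pos)) {
    p0 <- stats::dpois(0, lambda[pos])
    out[pos] <- stats::qpois(stats::runif(sum(pos), p0, 1), lambda[pos])
  }
  out[!pos] <- 1L
  as.integer(pmax(out, 1L))
}

#' Simulate unique-call counts conditional on detections
#'
#' Wherever a species was detected (`y = 1`) the number of unique calls in
#' that 5-minute survey is drawn from a zero-truncated Poisson whose mean is
#' the species' stratum-specific rate scaled by the shared survey activity
#' variable (`rate * exp(coupling * g_s * u_{ij})`), keeping counts
#' consistent with detections (a detected species has at least one call) and
#' anti-correlated across guilds.  Undetected species get count 0.
#'
#' @param dh A [simulate_detections()] object.
#' @param profiles Species profiles.
#' @param seed Integer seed.
#' @param coupling Coupling strength; defaults to the value used for `dh`.
#' @return A call-count table: data frame with `survey_id`, `site`,
#'   `stratum`, `morning`, `period`, `species`, `call_count`.
#' @export
simulate_call_counts <- function(dh, profiles = species_profiles(),
                                 seed = 1L, coupling = dh$coupling) {
  stopifnot(inherits(dh, "detection_history"))
  validate_profiles(profiles, dh$frame$design$strata)
  set.seed(as.integer(seed))
  sv <- dh$frame$surveys
  S <- nrow(profiles)
  g <- guild_sign(profiles)
  i_idx <- match(sv$site, dh$frame$sites$site)

  out <- vector("list", S)
  for (s in seq_len(S)) {
    rate0 <- unlist(profiles[s, paste0("rate_", sv$stratum)], use.names = FALSE)
    # mean-one lognormal activity multiplier: bursts and lulls, same average
    rate <- rate0 * exp(coupling * g[s] * dh$u[cbind(i_idx, sv$occasion)] -
                          0.5 * (coupling * dh$activity_sd)^2)
    yv <- dh$y[cbind(i_idx, sv$occasion, s)]
    n <- integer(nrow(sv))
    if (any(yv == 1L)) n[yv == 1L] <- rztpois(sum(yv == 1L), rate[yv == 1L])
    out[[s]] <- data.frame(survey_id = sv$survey_id, site = sv$site,
                           stratum = sv$stratum, morning = sv$morning,
                           period = sv$period, species = profiles$name[s],
                           call_count = n, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# lay one survey's worth of calls for one species onto [0, L];
# returns element times/types and the realized call count (gap-ruled species
# may not fit every intended call inside the survey window)
layout_elements <- function(n, model, L) {
  switch(model$kind,
    gap = {
      times <- numeric(0)
      realized <- 0L
      t <- stats::runif(1, 0, min(5, L / 2))
      for (k in seq_len(n)) {
        epc <- 1L + stats::rpois(1, model$epc_lambda)
        gaps <- if (epc > 1L) stats::runif(epc - 1L, model$intra[1], model$intra[2])
                else numeric(0)
        el <- t + c(0, cumsum(gaps))
        if (el[length(el)] > L) break
        times <- c(times, el)
        realized <- realized + 1L
        t <- el[length(el)] + stats::runif(1, model$inter[1], model$inter[2])
      }
      if (realized == 0L) {          # degenerate window: one bare element
        times <- stats::runif(1, 0, L)
        realized <- 1L
      }
      list(times = times, types = rep(model$type, length(times)), n = realized)
    },
    simple = list(times = sort(stats::runif(n, 0, L)),
                  types = rep(model$type, n), n = n),
    extra = {
      tq <- sort(stats::runif(n, 0, L))
      nx <- stats::rpois(1, n * model$extra_lambda)
      tx <- stats::runif(nx, 0, L)
      ord <- order(c(tq, tx))
      list(times = c(tq, tx)[ord],
           types = c(rep(model$type, n), rep(model$extra_type, nx))[ord],
           n = n)
    },
    train = {
      tm <- sort(stats::runif(n, 0, L))
      times <- tm
      types <- rep(model$marker, n)
      for (t0 in tm) {
        k <- stats::rpois(1, model$coo_lambda)
        if (k > 0) {
          tc <- t0 + cumsum(stats::runif(k, model$coo_gap[1], model$coo_gap[2]))
          tc <- tc[tc <= L]
          times <- c(times, tc)
          types <- c(types, rep(model$coo, length(tc)))
        }
      }
      ord <- order(times)
      list(times = times[ord], types = types[ord], n = n)
    },
    unit = {
      list(times = sort(stats::runif(n, 0, L)),
           types = sample(model$types, n, replace = TRUE, prob = model$probs),
           n = n)
    },
    stop("unknown element model kind: ", model$kind))
}

#' Simulate timestamped vocal element streams
#'
#' Draws per-survey unique-call counts (see [simulate_call_counts()]) and
#' renders each call as timestamped vocal elements under the species'
#' emission model, respecting its segmentation-gap invariants so that
#' [segment_calls()] recovers the generating call count exactly.  For
#' gap-ruled species a call that does not fit inside the survey window is
#' dropped and the realized count recorded, so the returned `counts` table
#' is always the segmentation-consistent truth.
#'
#' @inheritParams simulate_call_counts
#' @return An object of class `call_streams`: list with `streams` (data
#'   frame `survey_id`, `species`, `element_type`, `time_s`) and `counts`
#'   (realized call-count table).
#' @export
simulate_call_streams <- function(dh, profiles = species_profiles(),
                                  seed = 1L, coupling = dh$coupling) {
  counts <- simulate_call_counts(dh, profiles, seed = seed,
                                 coupling = coupling)
  validate_profiles(profiles, dh$frame$design$strata)
  L <- dh$frame$design$survey_length
  models <- lapply(profiles$name, element_model, profiles = profiles)
  names(models) <- profiles$name

  act <- which(counts$call_count > 0)
  parts <- vector("list", length(act))
  for (k in seq_along(act)) {
    r <- act[k]
    lay <- layout_elements(counts$call_count[r], models[[counts$species[r]]], L)
    counts$call_count[r] <- lay$n
    parts[[k]] <- data.frame(survey_id = counts$survey_id[r],
                             species = counts$species[r],
                             element_type = lay$types,
                             time_s = lay$times,
                             stringsAsFactors = FALSE)
  }
  streams <- if (length(parts)) do.call(rbind, parts) else
    data.frame(survey_id = character(), species = character(),
               element_type = character(), time_s = numeric(),
               stringsAsFactors = FALSE)
  rownames(streams) <- NULL
  structure(list(streams = streams, counts = counts), class = "call_streams")
}

#' Simulate a complete synthetic survey with known truth
#'
#' One-stop generator: realizes the survey frame, latent occupancy,
#' detection histories, call counts and vocal element streams, and packages
#' the generating parameters as a [truth_bundle()].  All stages are seeded
#' from a single integer.
#'
#' @param design A [study_design()].
#' @param profiles A [species_profiles()] table.
#' @param seed Integer master seed.
#' @param coupling Native/non-native activity coupling in `[0, 1]`.
#' @param activity_sd Survey-activity standard deviation.
#' @return List of class `community_sim` with elements `frame`, `z`,
#'   `detections`, `streams`, `counts`, `truth`, `profiles`, `seed`.
#' @export
simulate_community <- function(design = study_design(),
                               profiles = species_profiles(),
                               seed = 1L, coupling = 1, activity_sd = 2) {
  set.seed(as.integer(seed))
  ss <- sample.int(.Machine$integer.max, 4)
  frame <- generate_design(design, seed = ss[1])
  z <- simulate_occupancy(frame, profiles, seed = ss[2])
  dh <- simulate_detections(z, frame, profiles, seed = ss[3],
                            coupling = coupling, activity_sd = activity_sd)
  st <- simulate_call_streams(dh, profiles, seed = ss[4], coupling = coupling)
  structure(list(frame = frame, z = z, detections = dh,
                 streams = st$streams, counts = st$counts,
                 truth = truth_bundle(profiles, z),
                 profiles = profiles, seed = as.integer(seed)),
            class = "community_sim")
}

#' @export
print.community_sim <- function(x, ...) {
  cat("Synthetic acoustic survey: ", nrow(x$frame$sites), " sites, ",
      nrow(x$frame$surveys), " surveys, ", nrow(x$profiles),
      " species, ", nrow(x$streams), " vocal elements (seed ", x$seed,
      ")\n", sep = "")
  invisible(x)
}
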