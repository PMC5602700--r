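#' Species profiles: ground truth for the synthetic community
#'
#' One row per species, holding everything the generator needs: native
#' status, occupancy probability `psi`, detection coefficients on the logit
#' scale (`alpha` intercept, `beta_canopy` slope per unit canopy coverage
#' fraction, `beta_sunrise` / `beta_after` contrasts of the sunrise and
#' after-sunrise periods against before-sunrise), and expected unique calls
#' per 5-minute survey in each stratum (`rate_<stratum>` columns).
#'
#' The default roster holds the nine terrestrial passerines of a South
#' Pacific island valley community: two natives (an endemic kingfisher and a
#' fruit dove) and seven non-natives (red-vented bulbul, red jungle fowl,
#' zebra dove, common myna, silvereye, common waxbill, red-browed firetail).
#' Natives get
#' lower detection intercepts and no period pattern; zebra dove, myna and
#' waxbill get negative canopy slopes and an after-sunrise activity peak;
#' call rates follow the magnitudes of the published per-survey means.
#'
#' @return A data frame of class `species_profiles`.
#' @seealso [validate_profiles()], [simulate_occupancy()]
#' @export
species_profiles <- function() {
  p <- data.frame(
    name    = c("kingfisher", "fruit_dove", "bulbul", "jungle_fowl",
                "zebra_dove", "myna", "silvereye", "waxbill", "firetail"),
    native  = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    psi     = c(0.85, 0.70, 0.95, 0.90, 0.90, 0.85, 0.95, 0.85, 0.90),
    alpha   = c(-1.2, -1.4, 1.2, 0.8, 0.9, 0.2, 1.0, -0.3, -0.5),
    beta_canopy = c(0.0, 0.3, 0.0, 0.4, -1.5, -1.8, 0.0, -1.6, 0.3),
    beta_sunrise = c(0.0, 0.0, 0.2, 0.1, 0.5, 0.5, 0.4, 0.4, 0.3),
    beta_after   = c(0.0, 0.0, 0.3, 0.2, 1.0, 1.0, 0.8, 0.9, 0.7),
    rate_agriculture = c(0.6, 0.3, 200, 34, 45, 20, 270, 41, 2),
    rate_mixed       = c(0.5, 0.5, 100, 29, 21, 3, 175, 0.6, 5),
    rate_forest      = c(0.6, 0.45, 140, 52, 5, 1.1, 270, 0.3, 4.6),
    stringsAsFactors = FALSE)
  class(p) <- c("species_profiles", "data.frame")
  p
}

# Element-emission model per species: how a single unique call is rendered
# as timestamped vocal elements.  Kinds:
#   gap    - a burst of like elements; intra-call gaps stay strictly below the
#            species' segmentation threshold, inter-call gaps strictly above
#   simple - one qualifying element per call, placed freely
#   extra  - one qualifying element per call plus non-counting extras
#   train  - an opening marker element followed by a train of trailing
#            elements (only the marker is counted)
#   unit   - one unit element per call, type drawn from a small vocabulary
.species_elements <- list(
  kingfisher = list(kind = "gap", type = "klew", epc_lambda = 2,
                    intra = c(0.3, 1.4), inter = c(2.5, 6), threshold = 2),
  myna = list(kind = "gap", type = "myna_element", epc_lambda = 3,
              intra = c(0.1, 0.7), inter = c(1.3, 3), threshold = 1),
  silvereye = list(kind = "simple", type = "downsweep"),
  waxbill = list(kind = "simple", type = "dart"),
  firetail = list(kind = "simple", type = "upsweep_trill"),
  jungle_fowl = list(kind = "extra", type = "screech",
                     extra_type = "sweep", extra_lambda = 1),
  zebra_dove = list(kind = "train", marker = "large_coo", coo = "coo",
                    coo_lambda = 4, coo_gap = c(0.1, 0.35)),
  fruit_dove = list(kind = "train", marker = "large_coo", coo = "coo",
                    coo_lambda = 6, coo_gap = c(0.3, 0.8)),
  bulbul = list(kind = "unit",
                types = c("two_tone", "three_tone", "single_tone"),
                probs = c(0.45, 0.45, 0.10))
)

element_model <- function(species, profiles = NULL) {
  override <- attr(profiles, "element_models")
  m <- override[[species]] %||% .species_elements[[species]]
  if (is.null(m))
    m <- list(kind = "simple", type = paste0(species, "_element"))
  m
}

#' Element-type vocabulary per species
#'
#' @param species Character vector of species names.
#' @return Named list of allowed element-type labels.
#' @export
species_vocabulary <- function(species) {
  stats::setNames(lapply(species, function(sp) {
    m <- element_model(sp)
    switch(m$kind,
           gap = m$type,
           simple = m$type,
           extra = c(m$type, m$extra_type),
           train = c(m$marker, m$coo),
           unit = m$types)
  }), species)
}

#' Validate a species-profile table
#'
#' Checks the generator's invariants: `psi` in `[0, 1]`, nonnegative call
#' rates, finite detection coefficients, and — for species whose calls are
#' delimited by an inter-call gap rule — that the emission model's intra-call
#' gaps stay strictly below the segmentation threshold while inter-call gaps
#' stay strictly above it, so simulated streams segment back to the intended
#' call count.
#'
#' Custom emission models may be supplied as an `element_models` attribute
#' on the profile table (a named list in the internal model format); they
#' take precedence over the built-in models and are validated the same way.
#'
#' @param profiles A [species_profiles()]-shaped data frame.
#' @param strata Stratum labels whose `rate_<stratum>` columns must exist.
#' @return `profiles`, invisibly, if valid; otherwise an error.
#' @export
validate_profiles <- function(profiles,
                              strata = c("agriculture", "mixed", "forest")) {
  need <- c("name", "native", "psi", "alpha", "beta_canopy", "beta_sunrise",
            "beta_after", paste0("rate_", strata))
  miss <- setdiff(need, names(profiles))
  if (length(miss))
    stop("profiles: missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(profiles$name))
    stop("profiles: duplicated species names", call. = FALSE)
  if (any(profiles$psi < 0 | profiles$psi > 1))
    stop("profiles: psi must lie in [0, 1]", call. = FALSE)
  rates <- as.matrix(profiles[, paste0("rate_", strata), drop = FALSE])
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("profiles: call rates must be nonnegative and finite", call. = FALSE)
  coefs <- as.matrix(profiles[, c("alpha", "beta_canopy", "beta_sunrise",
                                  "beta_after")])
  if (any(!is.finite(coefs)))
    stop("profiles: detection coefficients must be finite", call. = FALSE)
  for (sp in profiles$name) {
    m <- element_model(sp, profiles)
    if (identical(m$kind, "gap")) {
      if (max(m$intra) >= m$threshold)
        stop("profiles: species '", sp, "': intra-call element gaps must be ",
             "strictly below the segmentation threshold (", m$threshold,
             " s)", call. = FALSE)
      if (min(m$inter) <= m$threshold)
        stop("profiles: species '", sp, "': inter-call gaps must be strictly ",
             "above the segmentation threshold (", m$threshold, " s)",
             call. = FALSE)
    }
  }
  invisible(profiles)
}

#' Ground-truth bundle for parameter-recovery tests
#'
#' Serializable record of every generating parameter, keyed exactly as the
#' occupancy model's posterior summary keys its parameters, so recovery
#' tests can join truth to estimate by name.
#'
#' @param profiles A [species_profiles()] table.
#' @param z Latent occupancy matrix (sites x species) from
#'   [simulate_occupancy()], or `NULL` to omit realized-occupancy entries.
#' @return A named list of numbers (class `truth_bundle`).
#' @export
truth_bundle <- function(profiles, z = NULL) {
  nm <- profiles$name
  key <- function(par) sprintf("%s[%s]", par, nm)
  out <- c(stats::setNames(as.list(profiles$psi), key("psi")),
           stats::setNames(as.list(profiles$alpha), key("alpha")),
           stats::setNames(as.list(profiles$beta_canopy), key("beta_canopy")),
           stats::setNames(as.list(profiles$beta_sunrise), key("beta_sunrise")),
           stats::setNames(as.list(profiles$beta_after),
                           key("beta_after_sunrise")))
  if (!is.null(z)) {
    if (!all(nm %in% colnames(z)))
      stop("truth_bundle: z columns must be named by species", call. = FALSE)
    out <- c(out, stats::setNames(as.list(colMeans(z[, nm, drop = FALSE])),
                                  key("zprop")))
  }
  structure(out, class = c("truth_bundle", "list"))
}

#' Write / read a truth bundle as JSON
#'
#' @param bundle A [truth_bundle()].
#' @param path File path.
#' @return `read_truth_bundle` returns the bundle; `write_truth_bundle`
#'   returns `path` invisibly.
#' @export
write_truth_bundle <- function(bundle, path) {
  jsonlite::write_json(unclass(bundle), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_bundle
#' @export
read_truth_bundle <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = FALSE),
            class = c("truth_bundle", "list"))
}
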