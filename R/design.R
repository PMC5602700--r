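#' Study design for a stratified acoustic point-count survey
#'
#' Describes the sampling frame of a morning acoustic survey: sites stratified
#' by land use, repeated short recordings on consecutive mornings, and an
#' ordinal canopy-cover classification at each site.  The default values give
#' the standard island-valley design: 5 sites in each of three land-use
#' strata, three
#' consecutive mornings, and three 5-minute recordings per morning timed
#' around local sunrise (30 min before, at, and 30 min after).
#'
#' @param n_sites_per_stratum Number of survey sites per land-use stratum.
#' @param strata Ordered land-use stratum labels.
#' @param n_mornings Number of consecutive survey mornings per site.
#' @param surveys_per_morning Number of recordings per morning; must equal
#'   `length(periods)` because each morning runs through the period sequence
#'   once, in order.
#' @param survey_length Length of one recording in seconds.
#' @param periods Ordered survey-period labels within a morning.
#' @param canopy_levels Named numeric vector mapping the five ordinal canopy
#'   classes to vegetation coverage fractions (open = 0 through covered = 1).
#' @param canopy_probs Optional named list (one entry per stratum) of
#'   probability vectors over the canopy classes.  When `NULL` and the strata
#'   are the standard agriculture/mixed/forest triple, forest is skewed
#'   towards covered canopy, agriculture towards open, and mixed is uniform;
#'   other strata default to uniform.
#'
#' @return An object of class `study_design`.
#' @seealso [generate_design()]
#' @export
#' @examples
#' d <- study_design()
#' d$n_sites_per_stratum * length(d$strata)   # 15 sites
study_design <- function(n_sites_per_stratum = 5,
                         strata = c("agriculture", "mixed", "forest"),
                         n_mornings = 3,
                         surveys_per_morning = 3,
                         survey_length = 300,
                         periods = c("before_sunrise", "sunrise", "after_sunrise"),
                         canopy_levels = c(open = 0, open_moderate = 0.25,
                                           moderate = 0.5, moderate_covered = 0.75,
                                           covered = 1),
                         canopy_probs = NULL) {
  for (fld in c("n_sites_per_stratum", "n_mornings", "surveys_per_morning",
                "survey_length")) {
    v <- get(fld)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("study_design: field '", fld, "' must be a positive number",
           call. = FALSE)
  }
  if (length(strata) < 1L) stop("study_design: 'strata' must be nonempty",
                                call. = FALSE)
  if (anyDuplicated(strata)) stop("study_design: duplicated stratum labels",
                                  call. = FALSE)
  if (surveys_per_morning != length(periods))
    stop("study_design: 'surveys_per_morning' must equal the number of ",
         "period labels (each morning runs the period sequence once)",
         call. = FALSE)
  if (is.null(names(canopy_levels)) || any(!is.finite(canopy_levels)))
    stop("study_design: 'canopy_levels' must be a named finite numeric vector",
         call. = FALSE)

  if (is.null(canopy_probs)) {
    k <- length(canopy_levels)
    unif <- rep(1 / k, k)
    canopy_probs <- stats::setNames(rep(list(unif), length(strata)), strata)
    if (k == 5L) {
      covered_skew <- c(0, 0, 0.1, 0.3, 0.6)
      if ("forest" %in% strata) canopy_probs[["forest"]] <- covered_skew
      if ("agriculture" %in% strata)
        canopy_probs[["agriculture"]] <- rev(covered_skew)
    }
  }
  if (!all(strata %in% names(canopy_probs)))
    stop("study_design: 'canopy_probs' must name every stratum", call. = FALSE)
  for (st in strata) {
    p <- canopy_probs[[st]]
    if (length(p) != length(canopy_levels) || any(p < 0) || sum(p) <= 0)
      stop("study_design: invalid canopy class probabilities for stratum '",
           st, "'", call. = FALSE)
    canopy_probs[[st]] <- p / sum(p)
  }

  structure(list(n_sites_per_stratum = as.integer(n_sites_per_stratum),
                 strata = as.character(strata),
                 n_mornings = as.integer(n_mornings),
                 surveys_per_morning = as.integer(surveys_per_morning),
                 survey_length = as.numeric(survey_length),
                 periods = as.character(periods),
                 canopy_levels = canopy_levels,
                 canopy_probs = canopy_probs),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  n_sites <- x$n_sites_per_stratum * length(x$strata)
  n_surv <- n_sites * x$n_mornings * x$surveys_per_morning
  cat("Acoustic survey design\n")
  cat("  sites:   ", n_sites, " (", x$n_sites_per_stratum, " per stratum: ",
      paste(x$strata, collapse = ", "), ")\n", sep = "")
  cat("  surveys: ", n_surv, " (", x$n_mornings, " mornings x ",
      x$surveys_per_morning, " x ", x$survey_length, " s)\n", sep = "")
  invisible(x)
}

#' Realize a survey frame: site table and survey schedule
#'
#' Draws one realization of the design: assigns each site a canopy-cover
#' class from its stratum-specific distribution and expands the full survey
#' schedule (site x morning x period).  Deterministic given `seed`.
#'
#' @param design A [study_design()].
#' @param seed Integer seed controlling the canopy class draws.
#'
#' @return An object of class `survey_frame`: a list with
#'   \describe{
#'     \item{sites}{data frame: `site`, `stratum`, `canopy_class`,
#'       `canopy` (coverage fraction in `[0, 1]`).}
#'     \item{surveys}{data frame: `survey_id`, `site`, `stratum`, `morning`,
#'       `period`, `occasion` (1-based survey occasion within a site, in
#'       chronological order).}
#'     \item{design}{the `study_design` used.}
#'   }
#' @export
#' @examples
#' fr <- generate_design(study_design(), seed = 1)
#' nrow(unique(fr$surveys[, c("site", "morning")]))   # 45 site-mornings
generate_design <- function(design = study_design(), seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  set.seed(as.integer(seed))

  strata <- design$strata
  nps <- design$n_sites_per_stratum
  classes <- names(design$canopy_levels)

  site_id <- function(st, k) sprintf("%s%02d", substr(st, 1, 2), k)
  sites <- do.call(rbind, lapply(strata, function(st) {
    cls <- sample(classes, nps, replace = TRUE, prob = design$canopy_probs[[st]])
    data.frame(site = site_id(st, seq_len(nps)),
               stratum = st,
               canopy_class = cls,
               canopy = unname(design$canopy_levels[cls]),
               stringsAsFactors = FALSE)
  }))
  rownames(sites) <- NULL

  grid <- expand.grid(period_idx = seq_along(design$periods),
                      morning = seq_len(design$n_mornings),
                      site = sites$site,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  surveys <- data.frame(
    site = grid$site,
    morning = grid$morning,
    period = design$periods[grid$period_idx],
    occasion = (grid$morning - 1L) * design$surveys_per_morning +
      grid$period_idx,
    stringsAsFactors = FALSE)
  surveys$stratum <- sites$stratum[match(surveys$site, sites$site)]
  surveys$survey_id <- sprintf("%s_d%d_%s", surveys$site, surveys$morning,
                               surveys$period)
  surveys <- surveys[order(surveys$site, surveys$occasion),
                     c("survey_id", "site", "stratum", "morning", "period",
                       "occasion")]
  rownames(surveys) <- NULL

  structure(list(sites = sites, surveys = surveys, design = design),
            class = "survey_frame")
}

#' @export
print.survey_frame <- function(x, ...) {
  cat("Survey frame: ", nrow(x$sites), " sites, ", nrow(x$surveys),
      " surveys (", sum(x$design$survey_length) * nrow(x$surveys) / 60,
      " recorded minutes)\n", sep = "")
  invisible(x)
}
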