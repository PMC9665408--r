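#' Sub-criterion levels for nutrient scoring
#'
#' The nutrition prioritization index combines two occurrence sub-criteria
#' (presence in the raw material, effect of processing) and three
#' public-health "severity" sub-criteria (dietary-policy relevance,
#' contribution of the food to nutrient intake, matrix effect on
#' bioavailability), each graded 1-3. These helpers compute one level
#' each; they are vectorized over components.
#'
#' \describe{
#'   \item{presence}{level 1 when the nutrient is absent or detected in
#'     fewer than 10% of analyzed samples, level 3 when present in all
#'     samples, level 2 otherwise.}
#'   \item{processing}{level from the effect of the manufacturing process
#'     on the concentration; by default a large reduction or loss scores 1,
#'     a moderate change 2, and a preserved or concentrated nutrient 3, so
#'     a higher level always means more of the nutrient reaches the
#'     consumer.}
#'   \item{policy}{level 1 when the nutrient appears in no food-based
#'     dietary guideline (FBDG) or fortification scheme of the countries
#'     under study, 3 when either instrument covers all countries, 2
#'     otherwise.}
#'   \item{intake}{layer 1 bins the average contribution of the food to
#'     population intake of the nutrient at configurable cut points
#'     (default tertiles); layer 2, used only when no contribution
#'     estimate exists, grades the composition difference between the two
#'     foods.}
#'   \item{bioavailability}{a stronger matrix-driven reduction of
#'     bioavailability lowers the public-health weight of the food as a
#'     source: significant reduction scores 1, moderate 2, mild or none 3.}
#' }
#'
#' @param sample_detection_fraction Fraction of analyzed samples in which
#'   the nutrient was reported, in [0, 1].
#' @param low_fraction Detection fraction below which presence scores 1.
#' @param effect A processing effect from
#'   \code{c("introduces_or_increases", "neutral", "reduces", "eliminates")}.
#' @param levels Named integer map from class to level.
#' @param fbdg_scope,fortification_scope One of \code{"none"},
#'   \code{"some_countries"}, \code{"all_countries"}.
#' @param contribution Layer-1 average contribution fraction of the food
#'   to population intake of the nutrient, or NA.
#' @param fallback_class Layer-2 composition-difference class
#'   (\code{"small_difference"}, \code{"moderate_difference"},
#'   \code{"large_difference"}), or NA.
#' @param cuts Two increasing cut points for the layer-1 bins.
#' @param fallback_levels Named integer map for layer-2 classes.
#' @param reduction Bioavailability-reduction class
#'   (\code{"significant"}, \code{"moderate"}, \code{"mild_or_none"}).
#' @return Integer vector of levels in \{1, 2, 3\}.
#' @examples
#' presence_level(c(0.05, 0.5, 1))     # 1 2 3
#' policy_level("all_countries", "none") # 3
#' intake_level(0.6, NA)               # 2 under the default tertile cuts
#' @name nutrition_levels
NULL

#' @rdname nutrition_levels
#' @export
presence_level <- function(sample_detection_fraction, low_fraction = 0.10) {
  f <- sample_detection_fraction
  if (any(is.na(f))) {
    stop("sample_detection_fraction is required (no qualitative flag given)",
         call. = FALSE)
  }
  if (any(f < 0 | f > 1)) {
    stop("sample_detection_fraction must lie in [0, 1]", call. = FALSE)
  }
  ifelse(f < low_fraction, 1L, ifelse(f >= 1, 3L, 2L))
}

#' @rdname nutrition_levels
#' @export
processing_level <- function(effect, levels = rba_config()$nutrition$processing_levels) {
  if (any(is.na(effect))) stop("processing effect is required", call. = FALSE)
  unknown <- setdiff(unique(effect), names(levels))
  if (length(unknown) > 0) {
    stop("unknown processing effect class: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  unname(levels[effect])
}

#' @rdname nutrition_levels
#' @export
policy_level <- function(fbdg_scope, fortification_scope) {
  check_scope <- function(x, what) {
    if (any(is.na(x)) || !all(x %in% rba_scopes)) {
      stop(what, " must be one of: ", paste(rba_scopes, collapse = ", "),
           call. = FALSE)
    }
  }
  check_scope(fbdg_scope, "fbdg_scope")
  check_scope(fortification_scope, "fortification_scope")
  none <- fbdg_scope == "none" & fortification_scope == "none"
  all_c <- fbdg_scope == "all_countries" | fortification_scope == "all_countries"
  ifelse(none, 1L, ifelse(all_c, 3L, 2L))
}

#' @rdname nutrition_levels
#' @export
intake_level <- function(contribution, fallback_class,
                         cuts = rba_config()$nutrition$intake_cuts,
                         fallback_levels = rba_config()$nutrition$intake_fallback_levels) {
  n <- max(length(contribution), length(fallback_class))
  contribution <- rep_len(contribution, n)
  fallback_class <- rep_len(fallback_class, n)
  if (any(is.na(contribution) & is.na(fallback_class))) {
    stop("neither layer-1 intake contribution nor layer-2 class is present",
         call. = FALSE)
  }
  if (any(!is.na(contribution) & (contribution < 0 | contribution > 1))) {
    stop("intake contribution must lie in [0, 1]", call. = FALSE)
  }
  layer1 <- ifelse(contribution > cuts[2], 3L,
                   ifelse(contribution > cuts[1], 2L, 1L))
  use_fb <- is.na(contribution)
  if (any(use_fb)) {
    fb <- fallback_class[use_fb]
    unknown <- setdiff(unique(fb), names(fallback_levels))
    if (length(unknown) > 0) {
      stop("unknown composition-difference class: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    layer1[use_fb] <- unname(fallback_levels[fb])
  }
  as.integer(layer1)
}

#' @rdname nutrition_levels
#' @export
bioavailability_level <- function(reduction,
                                  levels = rba_config()$nutrition$bioavailability_levels) {
  if (any(is.na(reduction))) {
    stop("bioavailability_reduction is required", call. = FALSE)
  }
  unknown <- setdiff(unique(reduction), names(levels))
  if (length(unknown) > 0) {
    stop("unknown bioavailability class: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  unname(levels[reduction])
}

#' Resolve conflicting detection fractions by source robustness
#'
#' When several sources report a nutrient's sample-detection fraction,
#' values from national repositories are taken as more robust than
#' analytical results for a single sample; among equally robust sources
#' the largest fraction is kept (erring towards presence).
#'
#' @param fractions Candidate detection fractions for one component.
#' @param sources Parallel vector of source tags; \code{"national_repository"}
#'   outranks \code{"single_sample"} (and any other tag).
#' @return One resolved fraction.
#' @export
resolve_detection_fraction <- function(fractions, sources = NULL) {
  keep <- !is.na(fractions)
  fractions <- fractions[keep]
  if (length(fractions) == 0) {
    stop("no detection fraction to resolve", call. = FALSE)
  }
  if (!is.null(sources)) {
    sources <- rep_len(sources, length(keep))[keep]
    if (any(sources == "national_repository", na.rm = TRUE)) {
      fractions <- fractions[!is.na(sources) & sources == "national_repository"]
    }
  }
  max(fractions)
}

#' Nutrition prioritization index from five sub-criterion levels
#'
#' Multiplies the two occurrence levels into the occurrence criterion
#' score, the three public-health levels into the severity criterion
#' score, and the two criteria into the prioritization index; with five
#' 3-point sub-criteria the index ranges over the 3-smooth products from
#' 1 to 243. Using three severity sub-criteria against two occurrence
#' sub-criteria realizes the 3/5-vs-2/5 proportional weighting that gives
#' public-health impact more weight than occurrence for nutrients.
#'
#' @param occurrence_levels Integer vector (or 2-column matrix) of the two
#'   occurrence sub-scores, each in \{1, 2, 3\}.
#' @param severity_levels Integer vector (or 3-column matrix) of the three
#'   severity sub-scores, each in \{1, 2, 3\}.
#' @return A tibble with \code{occurrence_score}, \code{severity_score},
#'   \code{index}.
#' @examples
#' nutrition_index(c(3, 3), c(3, 3, 3))$index # 243
#' nutrition_index(c(2, 2), c(3, 3, 3))$index # 108, the inclusion threshold
#' @export
nutrition_index <- function(occurrence_levels, severity_levels) {
  occ <- if (is.matrix(occurrence_levels)) occurrence_levels else {
    if (length(occurrence_levels) != 2) {
      stop("exactly 2 occurrence sub-scores required", call. = FALSE)
    }
    matrix(occurrence_levels, ncol = 2)
  }
  sev <- if (is.matrix(severity_levels)) severity_levels else {
    if (length(severity_levels) != 3) {
      stop("exactly 3 severity sub-scores required", call. = FALSE)
    }
    matrix(severity_levels, ncol = 3)
  }
  if (ncol(occ) != 2) stop("exactly 2 occurrence sub-scores required",
                           call. = FALSE)
  if (ncol(sev) != 3) stop("exactly 3 severity sub-scores required",
                           call. = FALSE)
  check_levels(c(occ, sev))
  occurrence_score <- as.integer(occ[, 1] * occ[, 2])
  severity_score <- as.integer(sev[, 1] * sev[, 2] * sev[, 3])
  tibble::tibble(
    occurrence_score = occurrence_score,
    severity_score = severity_score,
    index = occurrence_score * severity_score
  )
}

check_levels <- function(x) {
  if (any(is.na(x)) || !all(x %in% 1:3)) {
    stop("sub-criterion levels must be integers in {1, 2, 3}", call. = FALSE)
  }
}

score_nutrition_rows <- function(profiles, config) {
  cfg <- config$nutrition
  p1 <- presence_level(profiles$sample_detection_fraction,
                       cfg$presence_low_fraction)
  p2 <- processing_level(profiles$processing_effect, cfg$processing_levels)
  s1 <- policy_level(profiles$fbdg_scope, profiles$fortification_scope)
  s2 <- intake_level(profiles$intake_contribution,
                     profiles$intake_fallback_class,
                     cfg$intake_cuts, cfg$intake_fallback_levels)
  s3 <- bioavailability_level(profiles$bioavailability_reduction,
                              cfg$bioavailability_levels)
  idx <- nutrition_index(cbind(p1, p2), cbind(s1, s2, s3))
  sub_scores <- purrr::pmap(
    list(p1, p2, s1, s2, s3, profiles$sample_detection_fraction,
         profiles$processing_effect, profiles$fbdg_scope,
         profiles$fortification_scope, profiles$intake_contribution,
         profiles$intake_fallback_class, profiles$bioavailability_reduction),
    function(p1, p2, s1, s2, s3, det, proc, fbdg, fort, contrib, fb, bio) {
      tibble::tibble(
        criterion = c("occurrence", "occurrence",
                      "severity", "severity", "severity"),
        name = c("presence_in_raw_material", "processing_effect",
                 "policy_relevance", "intake_contribution",
                 "bioavailability"),
        level = c(p1, p2, s1, s2, s3),
        rationale = c(
          sprintf("detected in %.0f%% of samples", 100 * det),
          sprintf("processing effect: %s", proc),
          sprintf("FBDG scope: %s; fortification scope: %s", fbdg, fort),
          if (is.na(contrib)) sprintf("layer-2 composition difference: %s", fb)
          else sprintf("layer-1 contribution to intake: %.0f%%", 100 * contrib),
          sprintf("bioavailability reduction: %s", bio)
        )
      )
    }
  )
  tibble::tibble(
    component_id = profiles$component_id, food_id = profiles$food_id,
    domain = profiles$domain,
    occurrence_score = idx$occurrence_score,
    severity_score = idx$severity_score,
    index = idx$index, sub_scores = sub_scores
  )
}
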