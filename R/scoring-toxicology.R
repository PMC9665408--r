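#' Chemical hazard scoring
#'
#' The chemical hazard index multiplies an occurrence criterion and a
#' severity criterion, each graded 1-3, giving an index between 1 and 9
#' with the two criteria contributing equally.
#'
#' Occurrence has two sub-criteria. Presence relative to reference doses
#' scores 1 when the agent's concentration in the food is below the limit
#' of detection or quantitation (LOD/LOQ); above it, the score is 3 when
#' total exposure exceeds the health-based guidance value (HBGV;
#' non-genotoxic agents) or the margin of exposure (MoE) falls below
#' 10,000 (genotoxic carcinogens), and 2 when that exceedance condition
#' fails. Contribution to total exposure grades the share of total
#' dietary exposure coming from the food: <10% scores 1, 10-50% scores 2
#' (both edges in the band), >50% scores 3. The two sub-scores are
#' combined into one 1-3 criterion; the default combiner is the ceiling
#' of their mean, which keeps the final index within the printed 1-9
#' range (alternatives: \code{"min"}, \code{"max"}).
#'
#' Severity counts how many of four statements hold for the associated
#' disease or condition: high incidence in the population under study,
#' fatal, associated with lifelong disability, associated with high
#' disability (rounded disability weight above 0.4). The default map
#' grades at most one true statement as 1, exactly two as 2, and three
#' or more as 3.
#'
#' @param above_lod_loq Logical; concentration above LOD/LOQ.
#' @param genotoxic_carcinogen Logical; selects the MoE path (TRUE) or the
#'   HBGV path (FALSE). Required only when above LOD/LOQ.
#' @param exceeds_hbgv Logical; total exposure exceeds the HBGV
#'   (non-genotoxic path).
#' @param moe_below_10000 Logical; MoE below 10,000 (genotoxic path).
#' @param exposure_share Share of total dietary exposure from this food,
#'   in [0, 1].
#' @param bins Two increasing edges for the exposure bands (defaults 0.10
#'   and 0.50).
#' @param presence_score,contribution_score Sub-scores in \{1, 2, 3\}.
#' @param combiner \code{"ceiling_mean"} (default), \code{"min"}, or
#'   \code{"max"}.
#' @param high_incidence,fatal,lifelong_disability,high_disability The
#'   four severity statements as logicals.
#' @param map Named integer map from true-statement count (0-4) to level.
#' @param occurrence,severity Criterion scores in \{1, 2, 3\}.
#' @return Level helpers return integer levels; \code{tox_index()} returns
#'   a tibble with \code{occurrence_score}, \code{severity_score},
#'   \code{index}.
#' @examples
#' tox_presence_level(TRUE, genotoxic_carcinogen = TRUE,
#'                    moe_below_10000 = FALSE)     # 2
#' tox_exposure_level(c(0.05, 0.30, 0.60))         # 1 2 3
#' tox_severity(TRUE, TRUE, FALSE, FALSE)          # 2
#' tox_index(3, 3)$index                           # 9
#' @name toxicology_scoring
NULL

#' @rdname toxicology_scoring
#' @export
tox_presence_level <- function(above_lod_loq, genotoxic_carcinogen = NA,
                               exceeds_hbgv = NA, moe_below_10000 = NA) {
  n <- length(above_lod_loq)
  genotoxic_carcinogen <- rep_len(genotoxic_carcinogen, n)
  exceeds_hbgv <- rep_len(exceeds_hbgv, n)
  moe_below_10000 <- rep_len(moe_below_10000, n)
  if (any(is.na(above_lod_loq))) {
    stop("above_lod_loq is required", call. = FALSE)
  }
  above <- above_lod_loq
  if (any(above & is.na(genotoxic_carcinogen))) {
    stop("genotoxic_carcinogen flag required when the agent is above LOD/LOQ",
         call. = FALSE)
  }
  geno <- above & genotoxic_carcinogen
  nongeno <- above & !genotoxic_carcinogen
  if (any(geno & is.na(moe_below_10000))) {
    stop("moe_below_10000 flag required for genotoxic carcinogens",
         call. = FALSE)
  }
  if (any(nongeno & is.na(exceeds_hbgv))) {
    stop("exceeds_hbgv flag required for non-genotoxic agents", call. = FALSE)
  }
  exceed <- ifelse(geno, moe_below_10000, ifelse(nongeno, exceeds_hbgv, FALSE))
  ifelse(!above, 1L, ifelse(exceed, 3L, 2L))
}

#' @rdname toxicology_scoring
#' @export
tox_exposure_level <- function(exposure_share,
                               bins = rba_config()$toxicology$exposure_bins) {
  x <- exposure_share
  if (any(is.na(x))) stop("exposure share is required", call. = FALSE)
  if (any(x < 0 | x > 1)) {
    stop("exposure share must lie in [0, 1]", call. = FALSE)
  }
  # both printed edges belong to the middle band: exactly 10% and exactly
  # 50% score 2
  ifelse(x > bins[2], 3L, ifelse(x >= bins[1], 2L, 1L))
}

#' @rdname toxicology_scoring
#' @export
tox_occurrence <- function(presence_score, contribution_score,
                           combiner = c("ceiling_mean", "min", "max")) {
  combiner <- match.arg(combiner)
  check_levels(c(presence_score, contribution_score))
  out <- switch(combiner,
    ceiling_mean = ceiling((presence_score + contribution_score) / 2),
    min = pmin(presence_score, contribution_score),
    max = pmax(presence_score, contribution_score)
  )
  as.integer(out)
}

#' @rdname toxicology_scoring
#' @export
tox_severity <- function(high_incidence, fatal, lifelong_disability,
                         high_disability,
                         map = rba_config()$toxicology$severity_map) {
  statements <- cbind(high_incidence, fatal, lifelong_disability,
                      high_disability)
  if (any(is.na(statements))) {
    stop("all four severity statements must be TRUE or FALSE", call. = FALSE)
  }
  k <- rowSums(statements)
  unname(map[as.character(k)])
}

#' @rdname toxicology_scoring
#' @export
tox_index <- function(occurrence, severity) {
  check_levels(c(occurrence, severity))
  tibble::tibble(
    occurrence_score = as.integer(occurrence),
    severity_score = as.integer(severity),
    index = as.integer(occurrence * severity)
  )
}

score_toxicology_rows <- function(profiles, config) {
  cfg <- config$toxicology
  pres <- tox_presence_level(profiles$above_lod_loq,
                             profiles$genotoxic_carcinogen,
                             profiles$exceeds_hbgv,
                             profiles$moe_below_10000)
  contrib <- tox_exposure_level(profiles$exposure_share_of_diet,
                                cfg$exposure_bins)
  occ <- tox_occurrence(pres, contrib, cfg$occurrence_combiner)
  sev <- tox_severity(profiles$sev_high_incidence, profiles$sev_fatal,
                      profiles$sev_lifelong_disability,
                      profiles$sev_high_disability, cfg$severity_map)
  idx <- tox_index(occ, sev)
  k <- rowSums(cbind(profiles$sev_high_incidence, profiles$sev_fatal,
                     profiles$sev_lifelong_disability,
                     profiles$sev_high_disability))
  sub_scores <- purrr::pmap(
    list(pres, contrib, occ, sev, profiles$above_lod_loq,
         profiles$exposure_share_of_diet, k),
    function(pres, contrib, occ, sev, above, share, k) {
      tibble::tibble(
        criterion = c("occurrence", "occurrence", "occurrence", "severity"),
        name = c("presence_vs_reference_dose", "exposure_contribution",
                 "occurrence_combined", "severity_statements"),
        level = c(pres, contrib, occ, sev),
        rationale = c(
          if (above) "above LOD/LOQ" else "below LOD/LOQ",
          sprintf("%.0f%% of total dietary exposure", 100 * share),
          sprintf("combined from sub-scores %d and %d", pres, contrib),
          sprintf("%d of 4 severity statements hold", k)
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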