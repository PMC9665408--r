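#' Microbiological hazard scoring
#'
#' The microbiological hazard index follows the hazard-analysis tradition:
#' occurrence (criterion 1) combines the prevalence of the hazard in the
#' raw food with the effect of the manufacturing process, and severity
#' (criterion 2) grades the mean disease burden per case, expressed in
#' DALYs per 1,000 cases. The two criteria are multiplied so that they
#' contribute equally, giving an index between 1 and 9.
#'
#' The occurrence criterion multiplies its two 1-3 sub-scores, which
#' yields a raw product in \{1, 2, 3, 4, 6, 9\}; the raw product is then
#' re-mapped onto the 1-3 scale (default bands: 1-2 to 1, 3-4 to 2,
#' 6-9 to 3) so the final index stays within the 1-9 range. The band map
#' is configurable and recorded in run output.
#'
#' @param prevalence_level,process_level Integer sub-scores in \{1, 2, 3\}.
#' @param band_map Named integer map from raw product to 1-3.
#' @param daly_per_1000_cases Non-negative mean DALYs per 1,000 cases of
#'   illness.
#' @param bins Two increasing DALY edges; with the defaults \code{c(10, 100)}
#'   the bands are <10, 10-99, and 100-1,000 (closed on the left, so
#'   exactly 10 scores 2 and exactly 100 scores 3).
#' @param top Upper end of the top band; values above it clamp to level 3
#'   with a warning.
#' @param occurrence,severity Criterion scores in \{1, 2, 3\}.
#' @return \code{micro_occurrence()} and \code{micro_severity()} return
#'   integer levels; \code{micro_index()} returns a tibble with
#'   \code{occurrence_score}, \code{severity_score}, \code{index}.
#' @examples
#' micro_occurrence(2, 2)  # raw 4 -> band 2
#' micro_severity(c(5, 50, 500)) # 1 2 3
#' micro_index(2, 3)$index # 6
#' @name microbiology_scoring
NULL

#' @rdname microbiology_scoring
#' @export
micro_occurrence <- function(prevalence_level, process_level,
                             band_map = rba_config()$microbiology$occurrence_band_map) {
  check_levels(c(prevalence_level, process_level))
  raw <- prevalence_level * process_level
  unname(band_map[as.character(raw)])
}

#' @rdname microbiology_scoring
#' @export
micro_severity <- function(daly_per_1000_cases,
                           bins = rba_config()$microbiology$severity_bins,
                           top = rba_config()$microbiology$severity_top) {
  d <- daly_per_1000_cases
  if (any(is.na(d))) stop("DALY per 1,000 cases is required", call. = FALSE)
  if (any(d < 0)) stop("DALY per 1,000 cases must be non-negative",
                       call. = FALSE)
  if (any(d > top)) {
    warning("DALY per 1,000 cases above ", top,
            " for some hazards; clamped to the top severity band",
            call. = FALSE)
  }
  ifelse(d >= bins[2], 3L, ifelse(d >= bins[1], 2L, 1L))
}

#' @rdname microbiology_scoring
#' @export
micro_index <- function(occurrence, severity) {
  check_levels(c(occurrence, severity))
  tibble::tibble(
    occurrence_score = as.integer(occurrence),
    severity_score = as.integer(severity),
    index = as.integer(occurrence * severity)
  )
}

prevalence_level_from_class <- function(class, levels) {
  if (any(is.na(class))) stop("prevalence_class is required", call. = FALSE)
  unknown <- setdiff(unique(class), names(levels))
  if (length(unknown) > 0) {
    stop("unknown prevalence class: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  unname(levels[class])
}

score_microbiology_rows <- function(profiles, config) {
  cfg <- config$microbiology
  prev <- prevalence_level_from_class(profiles$prevalence_class,
                                      cfg$prevalence_levels)
  proc <- processing_level(profiles$processing_effect, cfg$processing_levels)
  occ <- micro_occurrence(prev, proc, cfg$occurrence_band_map)
  sev <- micro_severity(profiles$daly_per_1000_cases, cfg$severity_bins,
                        cfg$severity_top)
  idx <- micro_index(occ, sev)
  sub_scores <- purrr::pmap(
    list(prev, proc, occ, sev, profiles$prevalence_class,
         profiles$processing_effect, profiles$daly_per_1000_cases),
    function(prev, proc, occ, sev, pcls, peff, daly) {
      tibble::tibble(
        criterion = c("occurrence", "occurrence", "occurrence", "severity"),
        name = c("prevalence_in_raw_food", "process_effect",
                 "occurrence_combined", "daly_burden"),
        level = c(prev, proc, occ, sev),
        rationale = c(
          sprintf("prevalence class: %s", pcls),
          sprintf("process effect: %s", peff),
          sprintf("raw product %d banded to %d", prev * proc, occ),
          sprintf("%.1f DALYs per 1,000 cases", daly)
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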