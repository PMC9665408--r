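#' Apply the short-list inclusion thresholds
#'
#' A component enters the short list when its prioritization index reaches
#' the domain threshold (inclusive, so a printed limit is itself
#' includable). The defaults are 108 for nutrition — attainable, e.g. as
#' 2 x 2 x 3 x 3 x 3 — and 2 for both hazard domains, the same limit for
#' both foods in each domain.
#'
#' @param scores A tibble from [score_components()] (or [rank_components()]).
#' @param config An [rba_config()]; thresholds under
#'   \code{selection$thresholds}.
#' @return A list with \code{members} (short-listed score rows) and
#'   \code{ledger} (stage \code{"shortlist"}, one entry per scored row).
#' @export
apply_shortlist_threshold <- function(scores, config = NULL) {
  config <- as_rba_config(config)
  thr <- config$selection$thresholds
  threshold <- unlist(thr[scores$domain], use.names = FALSE)
  if (nrow(scores) == 0) {
    return(list(members = scores, ledger = ledger_prototype()))
  }
  keep <- scores$index >= threshold
  reason <- sprintf("index %d %s threshold %d", scores$index,
                    ifelse(keep, ">=", "<"), threshold)
  ledger <- tibble::tibble(
    component_id = scores$component_id, food_id = scores$food_id,
    domain = scores$domain, stage = "shortlist",
    decision = ifelse(keep, "included", "excluded"), reason = reason
  )
  list(members = scores[keep, ], ledger = ledger)
}

#' Expand short-listed nutrients symmetrically over both foods
#'
#' In a substitution assessment, a nutrient short-listed for only one of
#' the two foods is systematically considered for the other food as well,
#' so the change in nutrient exposure can be assessed on both sides. The
#' added candidates are flagged \code{symmetry_added}. Hazards are never
#' expanded this way: a hazard corresponds to a contamination, and each
#' food is considered independently.
#'
#' @param shortlist Nutrition short-list rows (columns \code{component_id},
#'   \code{food_id}, \code{domain}); calling this on hazard rows is an
#'   error.
#' @param foods Character vector of the two food ids in the scenario.
#' @return A tibble of final-list candidates with a \code{symmetry_added}
#'   flag.
#' @export
apply_nutrient_symmetry <- function(shortlist, foods) {
  if (nrow(shortlist) > 0 && any(shortlist$domain != "nutrition")) {
    stop("the symmetry rule applies to nutrients only; ",
         "hazards are considered independently per food", call. = FALSE)
  }
  if (length(foods) != 2) {
    stop("a substitution scenario has exactly two foods", call. = FALSE)
  }
  base <- tibble::tibble(
    component_id = shortlist$component_id, food_id = shortlist$food_id,
    domain = if (nrow(shortlist)) shortlist$domain else character(),
    symmetry_added = rep(FALSE, nrow(shortlist))
  )
  if (nrow(base) == 0) return(base)
  added <- base |>
    dplyr::group_by(.data$component_id) |>
    dplyr::filter(dplyr::n_distinct(.data$food_id) == 1) |>
    dplyr::summarise(
      food_id = setdiff(foods, .data$food_id),
      domain = "nutrition", .groups = "drop"
    ) |>
    dplyr::mutate(symmetry_added = TRUE)
  dplyr::bind_rows(base, added) |>
    dplyr::arrange(.data$component_id, .data$food_id)
}

checklist_prototype <- function() {
  tibble::tibble(
    component_id = character(), food_id = character(),
    has_dose_response = logical(), has_incidence = logical(),
    has_source_attribution = logical(), has_intake_data = logical(),
    has_composition_or_contamination = logical(),
    has_daly_per_case = logical()
  )
}

#' Coerce a data frame to the data-availability checklist schema
#'
#' @param x A data frame with \code{component_id}, \code{food_id} and the
#'   six availability flags (see [apply_checklist_gate()]).
#' @return A checklist tibble.
#' @export
as_checklist <- function(x) {
  x <- tibble::as_tibble(x)
  proto <- checklist_prototype()
  missing <- setdiff(names(proto), names(x))
  if (length(missing) > 0) {
    stop("checklist lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x[, names(proto)]
}

#' Gate final-list candidates on data availability
#'
#' A component can be carried into the quantitative burden model only when
#' the data it needs are available: dose-response data for each health
#' outcome, incidence of each outcome, source attribution (applicable to
#' microbiological hazards only), current and alternative food intake
#' data, composition or contamination data, and a DALY value per case.
#' Candidates missing any applicable item are excluded, and the missing
#' items are named in the ledger — such exclusions are a source of
#' uncertainty in the health impact and a priority for improvement, so
#' they must be communicated alongside results.
#'
#' All flags must be explicit TRUE/FALSE; an NA flag for a candidate is an
#' error, as is a candidate with no checklist row.
#'
#' @param candidates Tibble of final-list candidates (\code{component_id},
#'   \code{food_id}, \code{domain}, optionally \code{symmetry_added}).
#' @param checklist A tibble coercible via [as_checklist()].
#' @return A list with \code{members} (the final list, keeping
#'   \code{symmetry_added} if present) and \code{ledger} (stage
#'   \code{"finallist"}).
#' @export
apply_checklist_gate <- function(candidates, checklist) {
  checklist <- as_checklist(checklist)
  if (nrow(candidates) == 0) {
    return(list(members = candidates, ledger = ledger_prototype()))
  }
  joined <- dplyr::left_join(candidates, checklist,
                             by = c("component_id", "food_id"))
  no_status <- is.na(joined$has_dose_response) &
    is.na(joined$has_incidence) & is.na(joined$has_intake_data) &
    is.na(joined$has_composition_or_contamination) &
    is.na(joined$has_daly_per_case)
  if (any(no_status)) {
    stop("no checklist status for: ",
         paste(joined$component_id[no_status], joined$food_id[no_status],
               sep = "/", collapse = ", "), call. = FALSE)
  }
  flags <- c("has_dose_response", "has_incidence", "has_source_attribution",
             "has_intake_data", "has_composition_or_contamination",
             "has_daly_per_case")
  applicable <- function(flag, domain) {
    flag != "has_source_attribution" | domain == "microbiology"
  }
  missing_items <- purrr::map_chr(seq_len(nrow(joined)), function(i) {
    items <- character()
    for (flag in flags) {
      if (!applicable(flag, joined$domain[i])) next
      val <- joined[[flag]][i]
      if (is.na(val)) {
        stop("checklist flag ", flag, " must be explicit TRUE/FALSE for ",
             joined$component_id[i], "/", joined$food_id[i], call. = FALSE)
      }
      if (!val) items <- c(items, sub("^has_", "", flag))
    }
    paste(items, collapse = ", ")
  })
  keep <- missing_items == ""
  ledger <- tibble::tibble(
    component_id = joined$component_id, food_id = joined$food_id,
    domain = joined$domain, stage = "finallist",
    decision = ifelse(keep, "included", "excluded"),
    reason = ifelse(keep, "all required data available",
                    paste0("missing data: ", missing_items))
  )
  list(members = candidates[keep, ], ledger = ledger)
}
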