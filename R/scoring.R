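#' Score components with their domain's occurrence-by-severity criteria
#'
#' Dispatches every profile row to its domain scorer (nutrition,
#' microbiology, or toxicology) and returns one prioritization index per
#' component-by-food, with the full sub-score audit trail. The index is
#' always the product of the occurrence and severity criterion scores;
#' nutrition indices range over 1-243 (five 3-point sub-criteria),
#' hazard indices over 1-9.
#'
#' @param profiles Profile tibble; every row must satisfy
#'   [validate_profiles()] for its domain.
#' @param config An [rba_config()] or named override list.
#' @return A tibble with \code{component_id}, \code{food_id},
#'   \code{domain}, \code{occurrence_score}, \code{severity_score},
#'   \code{index}, and a \code{sub_scores} list-column of per-sub-criterion
#'   tibbles (criterion, name, level, rationale).
#' @export
score_components <- function(profiles, config = NULL) {
  config <- as_rba_config(config)
  profiles <- as_profiles(profiles)
  findings <- validate_profiles(profiles)
  if (nrow(findings) > 0) {
    stop("profiles are not scoreable; first finding: ",
         findings$component_id[1], "/", findings$food_id[1], " ",
         findings$field[1], ": ", findings$message[1],
         " (", nrow(findings), " finding(s) in total; run validate_profiles())",
         call. = FALSE)
  }
  pieces <- list()
  for (dom in rba_domains) {
    rows <- profiles[profiles$domain == dom, ]
    if (nrow(rows) == 0) next
    pieces[[dom]] <- switch(dom,
      nutrition = score_nutrition_rows(rows, config),
      microbiology = score_microbiology_rows(rows, config),
      toxicology = score_toxicology_rows(rows, config)
    )
  }
  out <- if (length(pieces) == 0) {
    tibble::tibble(component_id = character(), food_id = character(),
                   domain = character(), occurrence_score = integer(),
                   severity_score = integer(), index = integer(),
                   sub_scores = list())
  } else {
    dplyr::bind_rows(pieces)
  }
  stopifnot(all(out$index == out$occurrence_score * out$severity_score))
  out
}

#' Rank scored components within each food and domain
#'
#' Orders components by descending prioritization index; ties are broken
#' by descending severity criterion score and then by component id, so
#' the ranking is deterministic.
#'
#' @param scores A tibble from [score_components()].
#' @return The same tibble ordered within (food, domain), with a
#'   \code{rank} column.
#' @export
rank_components <- function(scores) {
  if (nrow(scores) == 0) {
    scores$rank <- integer()
    return(scores)
  }
  scores |>
    dplyr::arrange(.data$food_id, .data$domain, dplyr::desc(.data$index),
                   dplyr::desc(.data$severity_score), .data$component_id) |>
    dplyr::group_by(.data$food_id, .data$domain) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
}
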