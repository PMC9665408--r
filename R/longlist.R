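#' Relative concentration difference between two foods
#'
#' The long-list rule for nutrients present in both foods compares their
#' concentrations: the pair enters the long list only when the relative
#' difference exceeds a threshold (20% by default, chosen as a 10%
#' allowance for analytical error plus a 10% minimum meaningful
#' difference). The default denominator is the mean of the two values,
#' which makes the measure symmetric in the two foods and scale-invariant;
#' under it the result lies in [0, 2].
#'
#' @param conc_a,conc_b Non-negative concentrations in the same unit.
#'   Vectorized.
#' @param denominator One of \code{"mean"} (default), \code{"max"}, or
#'   \code{"reference"} (food A's value).
#' @return Numeric vector of relative differences.
#' @examples
#' relative_difference(100, 150) # 0.4
#' relative_difference(0, 50)    # 2: always passes any threshold <= 200%
#' @export
relative_difference <- function(conc_a, conc_b,
                                denominator = c("mean", "max", "reference")) {
  denominator <- match.arg(denominator)
  if (any(is.na(conc_a)) || any(is.na(conc_b))) {
    stop("both concentrations must be present", call. = FALSE)
  }
  if (any(conc_a < 0) || any(conc_b < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (any(conc_a == 0 & conc_b == 0)) {
    stop("relative difference is undefined when both concentrations are zero",
         call. = FALSE)
  }
  denom <- switch(denominator,
    mean = (conc_a + conc_b) / 2,
    max = pmax(conc_a, conc_b),
    reference = conc_a
  )
  if (denominator == "reference" && any(denom == 0)) {
    stop("reference denominator is zero", call. = FALSE)
  }
  abs(conc_a - conc_b) / denom
}

ledger_prototype <- function() {
  tibble::tibble(component_id = character(), food_id = character(),
                 domain = character(), stage = character(),
                 decision = character(), reason = character())
}

ledger_rows <- function(rows, stage, decision, reason) {
  if (nrow(rows) == 0) return(ledger_prototype())
  tibble::tibble(component_id = rows$component_id, food_id = rows$food_id,
                 domain = rows$domain, stage = stage, decision = decision,
                 reason = reason)
}

#' Assemble the long list from the two foods' profiles
#'
#' The long list gathers every candidate component per domain. Nutrients
#' present in only one food are always included (the comparison is a
#' substitution assessment), nutrients quantified in both foods are
#' included only when their relative concentration difference strictly
#' exceeds the configured threshold, and all reported microbiological and
#' toxicological hazards are included for each food in which they were
#' found. Every decision, with the computed difference where one was
#' computed, is logged to the selection ledger.
#'
#' When a nutrient has rows for both foods but lacks a numeric
#' concentration in one of them, it is kept on qualitative presence: the
#' numeric rule applies only when both numbers exist.
#'
#' @param profiles Profile tibble covering exactly two foods.
#' @param config An [rba_config()] (or named override list); uses
#'   \code{longlist$concentration_diff_threshold} and
#'   \code{longlist$diff_denominator}.
#' @return A list with \code{members} (the long-list profile rows) and
#'   \code{ledger} (one entry per submitted row, stage \code{"longlist"}).
#' @export
build_long_list <- function(profiles, config = NULL) {
  config <- as_rba_config(config)
  profiles <- as_profiles(profiles)
  if (anyDuplicated(profiles[, c("component_id", "food_id")]) > 0) {
    stop("duplicate (component_id, food_id) rows in profiles", call. = FALSE)
  }
  foods <- unique(profiles$food_id)
  if (nrow(profiles) > 0 && length(foods) != 2) {
    stop("long-list assembly expects profiles for exactly two foods, got ",
         length(foods), call. = FALSE)
  }
  threshold <- config$longlist$concentration_diff_threshold
  denom <- config$longlist$diff_denominator

  decide_nutrient <- function(rows) {
    if (nrow(rows) == 1) {
      return(list(include = TRUE,
                  reason = "present in one food only (substitution assessment)"))
    }
    conc <- rows$concentration
    if (any(is.na(conc))) {
      return(list(include = TRUE,
                  reason = "qualitative presence in both foods (no numeric rule)"))
    }
    if (all(conc == 0)) {
      return(list(include = FALSE,
                  reason = "relative difference undefined (zero in both foods)"))
    }
    units <- unique(rows$unit[!is.na(rows$unit)])
    if (length(units) > 1) {
      stop("concentration unit differs between foods for component ",
           rows$component_id[1], call. = FALSE)
    }
    d <- relative_difference(conc[1], conc[2], denominator = denom)
    list(
      include = d > threshold,
      reason = sprintf(
        "relative concentration difference %.4f %s threshold %.2f",
        d, if (d > threshold) ">" else "<=", threshold
      )
    )
  }

  ledger <- list()
  keep <- rep(TRUE, nrow(profiles))
  nut_idx <- which(profiles$domain == "nutrition")
  if (length(nut_idx) > 0) {
    nut <- profiles[nut_idx, ]
    for (cid in unique(nut$component_id)) {
      sel <- nut_idx[nut$component_id == cid]
      verdict <- decide_nutrient(profiles[sel, ])
      keep[sel] <- verdict$include
      ledger[[length(ledger) + 1]] <- ledger_rows(
        profiles[sel, ], "longlist",
        if (verdict$include) "included" else "excluded", verdict$reason
      )
    }
  }
  haz_idx <- which(profiles$domain != "nutrition")
  if (length(haz_idx) > 0) {
    ledger[[length(ledger) + 1]] <- ledger_rows(
      profiles[haz_idx, ], "longlist", "included",
      "hazard reported for this food (all reported hazards considered)"
    )
  }
  list(
    members = profiles[keep, ],
    ledger = if (length(ledger) == 0) ledger_prototype() else
      dplyr::bind_rows(ledger)
  )
}

#' Apply the evidence-level gate to the long list
#'
#' Components stay only when the evidence linking them to a health outcome
#' is classified as convincing; those with limited or contradictory
#' evidence are excluded and logged. Together with the
#' concentration-difference question applied at long-list assembly, this
#' realizes the rule that a "no" to either screening question drops the
#' component.
#'
#' @param long_list Profile tibble (typically \code{$members} from
#'   [build_long_list()]).
#' @return A list with \code{members} (the retained rows) and
#'   \code{ledger} (stage \code{"evidence_gate"}).
#' @export
evidence_gate <- function(long_list) {
  long_list <- as_profiles(long_list)
  if (any(is.na(long_list$evidence_level))) {
    stop("every long-list member needs an evidence_level", call. = FALSE)
  }
  bad <- !long_list$evidence_level %in% rba_evidence_levels
  if (any(bad)) {
    stop("unknown evidence_level: ",
         paste(unique(long_list$evidence_level[bad]), collapse = ", "),
         call. = FALSE)
  }
  keep <- long_list$evidence_level == "convincing"
  ledger <- dplyr::bind_rows(
    ledger_rows(long_list[keep, ], "evidence_gate", "included",
                "evidence level convincing"),
    ledger_rows(long_list[!keep, ], "evidence_gate", "excluded",
                paste0("evidence level: ", long_list$evidence_level[!keep]))
  )
  list(members = long_list[keep, ], ledger = ledger)
}
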