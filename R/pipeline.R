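#' Run the full three-tier component-selection pipeline
#'
#' Executes, in order: long-list assembly (concentration-difference rule
#' for nutrients, all reported hazards), the evidence gate, domain scoring
#' into occurrence-by-severity prioritization indices, ranking, the
#' short-list thresholds, the nutrient symmetry expansion, and the
#' data-availability checklist gate. Every inclusion and exclusion is
#' recorded in the selection ledger, and the configuration snapshot is
#' embedded in the result, so a run is fully determined by its inputs.
#'
#' @param profiles Profile tibble for the two foods under comparison
#'   (see [as_profiles()], [read_profiles()]).
#' @param checklist Data-availability checklist (see [as_checklist()]);
#'   required for the final-list gate. Candidates without a row are an
#'   error.
#' @param config An [rba_config()] or named override list.
#' @param outcomes Optional tibble of component-to-health-outcome links
#'   (\code{component_id}, \code{outcome_name},
#'   \code{direction} in \{"beneficial", "adverse"\}) used to build the
#'   outcome tree of the final list.
#' @param scenario_id Label stored in the result and reports.
#' @return An object of class \code{rba_run}: a list with \code{scenario_id},
#'   \code{foods}, \code{long_list}, \code{evidence_gated}, \code{scores}
#'   (ranked), \code{short_list}, \code{candidates} (after symmetry),
#'   \code{final_list}, \code{ledger}, \code{outcome_tree}, \code{config}.
#' @examples
#' novrba <- load_novrba()
#' run <- rba_run(novrba$profiles, novrba$checklist, outcomes = novrba$outcomes)
#' glance(run)
#' @export
rba_run <- function(profiles, checklist, config = NULL, outcomes = NULL,
                    scenario_id = "scenario") {
  config <- as_rba_config(config)
  profiles <- as_profiles(profiles)
  foods <- unique(profiles$food_id)

  ll <- build_long_list(profiles, config)
  eg <- evidence_gate(ll$members)
  scores <- rank_components(score_components(eg$members, config))
  sl <- apply_shortlist_threshold(scores, config)

  nut_sl <- sl$members[sl$members$domain == "nutrition", ]
  haz_sl <- sl$members[sl$members$domain != "nutrition", ]
  candidates <- dplyr::bind_rows(
    if (length(foods) == 2) apply_nutrient_symmetry(nut_sl, foods) else
      tibble::tibble(component_id = nut_sl$component_id,
                     food_id = nut_sl$food_id, domain = nut_sl$domain,
                     symmetry_added = rep(FALSE, nrow(nut_sl))),
    tibble::tibble(component_id = haz_sl$component_id,
                   food_id = haz_sl$food_id, domain = haz_sl$domain,
                   symmetry_added = rep(FALSE, nrow(haz_sl)))
  )
  fl <- if (nrow(candidates) > 0) {
    apply_checklist_gate(candidates, checklist)
  } else {
    list(members = candidates, ledger = ledger_prototype())
  }

  ledger <- dplyr::bind_rows(ll$ledger, eg$ledger, sl$ledger, fl$ledger)
  tree <- if (!is.null(outcomes)) {
    outcome_tree(fl$members, outcomes)
  } else {
    outcome_tree(fl$members,
                 tibble::tibble(component_id = character(),
                                outcome_name = character(),
                                direction = character()))
  }
  structure(
    list(scenario_id = scenario_id, foods = foods,
         long_list = ll$members, evidence_gated = eg$members,
         scores = scores, short_list = sl$members, candidates = candidates,
         final_list = fl$members, ledger = ledger, outcome_tree = tree,
         config = config),
    class = "rba_run"
  )
}

#' @export
print.rba_run <- function(x, ...) {
  cat("<rba_run>", x$scenario_id, "-- foods:",
      paste(x$foods, collapse = " vs "), "\n")
  counts <- glance(x)
  cat(sprintf("  long list: %d | evidence-gated: %d | short list: %d | final list: %d\n",
              counts$n_longlist, counts$n_evidence_gated, counts$n_shortlist,
              counts$n_finallist))
  cat("  ledger entries:", nrow(x$ledger), "\n")
  invisible(x)
}

#' Tidy a pipeline run into one row per scored component-by-food
#'
#' @param x An \code{rba_run}.
#' @param ... Unused.
#' @return A tibble of scores with logical stage-membership columns
#'   \code{in_shortlist}, \code{in_finallist}, and \code{symmetry_added}.
#' @method tidy rba_run
#' @export
tidy.rba_run <- function(x, ...) {
  key <- function(df) paste(df$component_id, df$food_id)
  scores <- x$scores
  scores$in_shortlist <- key(scores) %in% key(x$short_list)
  scores$in_finallist <- key(scores) %in% key(x$final_list)
  sym <- x$candidates[x$candidates$symmetry_added, ]
  extra <- sym[!key(sym) %in% key(scores), ]
  if (nrow(extra) > 0) {
    extra_rows <- tibble::tibble(
      component_id = extra$component_id, food_id = extra$food_id,
      domain = extra$domain, occurrence_score = NA_integer_,
      severity_score = NA_integer_, index = NA_integer_,
      sub_scores = vector("list", nrow(extra)), rank = NA_integer_,
      in_shortlist = FALSE, in_finallist = key(extra) %in% key(x$final_list)
    )
    scores <- dplyr::bind_rows(scores, extra_rows)
  }
  scores$symmetry_added <- key(scores) %in% key(sym)
  scores
}

#' One-row summary of a pipeline run
#'
#' @param x An \code{rba_run}.
#' @param ... Unused.
#' @return A one-row tibble of stage counts.
#' @method glance rba_run
#' @export
glance.rba_run <- function(x, ...) {
  tibble::tibble(
    scenario_id = x$scenario_id,
    n_profiles = nrow(x$long_list) +
      sum(x$ledger$stage == "longlist" & x$ledger$decision == "excluded"),
    n_longlist = nrow(x$long_list),
    n_evidence_gated = nrow(x$evidence_gated),
    n_shortlist = nrow(x$short_list),
    n_finallist = nrow(x$final_list),
    n_ledger = nrow(x$ledger)
  )
}

#' Plot prioritization indices against the short-list thresholds
#'
#' One panel per domain and food: components ordered by rank, index on
#' the y axis, the domain's inclusive threshold as a dashed line, and
#' final-list members emphasized.
#'
#' @param object An \code{rba_run}.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rba_run
#' @export
autoplot.rba_run <- function(object, ...) {
  d <- tidy(object)
  d <- d[!is.na(d$index), ]
  thr <- tibble::tibble(
    domain = rba_domains,
    threshold = unlist(object$config$selection$thresholds[rba_domains])
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$index,
                                  shape = .data$in_finallist,
                                  colour = .data$in_shortlist)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(data = thr,
                        ggplot2::aes(yintercept = .data$threshold),
                        linetype = "dashed") +
    ggplot2::facet_grid(domain ~ food_id, scales = "free") +
    ggplot2::labs(x = "rank within food and domain",
                  y = "prioritization index (occurrence x severity)",
                  colour = "short-listed", shape = "final list") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance
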