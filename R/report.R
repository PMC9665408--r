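#' Build the outcome tree of the final list
#'
#' Associates each final-list component with its identified health
#' outcomes and the direction of the expected effect — adverse or
#' beneficial. The same nutrient can carry both directions (e.g. adverse
#' at high intake, beneficial otherwise), so a component may contribute
#' several edges. Links that reference a component outside the final list
#' are dropped with a warning (not an error); final-list components with
#' no mapped outcome are kept with an NA outcome so the report can list
#' them under "no outcome mapped".
#'
#' @param final_list Tibble of final-list members (\code{component_id},
#'   \code{food_id}, \code{domain}).
#' @param outcome_links Tibble with \code{component_id},
#'   \code{outcome_name}, \code{direction} in
#'   \{"beneficial", "adverse"\}.
#' @return A tibble with one row per component-outcome edge (columns
#'   \code{component_id}, \code{domain}, \code{outcome_name},
#'   \code{direction}), components without links carrying NA.
#' @export
outcome_tree <- function(final_list, outcome_links) {
  outcome_links <- tibble::as_tibble(outcome_links)
  bad_dir <- !is.na(outcome_links$direction) &
    !outcome_links$direction %in% c("beneficial", "adverse")
  if (any(bad_dir)) {
    stop("outcome direction must be 'beneficial' or 'adverse'", call. = FALSE)
  }
  final_components <- unique(final_list[, c("component_id", "domain")])
  orphan <- setdiff(outcome_links$component_id,
                    final_components$component_id)
  if (length(orphan) > 0) {
    warning("outcome link(s) reference component(s) not in the final list: ",
            paste(orphan, collapse = ", "), call. = FALSE)
    outcome_links <- outcome_links[
      !outcome_links$component_id %in% orphan, ]
  }
  edges <- dplyr::inner_join(final_components, outcome_links,
                             by = "component_id")
  unlinked <- final_components[
    !final_components$component_id %in% edges$component_id, ]
  if (nrow(unlinked) > 0) {
    unlinked$outcome_name <- NA_character_
    unlinked$direction <- NA_character_
    edges <- dplyr::bind_rows(edges, unlinked)
  }
  dplyr::arrange(edges, .data$domain, .data$component_id,
                 .data$outcome_name)
}

#' Render the outcome tree as text
#'
#' A plain-text rendering of the component-to-outcome tree, grouped by
#' domain and component, each outcome labelled \code{[adverse]} or
#' \code{[beneficial]}; components without a mapped outcome are listed in
#' a closing "no outcome mapped" section.
#'
#' @param tree A tibble from [outcome_tree()].
#' @return A character vector of lines, invisibly printable with
#'   \code{cat(..., sep = "\n")}.
#' @export
format_outcome_tree <- function(tree) {
  lines <- character()
  linked <- tree[!is.na(tree$outcome_name), ]
  for (dom in intersect(rba_domains, unique(linked$domain))) {
    lines <- c(lines, paste0(dom, ":"))
    dd <- linked[linked$domain == dom, ]
    for (cid in unique(dd$component_id)) {
      lines <- c(lines, paste0("  ", cid))
      cc <- dd[dd$component_id == cid, ]
      lines <- c(lines, sprintf("    -> %s [%s]", cc$outcome_name,
                                cc$direction))
    }
  }
  unlinked <- tree[is.na(tree$outcome_name), ]
  if (nrow(unlinked) > 0) {
    lines <- c(lines, "no outcome mapped:",
               paste0("  ", unique(unlinked$component_id)))
  }
  lines
}

report_table_casts <- list(
  ledger = c(component_id = "character", food_id = "character",
             domain = "character", stage = "character",
             decision = "character", reason = "character"),
  membership = c(component_id = "character", food_id = "character",
                 domain = "character"),
  tree = c(component_id = "character", domain = "character",
           outcome_name = "character", direction = "character")
)

cast_columns <- function(df, casts) {
  df <- tibble::as_tibble(df)
  for (nm in names(casts)) {
    if (!nm %in% names(df)) {
      df[[nm]] <- vector(casts[[nm]], nrow(df))
      df[[nm]][] <- NA
    }
    df[[nm]] <- methods::as(df[[nm]], casts[[nm]])
  }
  df[, names(casts)]
}

#' Serialize a pipeline run to a JSON report
#'
#' Writes a structured report holding the scenario metadata, the
#' configuration snapshot, the long/short/final list memberships, the
#' ranked scores with their sub-score audit trail, the complete selection
#' ledger, and the outcome tree. The report carries no timestamps, so
#' identical inputs and configuration produce byte-identical files.
#'
#' @param run An \code{rba_run}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_run_report <- function(run, path) {
  membership <- function(df) {
    tibble::tibble(component_id = df$component_id, food_id = df$food_id,
                   domain = df$domain)
  }
  scores <- run$scores
  scores$sub_scores <- purrr::map(scores$sub_scores, as.data.frame)
  final_members <- membership(run$final_list)
  if ("symmetry_added" %in% names(run$final_list)) {
    final_members$symmetry_added <- run$final_list$symmetry_added
  }
  payload <- list(
    scenario_id = run$scenario_id,
    foods = as.list(run$foods),
    config = unclass(run$config),
    long_list = membership(run$long_list),
    evidence_gated = membership(run$evidence_gated),
    short_list = membership(run$short_list),
    final_list = final_members,
    scores = scores,
    ledger = run$ledger,
    outcome_tree = run$outcome_tree,
    outcome_tree_text = format_outcome_tree(run$outcome_tree)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a pipeline report back into tibbles
#'
#' Inverse of [write_run_report()] for the report's tabular parts: list
#' memberships, scores (with sub-score tibbles), ledger, and outcome
#' tree round-trip exactly.
#'
#' @param path Path to a JSON report.
#' @return A list mirroring the report structure, with tibbles for the
#'   tabular members.
#' @export
read_run_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  casts <- report_table_casts
  scores <- tibble::as_tibble(raw$scores)
  if (nrow(scores) > 0) {
    scores$component_id <- as.character(scores$component_id)
    scores$food_id <- as.character(scores$food_id)
    scores$domain <- as.character(scores$domain)
    scores$occurrence_score <- as.integer(scores$occurrence_score)
    scores$severity_score <- as.integer(scores$severity_score)
    scores$index <- as.integer(scores$index)
    scores$rank <- as.integer(scores$rank)
    scores$sub_scores <- purrr::map(scores$sub_scores, function(s) {
      s <- tibble::as_tibble(s)
      s$level <- as.numeric(s$level)
      s
    })
  } else {
    scores <- tibble::tibble(component_id = character(),
                             food_id = character(), domain = character(),
                             occurrence_score = integer(),
                             severity_score = integer(), index = integer(),
                             sub_scores = list(), rank = integer())
  }
  final_list <- tibble::as_tibble(raw$final_list)
  if ("symmetry_added" %in% names(final_list)) {
    sym <- as.logical(final_list$symmetry_added)
    final_list <- cast_columns(final_list, casts$membership)
    final_list$symmetry_added <- sym
  } else {
    final_list <- cast_columns(final_list, casts$membership)
  }
  list(
    scenario_id = raw$scenario_id,
    foods = unlist(raw$foods),
    config = raw$config,
    long_list = cast_columns(raw$long_list, casts$membership),
    evidence_gated = cast_columns(raw$evidence_gated, casts$membership),
    short_list = cast_columns(raw$short_list, casts$membership),
    final_list = final_list,
    scores = scores,
    ledger = cast_columns(raw$ledger, casts$ledger),
    outcome_tree = cast_columns(raw$outcome_tree, casts$tree),
    outcome_tree_text = unlist(raw$outcome_tree_text)
  )
}
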