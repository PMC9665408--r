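#' Default configuration for the component-selection engine
#'
#' Returns the full set of tunable parameters governing the three-tier
#' selection pipeline: the long-list concentration-difference rule, the
#' class-to-level maps and bin edges behind every 1-3 sub-criterion, the
#' occurrence combiners that keep the hazard indices on the printed 1-9
#' scale, and the short-list inclusion thresholds. The defaults are the
#' profile used in the beef-versus-cricket substitution case study.
#'
#' Overrides are supplied as named nested lists and merged recursively, so
#' \code{rba_config(selection = list(thresholds = list(nutrition = 120)))}
#' changes one threshold and keeps everything else.
#'
#' @param ... Named overrides, nested as in the default list. Unknown names
#'   are an error.
#'
#' @return A named list of class \code{rba_config} with elements
#'   \code{longlist}, \code{nutrition}, \code{microbiology},
#'   \code{toxicology}, \code{selection}.
#'
#' @examples
#' cfg <- rba_config()
#' cfg$selection$thresholds$nutrition
#' rba_config(longlist = list(concentration_diff_threshold = 0.25))$longlist
#' @export
rba_config <- function(...) {
  defaults <- list(
    longlist = list(
      # nutrients present in both foods enter the long list only if their
      # relative concentration difference exceeds this (strict >)
      concentration_diff_threshold = 0.20,
      # denominator of the relative difference: "mean" (symmetric),
      # "max", or "reference" (food A)
      diff_denominator = "mean"
    ),
    nutrition = list(
      # sample-detection sub-criterion: level 1 below this fraction,
      # level 3 only when detected in all samples, level 2 otherwise
      presence_low_fraction = 0.10,
      processing_levels = c(
        eliminates = 1L, reduces = 2L,
        neutral = 3L, introduces_or_increases = 3L
      ),
      # layer-1 contribution of the food to population nutrient intake,
      # binned at tertiles: <= cut1 -> 1, <= cut2 -> 2, else 3
      intake_cuts = c(1 / 3, 2 / 3),
      intake_fallback_levels = c(
        small_difference = 1L, moderate_difference = 2L,
        large_difference = 3L
      ),
      bioavailability_levels = c(
        significant = 1L, moderate = 2L, mild_or_none = 3L
      )
    ),
    microbiology = list(
      processing_levels = c(
        eliminates = 1L, reduces = 1L,
        neutral = 2L, introduces_or_increases = 3L
      ),
      prevalence_levels = c(rare = 1L, occasional = 2L, common = 3L),
      # raw prevalence x process product (1,2,3,4,6,9) re-mapped to 1-3 so
      # the final hazard index stays on the printed 1-9 scale
      occurrence_band_map = c(
        `1` = 1L, `2` = 1L, `3` = 2L, `4` = 2L, `6` = 3L, `9` = 3L
      ),
      # DALY per 1,000 cases: <10 -> 1, 10-99 -> 2, 100-1,000 -> 3
      # (closed-left bins; values above the top edge clamp to 3)
      severity_bins = c(10, 100),
      severity_top = 1000
    ),
    toxicology = list(
      # proportion of total dietary exposure: <10% -> 1, 10-50% -> 2, >50% -> 3
      exposure_bins = c(0.10, 0.50),
      # combine the presence and exposure-contribution sub-scores into one
      # 1-3 occurrence criterion; "ceiling_mean" keeps the index in 1-9
      occurrence_combiner = "ceiling_mean",
      # count of true severity statements -> level
      severity_map = c(`0` = 1L, `1` = 1L, `2` = 2L, `3` = 3L, `4` = 3L)
    ),
    selection = list(
      # inclusive thresholds (index >= threshold is short-listed)
      thresholds = list(nutrition = 108L, microbiology = 2L, toxicology = 2L)
    )
  )
  overrides <- list(...)
  if (length(overrides) > 0 &&
      (is.null(names(overrides)) || any(names(overrides) == ""))) {
    stop("configuration overrides must be named", call. = FALSE)
  }
  cfg <- merge_config(defaults, overrides, path = "")
  structure(cfg, class = "rba_config")
}

# recursive merge; override leaves replace default leaves, unknown keys error
merge_config <- function(base, override, path) {
  for (nm in names(override)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base)) {
      stop("unknown configuration key: ", here, call. = FALSE)
    }
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], here)
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a configuration file
#'
#' Reads a YAML configuration file and merges it over the defaults of
#' [rba_config()]. Keys follow the same nesting, e.g.
#' \code{selection: thresholds: nutrition: 108}.
#'
#' @param path Path to a YAML file.
#' @return An \code{rba_config} list.
#' @export
read_rba_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(rba_config, raw)
}

as_rba_config <- function(config) {
  if (is.null(config)) return(rba_config())
  if (inherits(config, "rba_config")) return(config)
  if (is.list(config)) return(do.call(rba_config, config))
  stop("`config` must be NULL, an rba_config, or a named list", call. = FALSE)
}

#' @export
print.rba_config <- function(x, ...) {
  cat("<rba_config>\n")
  cat("  longlist: diff threshold", x$longlist$concentration_diff_threshold,
      "(denominator:", paste0(x$longlist$diff_denominator, ")\n"))
  thr <- x$selection$thresholds
  cat("  shortlist thresholds: nutrition", thr$nutrition,
      "| microbiology", thr$microbiology,
      "| toxicology", thr$toxicology, "\n")
  invisible(x)
}
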