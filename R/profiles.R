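#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom generics tidy glance
NULL

# enumerations shared across the engine
rba_domains <- c("nutrition", "microbiology", "toxicology")
rba_evidence_levels <- c("convincing", "limited", "contradictory")
rba_processing_effects <- c(
  "introduces_or_increases", "neutral", "reduces", "eliminates"
)
rba_scopes <- c("none", "some_countries", "all_countries")
rba_stage_levels <- c("longlist", "evidence_gate", "shortlist", "finallist")

# every column a profile table may carry, with its prototype
profile_prototype <- function() {
  tibble::tibble(
    component_id = character(), component_name = character(),
    food_id = character(), domain = character(),
    concentration = double(), unit = character(),
    sample_detection_fraction = double(), detection_source = character(),
    prevalence_fraction = double(),
    processing_effect = character(), evidence_level = character(),
    fbdg_scope = character(), fortification_scope = character(),
    intake_contribution = double(), intake_fallback_class = character(),
    bioavailability_reduction = character(),
    prevalence_class = character(), daly_per_1000_cases = double(),
    above_lod_loq = logical(), genotoxic_carcinogen = logical(),
    exceeds_hbgv = logical(), moe_below_10000 = logical(),
    exposure_share_of_diet = double(),
    sev_high_incidence = logical(), sev_fatal = logical(),
    sev_lifelong_disability = logical(), sev_high_disability = logical(),
    synthesized = logical()
  )
}

#' Coerce a data frame to the component-profile schema
#'
#' Fills absent optional columns with NA and checks required columns.
#' One row describes one candidate component in one food.
#'
#' @param x A data frame with at least \code{component_id}, \code{food_id},
#'   \code{domain}, \code{evidence_level}.
#' @return A tibble with the full profile column set.
#' @export
as_profiles <- function(x) {
  x <- tibble::as_tibble(x)
  required <- c("component_id", "food_id", "domain", "evidence_level")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("profile table lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  proto <- profile_prototype()
  extra <- setdiff(names(x), names(proto))
  if (length(extra) > 0) {
    stop("unknown profile column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  for (nm in setdiff(names(proto), names(x))) {
    x[[nm]] <- proto[[nm]][rep(NA_integer_, nrow(x))]
  }
  x[, names(proto)]
}

#' Read component profiles from a delimited file
#'
#' Reads a comma-separated UTF-8 table with a header row, one row per
#' component-by-food, into the profile schema. Rows that cannot be typed
#' (unknown domain tag, duplicated component-food key, concentration-unit
#' mismatch between the two foods for the same component) are dropped and
#' collected into a rejection report rather than raising, so one bad row
#' does not block a load.
#'
#' A \code{daly_per_case} column, if present instead of
#' \code{daly_per_1000_cases}, is converted (multiplied by 1,000) on load.
#'
#' @param path Path to a CSV file.
#' @return A profile tibble; rejected rows (with their file row numbers and
#'   a named reason) are attached as attribute \code{"rejected"} and
#'   retrievable with [profile_problems()].
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0) {
    out <- as_profiles(raw[intersect(names(raw), names(profile_prototype()))])
    attr(out, "rejected") <- rejection_prototype()
    return(out)
  }
  if ("daly_per_case" %in% names(raw) &&
      !"daly_per_1000_cases" %in% names(raw)) {
    raw$daly_per_1000_cases <- raw$daly_per_case * 1000
    raw$daly_per_case <- NULL
  }
  raw$.row <- seq_len(nrow(raw)) + 1L # header is line 1

  rejected <- rejection_prototype()
  reject <- function(rows, reason) {
    rejected <<- dplyr::bind_rows(rejected, tibble::tibble(
      row = rows$.row, component_id = as.character(rows$component_id),
      food_id = as.character(rows$food_id), reason = reason
    ))
  }

  bad_domain <- !raw$domain %in% rba_domains
  if (any(bad_domain)) {
    reject(raw[bad_domain, ],
           paste0("unknown domain tag: ", raw$domain[bad_domain]))
    raw <- raw[!bad_domain, ]
  }
  dup <- duplicated(raw[, c("component_id", "food_id")])
  if (any(dup)) {
    reject(raw[dup, ], "duplicate (component_id, food_id) key")
    raw <- raw[!dup, ]
  }
  if ("unit" %in% names(raw)) {
    units <- stats::aggregate(
      unit ~ component_id, data = raw[!is.na(raw$unit), c("component_id", "unit")],
      FUN = function(u) length(unique(u))
    )
    clash <- units$component_id[units$unit > 1]
    if (length(clash) > 0) {
      bad <- raw$component_id %in% clash
      reject(raw[bad, ], "concentration unit differs between foods")
      raw <- raw[!bad, ]
    }
  }
  raw$.row <- NULL
  out <- as_profiles(raw)
  attr(out, "rejected") <- rejected
  out
}

rejection_prototype <- function() {
  tibble::tibble(row = integer(), component_id = character(),
                 food_id = character(), reason = character())
}

#' Rows rejected during a profile load
#'
#' @param profiles A tibble returned by [read_profiles()].
#' @return A tibble of rejected rows (file row number, keys, reason).
#' @export
profile_problems <- function(profiles) {
  rej <- attr(profiles, "rejected")
  if (is.null(rej)) rejection_prototype() else rej
}

#' Validate component profiles against their domain's scoring requirements
#'
#' Checks each profile row for the attributes its domain scorer needs:
#' detection fraction, processing effect, policy scopes, intake information
#' and bioavailability class for nutrients; prevalence class, processing
#' effect and DALY burden for microbiological hazards; detection and
#' reference-dose flags, exposure share and the four severity statements
#' for chemical hazards. Findings are data, not exceptions: an empty result
#' means the table is ready to score.
#'
#' @param profiles A profile tibble (see [as_profiles()]).
#' @return A tibble of findings with columns \code{component_id},
#'   \code{food_id}, \code{field}, \code{message}; zero rows when valid.
#' @export
validate_profiles <- function(profiles) {
  profiles <- as_profiles(profiles)
  findings <- list()
  flag <- function(rows, field, message) {
    if (!any(rows)) return()
    findings[[length(findings) + 1]] <<- tibble::tibble(
      component_id = profiles$component_id[rows],
      food_id = profiles$food_id[rows],
      field = field, message = message
    )
  }
  in_01 <- function(x) !is.na(x) & (x < 0 | x > 1)
  flag(in_01(profiles$prevalence_fraction), "prevalence_fraction",
       "must lie in [0, 1]")
  flag(in_01(profiles$sample_detection_fraction), "sample_detection_fraction",
       "must lie in [0, 1]")
  flag(!is.na(profiles$concentration) & profiles$concentration < 0,
       "concentration", "must be non-negative")
  flag(!profiles$evidence_level %in% rba_evidence_levels, "evidence_level",
       paste("must be one of:", paste(rba_evidence_levels, collapse = ", ")))
  flag(!is.na(profiles$processing_effect) &
         !profiles$processing_effect %in% rba_processing_effects,
       "processing_effect",
       paste("must be one of:", paste(rba_processing_effects, collapse = ", ")))

  nut <- profiles$domain == "nutrition"
  flag(nut & is.na(profiles$sample_detection_fraction),
       "sample_detection_fraction", "required for nutrition scoring")
  flag(nut & is.na(profiles$processing_effect), "processing_effect",
       "required for nutrition scoring")
  flag(nut & (is.na(profiles$fbdg_scope) |
                !profiles$fbdg_scope %in% rba_scopes), "fbdg_scope",
       "required for nutrition scoring (none/some_countries/all_countries)")
  flag(nut & (is.na(profiles$fortification_scope) |
                !profiles$fortification_scope %in% rba_scopes),
       "fortification_scope",
       "required for nutrition scoring (none/some_countries/all_countries)")
  flag(nut & is.na(profiles$intake_contribution) &
         is.na(profiles$intake_fallback_class), "intake_contribution",
       "layer-1 contribution or layer-2 composition-difference class required")
  flag(nut & is.na(profiles$bioavailability_reduction),
       "bioavailability_reduction", "required for nutrition scoring")

  mic <- profiles$domain == "microbiology"
  flag(mic & is.na(profiles$prevalence_class), "prevalence_class",
       "required for microbiology scoring")
  flag(mic & is.na(profiles$processing_effect), "processing_effect",
       "required for microbiology scoring")
  flag(mic & is.na(profiles$daly_per_1000_cases), "daly_per_1000_cases",
       "required for microbiology scoring (DALY per 1,000 cases)")
  flag(mic & !is.na(profiles$daly_per_1000_cases) &
         profiles$daly_per_1000_cases < 0, "daly_per_1000_cases",
       "must be non-negative")

  tox <- profiles$domain == "toxicology"
  flag(tox & is.na(profiles$above_lod_loq), "above_lod_loq",
       "required for toxicology scoring")
  above <- tox & !is.na(profiles$above_lod_loq) & profiles$above_lod_loq
  flag(above & is.na(profiles$genotoxic_carcinogen), "genotoxic_carcinogen",
       "required when the agent is above LOD/LOQ")
  geno <- above & !is.na(profiles$genotoxic_carcinogen) &
    profiles$genotoxic_carcinogen
  nongeno <- above & !is.na(profiles$genotoxic_carcinogen) &
    !profiles$genotoxic_carcinogen
  flag(geno & is.na(profiles$moe_below_10000), "moe_below_10000",
       "margin-of-exposure flag required for genotoxic carcinogens")
  flag(nongeno & is.na(profiles$exceeds_hbgv), "exceeds_hbgv",
       "HBGV-exceedance flag required for non-genotoxic agents")
  flag(tox & is.na(profiles$exposure_share_of_diet), "exposure_share_of_diet",
       "required for toxicology scoring")
  flag(tox & in_01(profiles$exposure_share_of_diet), "exposure_share_of_diet",
       "must lie in [0, 1]")
  for (st in c("sev_high_incidence", "sev_fatal", "sev_lifelong_disability",
               "sev_high_disability")) {
    flag(tox & is.na(profiles[[st]]), st,
         "severity statement must be TRUE or FALSE")
  }

  if (length(findings) == 0) {
    tibble::tibble(component_id = character(), food_id = character(),
                   field = character(), message = character())
  } else {
    dplyr::bind_rows(findings)
  }
}
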