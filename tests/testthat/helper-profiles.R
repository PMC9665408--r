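# in-code builders for single-row profiles; override any field via ...
nutrition_profile <- function(component_id = "iron", food_id = "food_a", ...) {
  base <- tibble::tibble(
    component_id = component_id, food_id = food_id, domain = "nutrition",
    concentration = 100, unit = "mg_per_100g",
    sample_detection_fraction = 1, processing_effect = "neutral",
    evidence_level = "convincing", fbdg_scope = "all_countries",
    fortification_scope = "none", intake_contribution = 0.8,
    bioavailability_reduction = "moderate"
  )
  modify_row(base, ...)
}

micro_profile <- function(component_id = "salmonella", food_id = "food_a",
                          ...) {
  base <- tibble::tibble(
    component_id = component_id, food_id = food_id, domain = "microbiology",
    prevalence_class = "common", processing_effect = "neutral",
    daly_per_1000_cases = 50, evidence_level = "convincing"
  )
  modify_row(base, ...)
}

tox_profile <- function(component_id = "cadmium", food_id = "food_a", ...) {
  base <- tibble::tibble(
    component_id = component_id, food_id = food_id, domain = "toxicology",
    above_lod_loq = TRUE, genotoxic_carcinogen = FALSE, exceeds_hbgv = TRUE,
    moe_below_10000 = NA, exposure_share_of_diet = 0.3,
    sev_high_incidence = FALSE, sev_fatal = TRUE,
    sev_lifelong_disability = TRUE, sev_high_disability = FALSE,
    evidence_level = "convincing"
  )
  modify_row(base, ...)
}

modify_row <- function(base, ...) {
  dots <- list(...)
  for (nm in names(dots)) base[[nm]] <- dots[[nm]]
  as_profiles(base)
}

full_checklist <- function(profiles, ...) {
  dots <- list(...)
  out <- unique(profiles[, c("component_id", "food_id")])
  for (flag in c("has_dose_response", "has_incidence",
                 "has_source_attribution", "has_intake_data",
                 "has_composition_or_contamination", "has_daly_per_case")) {
    out[[flag]] <- TRUE
  }
  for (nm in names(dots)) out[[nm]] <- dots[[nm]]
  out
}

empty_profiles <- function() {
  as_profiles(tibble::tibble(component_id = character(),
                             food_id = character(), domain = character(),
                             evidence_level = character()))
}

run_key <- function(d) sort(paste(d$component_id, d$food_id))
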