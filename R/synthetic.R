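#' Specification for the synthetic-profile generator
#'
#' Describes a seeded synthetic substitution scenario: how many candidate
#' components to draw per domain, the probability of each 1-3 level for
#' every sub-criterion, the evidence-level mix, how often a nutrient is
#' present in only one food or fails the concentration-difference rule,
#' and how often each checklist item is missing. The defaults emulate the
#' magnitudes of the beef-versus-cricket study: about forty nutrition
#' candidates and a dozen hazards per domain, a mostly convincing
#' evidence base, and occasional data gaps.
#'
#' @param seed Integer seed fixing all randomness of the draw.
#' @param n_nutrition,n_microbiology,n_toxicology Number of candidate
#'   components per domain.
#' @param nutrition_probs Named list of 3-vectors (levels 1-3) for
#'   \code{presence}, \code{processing}, \code{policy}, \code{intake},
#'   \code{bioavailability}.
#' @param micro_probs Named list of 3-vectors for \code{prevalence},
#'   \code{process}, \code{severity}.
#' @param tox_probs Named list of 3-vectors for \code{presence},
#'   \code{exposure}, \code{severity}.
#' @param evidence_probs Probabilities of
#'   \code{c(convincing, limited, contradictory)}.
#' @param p_single_food Probability that a nutrient is quantified in one
#'   food only.
#' @param p_below_threshold Probability that a both-food nutrient pair
#'   fails the 20% concentration-difference rule.
#' @param p_both_foods_hazard Probability that a hazard is reported for
#'   both foods rather than one.
#' @param checklist_missing_prob Probability that any one applicable
#'   checklist item is missing for a component.
#' @return A list of class \code{rba_synthetic_spec}.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_nutrition = 40L, n_microbiology = 14L,
                           n_toxicology = 12L,
                           nutrition_probs = NULL, micro_probs = NULL,
                           tox_probs = NULL,
                           evidence_probs = c(0.85, 0.10, 0.05),
                           p_single_food = 0.15,
                           p_below_threshold = 0.20,
                           p_both_foods_hazard = 0.40,
                           checklist_missing_prob = 0.15) {
  u <- rep(1 / 3, 3)
  fill <- function(x, names3) {
    if (is.null(x)) x <- list()
    for (nm in names3) if (is.null(x[[nm]])) x[[nm]] <- u
    x[names3]
  }
  spec <- list(
    seed = as.integer(seed),
    n = c(nutrition = as.integer(n_nutrition),
          microbiology = as.integer(n_microbiology),
          toxicology = as.integer(n_toxicology)),
    nutrition_probs = fill(nutrition_probs,
      c("presence", "processing", "policy", "intake", "bioavailability")),
    micro_probs = fill(micro_probs, c("prevalence", "process", "severity")),
    tox_probs = fill(tox_probs, c("presence", "exposure", "severity")),
    evidence_probs = evidence_probs,
    p_single_food = p_single_food,
    p_below_threshold = p_below_threshold,
    p_both_foods_hazard = p_both_foods_hazard,
    checklist_missing_prob = checklist_missing_prob
  )
  for (pv in c(spec$nutrition_probs, spec$micro_probs, spec$tox_probs,
               list(spec$evidence_probs))) {
    if (length(pv) != 3 || any(pv < 0) || abs(sum(pv) - 1) > 1e-8) {
      stop("level-probability vectors must be length 3, non-negative, ",
           "and sum to 1", call. = FALSE)
    }
  }
  for (p in c(spec$p_single_food, spec$p_below_threshold,
              spec$p_both_foods_hazard, spec$checklist_missing_prob)) {
    if (is.na(p) || p < 0 || p > 1) {
      stop("probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(spec, class = "rba_synthetic_spec")
}

#' Generate seeded synthetic profiles with ground truth
#'
#' Draws component profiles for a two-food substitution scenario from the
#' level distributions of a [synthetic_spec()], together with a matching
#' checklist and the ground-truth indices and stage decisions computed by
#' an independent straight-line oracle that shares no code with the
#' selection engine. Repeated calls with the same spec are identical.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with \code{profiles}, \code{checklist}, and
#'   \code{truth}; \code{truth$rows} holds per-profile-row stage
#'   decisions and scores (\code{index} is NA for rows excluded before
#'   scoring), and \code{truth$final} the final-list membership including
#'   symmetry-added nutrient candidates.
#' @examples
#' out <- generate_profiles(synthetic_spec(seed = 7, n_nutrition = 5,
#'                                         n_microbiology = 3,
#'                                         n_toxicology = 3))
#' out$truth$rows
#' @export
generate_profiles <- function(spec) {
  stopifnot(inherits(spec, "rba_synthetic_spec"))
  set.seed(spec$seed)
  foods <- c("food_a", "food_b")
  draw_level <- function(probs) sample(1:3, 1, prob = probs)
  evidence <- function() sample(rba_evidence_levels, 1,
                                prob = spec$evidence_probs)

  rows <- list()
  add_row <- function(r) rows[[length(rows) + 1]] <<- r

  # nutrition: draw per component (presence pattern), per-food attributes
  np <- spec$nutrition_probs
  for (i in seq_len(spec$n["nutrition"])) {
    cid <- sprintf("nut_%03d", i)
    single <- stats::runif(1) < spec$p_single_food
    in_foods <- if (single) sample(foods, 1) else foods
    conc <- if (single) {
      stats::runif(1, 10, 500)
    } else {
      a <- stats::runif(1, 10, 500)
      u <- if (stats::runif(1) < spec$p_below_threshold) {
        stats::runif(1, 0, 0.22)    # relative diff |u|/(1+u/2) stays <= 20%
      } else {
        stats::runif(1, 0.3, 1.5)   # comfortably above the 20% rule
      }
      c(a, a * (1 + u))
    }
    ev <- evidence()
    for (j in seq_along(in_foods)) {
      lv <- c(presence = draw_level(np$presence),
              processing = draw_level(np$processing),
              policy = draw_level(np$policy),
              intake = draw_level(np$intake),
              bioavailability = draw_level(np$bioavailability))
      add_row(tibble::tibble(
        component_id = cid, food_id = in_foods[j], domain = "nutrition",
        concentration = conc[j], unit = "mg_per_100g",
        sample_detection_fraction = switch(lv[["presence"]],
          stats::runif(1, 0, 0.0999), stats::runif(1, 0.1, 0.999), 1),
        processing_effect = switch(lv[["processing"]],
          "eliminates", "reduces",
          sample(c("neutral", "introduces_or_increases"), 1)),
        evidence_level = ev,
        fbdg_scope = switch(lv[["policy"]],
          "none", "some_countries", "all_countries"),
        fortification_scope = "none",
        intake_contribution = switch(lv[["intake"]],
          stats::runif(1, 0, 1 / 3 - 1e-6),
          stats::runif(1, 1 / 3 + 1e-6, 2 / 3 - 1e-6),
          stats::runif(1, 2 / 3 + 1e-6, 1)),
        bioavailability_reduction = switch(lv[["bioavailability"]],
          "significant", "moderate", "mild_or_none"),
        synthesized = TRUE
      ))
    }
  }

  mp <- spec$micro_probs
  for (i in seq_len(spec$n["microbiology"])) {
    cid <- sprintf("mic_%03d", i)
    in_foods <- if (stats::runif(1) < spec$p_both_foods_hazard) foods else
      sample(foods, 1)
    ev <- evidence()
    for (f in in_foods) {
      add_row(tibble::tibble(
        component_id = cid, food_id = f, domain = "microbiology",
        prevalence_class = switch(draw_level(mp$prevalence),
          "rare", "occasional", "common"),
        processing_effect = switch(draw_level(mp$process),
          sample(c("reduces", "eliminates"), 1), "neutral",
          "introduces_or_increases"),
        daly_per_1000_cases = switch(draw_level(mp$severity),
          stats::runif(1, 0, 9.999), stats::runif(1, 10, 99.9),
          stats::runif(1, 100, 1000)),
        evidence_level = ev, synthesized = TRUE
      ))
    }
  }

  tp <- spec$tox_probs
  for (i in seq_len(spec$n["toxicology"])) {
    cid <- sprintf("tox_%03d", i)
    in_foods <- if (stats::runif(1) < spec$p_both_foods_hazard) foods else
      sample(foods, 1)
    ev <- evidence()
    for (f in in_foods) {
      plev <- draw_level(tp$presence)
      geno <- if (plev == 1) NA else stats::runif(1) < 0.5
      k <- switch(draw_level(tp$severity),
                  sample(0:1, 1), 2L, sample(3:4, 1))
      statements <- rep(FALSE, 4)
      if (k > 0) statements[sample(4, k)] <- TRUE
      add_row(tibble::tibble(
        component_id = cid, food_id = f, domain = "toxicology",
        above_lod_loq = plev > 1,
        genotoxic_carcinogen = geno,
        exceeds_hbgv = if (isFALSE(geno)) plev == 3 else NA,
        moe_below_10000 = if (isTRUE(geno)) plev == 3 else NA,
        exposure_share_of_diet = switch(draw_level(tp$exposure),
          stats::runif(1, 0, 0.0999), stats::runif(1, 0.1, 0.5),
          stats::runif(1, 0.5 + 1e-6, 1)),
        sev_high_incidence = statements[1], sev_fatal = statements[2],
        sev_lifelong_disability = statements[3],
        sev_high_disability = statements[4],
        evidence_level = ev, synthesized = TRUE
      ))
    }
  }

  profiles <- as_profiles(dplyr::bind_rows(rows))
  checklist <- profiles[, c("component_id", "food_id", "domain")]
  miss <- function(n) stats::runif(n) < spec$checklist_missing_prob
  n <- nrow(checklist)
  checklist$has_dose_response <- !miss(n)
  checklist$has_incidence <- !miss(n)
  checklist$has_source_attribution <- ifelse(
    checklist$domain == "microbiology", !miss(n), TRUE)
  checklist$has_intake_data <- !miss(n)
  checklist$has_composition_or_contamination <- !miss(n)
  checklist$has_daly_per_case <- !miss(n)
  # symmetry-added nutrient candidates need a status for the other food too
  nut <- checklist[checklist$domain == "nutrition", ]
  extra <- dplyr::anti_join(
    tidyr::expand_grid(component_id = unique(nut$component_id),
                       food_id = foods),
    nut[, c("component_id", "food_id")],
    by = c("component_id", "food_id"))
  if (nrow(extra) > 0) {
    m <- nrow(extra)
    extra$domain <- "nutrition"
    extra$has_dose_response <- !miss(m)
    extra$has_incidence <- !miss(m)
    extra$has_source_attribution <- TRUE
    extra$has_intake_data <- !miss(m)
    extra$has_composition_or_contamination <- !miss(m)
    extra$has_daly_per_case <- !miss(m)
    checklist <- dplyr::bind_rows(checklist, extra)
  }
  checklist$domain <- NULL

  truth <- oracle_truth(profiles, checklist, foods)
  list(profiles = profiles, checklist = checklist, truth = truth)
}

# ---------------------------------------------------------------------------
# Independent straight-line oracle. Recomputes every level, index, and stage
# decision directly from the raw attributes with hard-coded rules and plain
# loops; shares no code or configuration with the engine it validates.
oracle_truth <- function(profiles, checklist, foods) {
  n <- nrow(profiles)
  in_longlist <- logical(n)
  occ <- rep(NA_integer_, n)
  sev <- rep(NA_integer_, n)
  index <- rep(NA_integer_, n)

  for (i in seq_len(n)) {
    p <- profiles[i, ]
    if (p$domain == "nutrition") {
      mate <- which(profiles$component_id == p$component_id &
                      profiles$food_id != p$food_id)
      if (length(mate) == 0) {
        in_longlist[i] <- TRUE
      } else {
        ca <- p$concentration
        cb <- profiles$concentration[mate[1]]
        if (is.na(ca) || is.na(cb)) {
          in_longlist[i] <- TRUE
        } else if (ca == 0 && cb == 0) {
          in_longlist[i] <- FALSE
        } else {
          in_longlist[i] <- (abs(ca - cb) / ((ca + cb) / 2)) > 0.20
        }
      }
    } else {
      in_longlist[i] <- TRUE
    }
  }
  in_evidence <- in_longlist & profiles$evidence_level == "convincing"

  for (i in which(in_evidence)) {
    p <- profiles[i, ]
    if (p$domain == "nutrition") {
      f <- p$sample_detection_fraction
      l1 <- if (f < 0.10) 1 else if (f >= 1) 3 else 2
      l2 <- switch(p$processing_effect, eliminates = 1, reduces = 2,
                   neutral = 3, introduces_or_increases = 3)
      l3 <- if (p$fbdg_scope == "none" && p$fortification_scope == "none") {
        1
      } else if (p$fbdg_scope == "all_countries" ||
                 p$fortification_scope == "all_countries") {
        3
      } else {
        2
      }
      ic <- p$intake_contribution
      l4 <- if (!is.na(ic)) {
        if (ic > 2 / 3) 3 else if (ic > 1 / 3) 2 else 1
      } else {
        switch(p$intake_fallback_class, small_difference = 1,
               moderate_difference = 2, large_difference = 3)
      }
      l5 <- switch(p$bioavailability_reduction, significant = 1,
                   moderate = 2, mild_or_none = 3)
      occ[i] <- l1 * l2
      sev[i] <- l3 * l4 * l5
    } else if (p$domain == "microbiology") {
      l1 <- switch(p$prevalence_class, rare = 1, occasional = 2, common = 3)
      l2 <- switch(p$processing_effect, eliminates = 1, reduces = 1,
                   neutral = 2, introduces_or_increases = 3)
      raw <- l1 * l2
      occ[i] <- if (raw <= 2) 1 else if (raw <= 4) 2 else 3
      d <- p$daly_per_1000_cases
      sev[i] <- if (d >= 100) 3 else if (d >= 10) 2 else 1
    } else {
      if (!p$above_lod_loq) {
        s1 <- 1
      } else {
        hit <- if (p$genotoxic_carcinogen) p$moe_below_10000 else
          p$exceeds_hbgv
        s1 <- if (hit) 3 else 2
      }
      x <- p$exposure_share_of_diet
      s2 <- if (x > 0.5) 3 else if (x >= 0.1) 2 else 1
      occ[i] <- ceiling((s1 + s2) / 2)
      k <- sum(c(p$sev_high_incidence, p$sev_fatal,
                 p$sev_lifelong_disability, p$sev_high_disability))
      sev[i] <- if (k >= 3) 3 else if (k == 2) 2 else 1
    }
    index[i] <- occ[i] * sev[i]
  }

  threshold <- c(nutrition = 108, microbiology = 2, toxicology = 2)
  in_shortlist <- !is.na(index) &
    index >= unname(threshold[profiles$domain])

  rows <- tibble::tibble(
    component_id = profiles$component_id, food_id = profiles$food_id,
    domain = profiles$domain, in_longlist = in_longlist,
    in_evidence = in_evidence, occurrence_score = as.integer(occ),
    severity_score = as.integer(sev), index = as.integer(index),
    in_shortlist = in_shortlist
  )

  # final-list candidates: short-listed rows, plus the mirror food for any
  # nutrient short-listed in exactly one food
  cand <- rows[rows$in_shortlist,
               c("component_id", "food_id", "domain")]
  cand$symmetry_added <- FALSE
  nut <- cand[cand$domain == "nutrition", ]
  for (cid in unique(nut$component_id)) {
    have <- nut$food_id[nut$component_id == cid]
    if (length(have) == 1) {
      cand <- rbind(cand, data.frame(
        component_id = cid, food_id = setdiff(foods, have),
        domain = "nutrition", symmetry_added = TRUE))
    }
  }
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    st <- checklist[checklist$component_id == cand$component_id[i] &
                      checklist$food_id == cand$food_id[i], ]
    stopifnot(nrow(st) == 1)
    ok <- st$has_dose_response && st$has_incidence && st$has_intake_data &&
      st$has_composition_or_contamination && st$has_daly_per_case
    if (cand$domain[i] == "microbiology") {
      ok <- ok && st$has_source_attribution
    }
    keep[i] <- ok
  }
  final <- tibble::as_tibble(cand[keep, ])
  list(rows = rows, final = final)
}

#' Closed-form distribution of the prioritization index
#'
#' Enumerates every combination of sub-criterion levels with the level
#' probabilities of a synthetic spec and accumulates the probability mass
#' of each attainable index value (243 combinations for nutrition, 27 for
#' each hazard domain). Computed by direct enumeration with the default
#' combination rules hard-coded, independently of the scoring engine, so
#' it can serve as the reference for the empirical short-list inclusion
#' rate of generated components.
#'
#' @param domain One of \code{"nutrition"}, \code{"microbiology"},
#'   \code{"toxicology"}.
#' @param probs Named list of 3-vectors of level probabilities, as in
#'   [synthetic_spec()] for that domain.
#' @return A tibble with \code{index} and \code{prob}, summing to 1.
#' @examples
#' d <- index_distribution("nutrition", list(
#'   presence = rep(1/3, 3), processing = rep(1/3, 3),
#'   policy = rep(1/3, 3), intake = rep(1/3, 3),
#'   bioavailability = rep(1/3, 3)))
#' sum(d$prob[d$index >= 108]) # P(short-listed)
#' @export
index_distribution <- function(domain = c("nutrition", "microbiology",
                                          "toxicology"), probs) {
  domain <- match.arg(domain)
  acc <- new.env()
  add <- function(idx, p) {
    key <- as.character(idx)
    acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + p
  }
  if (domain == "nutrition") {
    for (a in 1:3) for (b in 1:3) for (c in 1:3) for (d in 1:3) for (e in 1:3) {
      add(a * b * c * d * e,
          probs$presence[a] * probs$processing[b] * probs$policy[c] *
            probs$intake[d] * probs$bioavailability[e])
    }
  } else if (domain == "microbiology") {
    for (a in 1:3) for (b in 1:3) for (s in 1:3) {
      raw <- a * b
      occ <- if (raw <= 2) 1 else if (raw <= 4) 2 else 3
      add(occ * s, probs$prevalence[a] * probs$process[b] * probs$severity[s])
    }
  } else {
    for (a in 1:3) for (b in 1:3) for (s in 1:3) {
      occ <- ceiling((a + b) / 2)
      add(occ * s, probs$presence[a] * probs$exposure[b] * probs$severity[s])
    }
  }
  idx <- sort(as.integer(ls(acc)))
  tibble::tibble(index = idx,
                 prob = vapply(as.character(idx), function(k) acc[[k]],
                               numeric(1), USE.NAMES = FALSE))
}
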