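AGE_CLASSES <- c("young", "mid", "old")  # <45, 45-60, >60
OWNER_ELEMENT_CLASSES <- c(FARMER_TYPES, "resident")

age_class <- function(age) {
  fifelse(age < 45, "young", fifelse(age <= 60, "mid", "old"))
}

# Neutral (scenario-free) parameter tables. Scenario files are patches over
# this base; all values are calibration defaults (the behavioural directions
# come from the policy narratives, the magnitudes from calibration against
# the 2005/2030 indicator table).
scenario_base <- function() {
  list(
    name = "base",
    cessation = list(
      base = list(
        expansionist = c(young = 0.0005, mid = 0.0005, old = 0.0010),
        conventional = c(young = 0.0010, mid = 0.0015, old = 0.0020),
        diversified_multifunctional = c(young = 0.0030, mid = 0.0040, old = 0.0050),
        hobby = c(young = 0.0040, mid = 0.0040, old = 0.0040)),
      scenario_mult = 1.0,
      small_farm_subsidy = 1.0,       # multiplier on cessation when dsu < 10
      low_productivity_mult = 1.0,    # multiplier when farm mean productivity low
      low_productivity_threshold = 0.35,
      leader_diversified_mult = 1.0), # cessation multiplier for diversified in LEADER zones
    retirement = list(
      hazard = 0.094,                  # annual retirement prob once past personal retirement age
      age_shift = 0,                  # years added to personal retirement ages
      succession = c(expansionist = 0.933, conventional = 0.7245,
                     diversified_multifunctional = 0.104, hobby = 0.19),
      successor_age_mean = 36, successor_age_sd = 6),
    expansion = list(
      propensity = c(expansionist = 1.0, conventional = 0.30,
                     diversified_multifunctional = 0.15, hobby = 0),
      participation = c(expansionist = 0.35, conventional = 0.10,
                        diversified_multifunctional = 0.05, hobby = 0),
      participation_mult = 1.0,
      propensity_mult = 1.0,          # applied to expansionists (flat-rate cap lever)
      capacity = 6L,                  # parcels a farm can buy per year
      radius_m = 15000,
      proximity_scale_m = 3000,
      productivity_floor = 0.0,       # no bids on parcels below this score
      zone_mult = c(agri_development = 1.0, habitat_directive = 1.0,
                    landscape_protection = 1.0)),
    contraction = c(expansionist = 0.02, conventional = 0.02,
                    diversified_multifunctional = 0.02, hobby = 0.02),
    market = list(
      p_estate = 0.25,
      estate_aesthetic_min = 0.75,
      estate_max_ha = 2,
      p_nature = c(habitat_directive = 0.0, landscape_protection = 0.0),
      dsu_per_ha = 1.1),
    elements = list(
      base = list(
        expansionist = c(cut = 0.030, keep = 0.935, plant = 0.035),
        conventional = c(cut = 0.020, keep = 0.945, plant = 0.035),
        diversified_multifunctional = c(cut = 0.010, keep = 0.945, plant = 0.045),
        hobby = c(cut = 0.010, keep = 0.955, plant = 0.035),
        resident = c(cut = 0.010, keep = 0.940, plant = 0.050)),
      protect_cut_mult = 1.0,         # cut multiplier inside protection/habitat zones
      protect_plant_mult = 1.0,       # plant multiplier inside protection/habitat zones
      stewardship_plant_bonus = 0.005,  # spontaneous nature stewardship in habitat zones
      cut_fraction = 0.5,
      plant_increment_m_ha = 50),
    tourism = list(
      gain = 0.0,
      weights = c(elements = 0.6, semi_natural = 0.3, attractions = 0.1))
  )
}

deep_merge <- function(base, patch) {
  for (nm in names(patch)) {
    if (is.list(patch[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(patch[[nm]]))) {
      base[[nm]] <- deep_merge(base[[nm]], patch[[nm]])
    } else if (is.null(names(base[[nm]])) || is.list(base[[nm]]) ||
               is.null(base[[nm]])) {
      base[[nm]] <- patch[[nm]]
    } else {
      # named atomic vector: element-wise override
      v <- base[[nm]]
      pv <- unlist(patch[[nm]])
      v[names(pv)] <- pv
      base[[nm]] <- v
    }
  }
  base
}

yamlify_scenario <- function(raw) {
  # yaml reads named vectors as lists; flatten the leaves we store as vectors
  flat <- function(x) if (is.list(x)) unlist(x) else x
  for (p in list(c("cessation", "base"), c("elements", "base"))) {
    node <- raw[[p[1]]][[p[2]]]
    if (!is.null(node)) raw[[p[1]]][[p[2]]] <- lapply(node, flat)
  }
  for (p in list(c("retirement", "succession"), c("expansion", "propensity"),
                 c("expansion", "participation"), c("expansion", "zone_mult"),
                 c("market", "p_nature"), c("tourism", "weights"))) {
    node <- raw[[p[1]]][[p[2]]]
    if (!is.null(node)) raw[[p[1]]][[p[2]]] <- flat(node)
  }
  if (!is.null(raw$contraction)) raw$contraction <- flat(raw$contraction)
  raw
}

#' Load a policy scenario
#'
#' Returns the fully populated, validated parameter set of a policy future.
#' `"BTS"` (balanced, targeted and sustainable support) and `"AMIS"`
#' (abolition of market and income support) load the shipped presets; a file
#' path loads a user scenario. Scenario files are YAML patches over the
#' neutral base tables, so a custom scenario only needs to state what it
#' changes.
#'
#' @param name_or_path `"BTS"`, `"AMIS"` or the path of a YAML scenario file.
#' @return A validated list of class `scenario_params`.
#' @examples
#' bts <- load_scenario("BTS")
#' bts$cessation$small_farm_subsidy   # < 1: small-farm subsidy lowers cessation
#' @export
load_scenario <- function(name_or_path) {
  path <- if (toupper(name_or_path) %in% c("BTS", "AMIS")) {
    system.file("extdata", "scenarios",
                paste0(tolower(name_or_path), ".yaml"),
                package = "coulisse", mustWork = TRUE)
  } else {
    if (!file.exists(name_or_path))
      stopf("scenario `%s` is neither a preset (BTS, AMIS) nor a readable file",
            name_or_path)
    name_or_path
  }
  raw <- yamlify_scenario(yaml::read_yaml(path))
  sc <- deep_merge(scenario_base(), raw)
  validate_scenario(sc)
}

#' Path of a shipped scenario preset file
#' @param name `"BTS"` or `"AMIS"`.
#' @return File path of the YAML preset.
#' @export
scenario_preset_path <- function(name) {
  system.file("extdata", "scenarios", paste0(tolower(name), ".yaml"),
              package = "coulisse", mustWork = TRUE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1))
    stopf("scenario field `%s` must hold probabilities in [0, 1]", field)
}
check_mult <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x <= 0))
    stopf("scenario field `%s` must hold positive multipliers", field)
}

validate_scenario <- function(sc) {
  ces <- sc$cessation
  for (ty in FARMER_TYPES) {
    row <- ces$base[[ty]]
    if (is.null(row) || !all(AGE_CLASSES %in% names(row)))
      stopf("scenario field `cessation.base.%s` must give rates for age classes %s",
            ty, paste(AGE_CLASSES, collapse = ", "))
    check_prob(row, paste0("cessation.base.", ty))
  }
  check_mult(ces$scenario_mult, "cessation.scenario_mult")
  check_mult(ces$small_farm_subsidy, "cessation.small_farm_subsidy")
  check_mult(ces$low_productivity_mult, "cessation.low_productivity_mult")
  check_mult(ces$leader_diversified_mult, "cessation.leader_diversified_mult")
  check_prob(sc$retirement$hazard, "retirement.hazard")
  if (!all(FARMER_TYPES %in% names(sc$retirement$succession)))
    stopf("scenario field `retirement.succession` must cover all farmer types")
  check_prob(sc$retirement$succession, "retirement.succession")
  exp <- sc$expansion
  if (!all(FARMER_TYPES %in% names(exp$propensity)))
    stopf("scenario field `expansion.propensity` must cover all farmer types")
  if (any(exp$propensity < 0)) stopf("scenario field `expansion.propensity` must be >= 0")
  if (any(exp$propensity > exp$propensity[["expansionist"]]))
    stopf("scenario field `expansion.propensity`: no type may exceed the expansionist propensity")
  check_prob(exp$participation, "expansion.participation")
  check_mult(exp$participation_mult, "expansion.participation_mult")
  check_mult(exp$propensity_mult, "expansion.propensity_mult")
  check_mult(exp$zone_mult, "expansion.zone_mult")
  check_prob(sc$contraction, "contraction")
  check_prob(sc$market$p_estate, "market.p_estate")
  check_prob(sc$market$p_nature, "market.p_nature")
  el <- sc$elements
  for (cl in OWNER_ELEMENT_CLASSES) {
    tri <- el$base[[cl]]
    if (is.null(tri) || !all(c("cut", "keep", "plant") %in% names(tri)))
      stopf("scenario field `elements.base.%s` must give cut/keep/plant", cl)
    check_prob(tri, paste0("elements.base.", cl))
    if (abs(sum(tri) - 1) > 1e-9)
      stopf("scenario field `elements.base.%s` probabilities must sum to 1 (got %.12f)",
            cl, sum(tri))
  }
  check_mult(el$protect_cut_mult, "elements.protect_cut_mult")
  check_mult(el$protect_plant_mult, "elements.protect_plant_mult")
  check_prob(el$stewardship_plant_bonus, "elements.stewardship_plant_bonus")
  check_prob(el$cut_fraction, "elements.cut_fraction")
  if (el$plant_increment_m_ha < 0) stopf("scenario field `elements.plant_increment_m_ha` must be >= 0")
  if (sc$tourism$gain < 0) stopf("scenario field `tourism.gain` must be >= 0")
  structure(sc, class = "scenario_params")
}

#' @export
print.scenario_params <- function(x, ...) {
  cat(sprintf("<scenario_params> %s\n", x$name))
  cat(sprintf("  small-farm subsidy multiplier %.2f | tourism gain %.2f | nature purchase (habitat) %.2f\n",
              x$cessation$small_farm_subsidy, x$tourism$gain,
              x$market$p_nature[["habitat_directive"]]))
  invisible(x)
}
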