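library(data.table)

# ---- small generated fixtures ----------------------------------------------

tiny_cfg <- function(...) {
  args <- modifyList(list(n_farmers = 60L, agri_area_ha = 1600,
                          semi_natural_ha = 180, pct_residents = 38,
                          n_villages = 3L, scatter_radius_m = 3000),
                     list(...))
  do.call(region_config, args)
}

tenth_cfg <- function(...) {
  # 1/10-scale fixture of the default region (shares preserved)
  args <- modifyList(list(n_farmers = 171L, agri_area_ha = 4576,
                          semi_natural_ha = 504, pct_residents = 38,
                          n_villages = 4L, scatter_radius_m = 5000),
                     list(...))
  do.call(region_config, args)
}

# the full-scale default region is expensive (~6 s); build it once per test run
.fixture_cache <- new.env(parent = emptyenv())
get_full_region <- function() {
  if (is.null(.fixture_cache$full))
    .fixture_cache$full <- generate_region(region_config(), seed = 42)
  .fixture_cache$full
}
get_tiny_region <- function() {
  if (is.null(.fixture_cache$tiny))
    .fixture_cache$tiny <- generate_region(tiny_cfg(), seed = 7)
  .fixture_cache$tiny
}

# ---- hand-built toy region --------------------------------------------------

# n_farmers farmsteads on a line 1 km apart, each farm = farmstead + one
# extra parcel; fully deterministic, no RNG
toy_region <- function(n_farmers = 3L,
                       types = rep("conventional", n_farmers),
                       extra_offset_m = rep(2000, n_farmers)) {
  np <- 2L * n_farmers
  ids <- seq_len(np)
  x <- c((seq_len(n_farmers) - 1) * 1000 + 50,
         (seq_len(n_farmers) - 1) * 1000 + 50)
  y <- c(rep(50, n_farmers), 50 + extra_offset_m)
  parcels <- data.table(
    id = ids, x = x, y = y, area_ha = 1,
    land_use = "agriculture", productivity = 0.5, aesthetic = 0.5,
    element_m = 100,
    z_protect = FALSE, z_habitat = FALSE, z_agridev = FALSE,
    z_leader = FALSE, z_pilot = FALSE, z_attraction = FALSE,
    owner_id = rep(seq_len(n_farmers), 2L), owner_class = "farmer")
  farmers <- data.table(
    id = seq_len(n_farmers), type = types, age = 45, dsu = 30,
    x = x[seq_len(n_farmers)], y = y[seq_len(n_farmers)],
    farmstead_id = seq_len(n_farmers), retire_age = 65, active = TRUE)
  residents <- data.table(id = integer(), x = numeric(), y = numeric(),
                          residence_id = integer(), migrant = logical())
  structure(list(parcels = parcels, farmers = farmers, residents = residents,
                 year = 2005L, start_year = 2005L, tourism_demand = 1.0,
                 grid = list(nx = max(1L, as.integer(ceiling(max(x) / 100))),
                             ny = as.integer(ceiling(max(y) / 100)),
                             cell_m = 100),
                 total_area_ha = sum(parcels$area_ha),
                 baseline = list(element_total_m = sum(parcels$element_m),
                                 semi_natural_ha = 0, attraction_n = 0),
                 config = NULL),
            class = "region")
}

# ---- scenarios for surgical tests ------------------------------------------

# all dynamics switched off: a step only ages agents and advances the year
scenario_zeroed <- function() {
  sc <- coulisse:::scenario_base()
  for (ty in names(sc$cessation$base))
    sc$cessation$base[[ty]][] <- 0
  sc$retirement$hazard <- 0
  sc$expansion$participation[] <- 0
  sc$contraction[] <- 0
  sc$market$p_estate <- 0
  sc$market$p_nature[] <- 0
  for (cl in names(sc$elements$base))
    sc$elements$base[[cl]] <- c(cut = 0, keep = 1, plant = 0)
  sc$elements$stewardship_plant_bonus <- 0
  sc$tourism$gain <- 0
  sc$name <- "zeroed"
  coulisse:::validate_scenario(sc)
}

# zeroed scenario with one uniform annual cessation probability for everyone
scenario_flat_cessation <- function(p) {
  sc <- scenario_zeroed()
  for (ty in names(sc$cessation$base))
    sc$cessation$base[[ty]][] <- p
  sc$name <- sprintf("flat_cessation_%g", p)
  coulisse:::validate_scenario(sc)
}
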