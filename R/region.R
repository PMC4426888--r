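#' Configuration for the synthetic region generator
#'
#' Builds (and validates) the settings that [generate_region()] turns into a
#' synthetic bocage region of 1-ha grid parcels, policy zones, landscape
#' elements and agent populations. Defaults reproduce the 2005 baseline of the
#' case region: 1,705 farmers, 45,765 ha agricultural area, 5,045 ha
#' semi-natural area, 31% diversified/multifunctional farmers and rural
#' residents making up 38% of the rural population.
#'
#' The grid extent is auto-sized so that the configured land-use areas tile it
#' exactly (every parcel must have an owner or be semi-natural). Passing `nx`
#' and `ny` fixes the extent instead; a fixed extent too small for the
#' requested areas is rejected.
#'
#' @param n_farmers Number of active farm households at baseline.
#' @param agri_area_ha Agricultural area in hectares (= number of 1-ha cells).
#' @param semi_natural_ha Semi-natural area in hectares.
#' @param pct_residents Rural residents as a percentage of (farmers +
#'   residents); sets the resident count.
#' @param resident_parcels Parcels held per resident (residence included).
#' @param type_mix Named shares of farmer management types; must sum to 1.
#'   The `diversified_multifunctional` share is the baseline multifunctional
#'   percentage.
#' @param cell_m Cell edge length in metres (100 m = 1 ha).
#' @param nx,ny Optional fixed grid extent in cells.
#' @param age_mean,age_sd,age_min,age_max Truncated-normal farmer age
#'   distribution (years).
#' @param retire_age_mean,retire_age_sd Personal retirement-age draw (years).
#' @param dsu_meanlog,dsu_sdlog Log-normal farm economic size (Dutch Size
#'   Units); farms below 10 DSU count as small farms.
#' @param contiguous_frac Fraction of each farm allocated contiguously around
#'   the farmstead; the remainder is scattered over the region.
#' @param scatter_radius_m Radius (m) within which scattered holdings are
#'   drawn; tunes the mean farmstead-to-farthest-parcel distance.
#' @param zone_fracs Named area fractions of the policy zones.
#' @param attraction_frac Fraction of parcels tagged as tourist attractions.
#' @param element_total_km Baseline total length of landscape elements
#'   (hedgerows, tree lines) region-wide, in km.
#' @param element_gamma_shape Shape of the per-parcel gamma draw for element
#'   length.
#' @param element_protect_mult Relative element density inside landscape
#'   protection zones.
#' @param n_villages Number of village clusters seeding residential parcels.
#' @param start_year First simulated calendar year.
#' @return A validated list of class `region_config`.
#' @seealso [generate_region()], [load_region_config()]
#' @export
region_config <- function(n_farmers = 1705L,
                          agri_area_ha = 45765,
                          semi_natural_ha = 5045,
                          pct_residents = 38,
                          resident_parcels = 2L,
                          type_mix = c(expansionist = 0.35,
                                       conventional = 0.34,
                                       diversified_multifunctional = 0.31,
                                       hobby = 0),
                          cell_m = 100,
                          nx = NULL, ny = NULL,
                          age_mean = 55, age_sd = 10,
                          age_min = 25, age_max = 75,
                          retire_age_mean = 65, retire_age_sd = 5,
                          dsu_meanlog = log(30), dsu_sdlog = 1,
                          contiguous_frac = 0.6,
                          scatter_radius_m = 16500,
                          zone_fracs = c(landscape_protection = 0.15,
                                         habitat_directive = 0.10,
                                         agri_development = 0.25,
                                         leader = 0.20,
                                         pilot = 0.08),
                          attraction_frac = 0.0002,
                          element_total_km = 5000,
                          element_gamma_shape = 1.2,
                          element_protect_mult = 2,
                          n_villages = 12L,
                          start_year = 2005L) {
  cfg <- list(n_farmers = as.integer(n_farmers),
              agri_area_ha = agri_area_ha,
              semi_natural_ha = semi_natural_ha,
              pct_residents = pct_residents,
              resident_parcels = as.integer(resident_parcels),
              type_mix = type_mix, cell_m = cell_m, nx = nx, ny = ny,
              age_mean = age_mean, age_sd = age_sd,
              age_min = age_min, age_max = age_max,
              retire_age_mean = retire_age_mean,
              retire_age_sd = retire_age_sd,
              dsu_meanlog = dsu_meanlog, dsu_sdlog = dsu_sdlog,
              contiguous_frac = contiguous_frac,
              scatter_radius_m = scatter_radius_m,
              zone_fracs = zone_fracs,
              attraction_frac = attraction_frac,
              element_total_km = element_total_km,
              element_gamma_shape = element_gamma_shape,
              element_protect_mult = element_protect_mult,
              n_villages = as.integer(n_villages),
              start_year = as.integer(start_year))
  validate_region_config(cfg)
  structure(cfg, class = "region_config")
}

validate_region_config <- function(cfg) {
  if (cfg$n_farmers < 1L) stopf("infeasible config: n_farmers must be >= 1")
  if (cfg$agri_area_ha < cfg$n_farmers)
    stopf("infeasible config: agricultural area (%s ha) smaller than farmer count (%s); every farm needs a farmstead parcel",
          cfg$agri_area_ha, cfg$n_farmers)
  if (cfg$semi_natural_ha < 0) stopf("infeasible config: semi_natural_ha < 0")
  if (cfg$pct_residents < 0 || cfg$pct_residents >= 100)
    stopf("infeasible config: pct_residents must be in [0, 100)")
  mix <- cfg$type_mix
  need <- c("expansionist", "conventional", "diversified_multifunctional", "hobby")
  if (!all(need %in% names(mix)))
    stopf("infeasible config: type_mix must name all of: %s", paste(need, collapse = ", "))
  if (abs(sum(mix) - 1) > 1e-8 || any(mix < 0))
    stopf("infeasible config: type_mix shares must be non-negative and sum to 1")
  if (cfg$contiguous_frac < 0 || cfg$contiguous_frac > 1)
    stopf("infeasible config: contiguous_frac must be in [0, 1]")
  zf <- cfg$zone_fracs
  zneed <- c("landscape_protection", "habitat_directive", "agri_development",
             "leader", "pilot")
  if (!all(zneed %in% names(zf)) || any(zf < 0) || any(zf > 1))
    stopf("infeasible config: zone_fracs must name %s with values in [0, 1]",
          paste(zneed, collapse = ", "))
  n_res <- resident_count(cfg)
  total <- total_cells_needed(cfg)
  if (!is.null(cfg$nx) || !is.null(cfg$ny)) {
    if (is.null(cfg$nx) || is.null(cfg$ny))
      stopf("infeasible config: nx and ny must be given together")
    if (cfg$nx * cfg$ny < total)
      stopf("infeasible config: requested areas (%d ha: %s agricultural + %s semi-natural + %d residential) exceed the fixed region extent of %d ha",
            total, cfg$agri_area_ha, cfg$semi_natural_ha,
            n_res * cfg$resident_parcels, cfg$nx * cfg$ny)
  }
  invisible(cfg)
}

resident_count <- function(cfg) {
  p <- cfg$pct_residents / 100
  as.integer(round(p / (1 - p) * cfg$n_farmers))
}

total_cells_needed <- function(cfg) {
  as.integer(round(cfg$agri_area_ha) + round(cfg$semi_natural_ha) +
               resident_count(cfg) * cfg$resident_parcels)
}

#' Read a region-generator configuration from a YAML file
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [region_config()]. Missing keys take the defaults.
#' @return A `region_config` object.
#' @export
load_region_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("type_mix", "zone_fracs"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  do.call(region_config, raw)
}

# largest-remainder apportionment of `total` into integer counts ~ weights
apportion <- function(weights, total) {
  if (total == 0L) return(rep(0L, length(weights)))
  w <- weights / sum(weights)
  raw <- w * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# --- blob growth -------------------------------------------------------------
# Grow contiguous blobs on the (possibly ragged) row-major grid of `n_total`
# cells, nx per row. `allowed`: logical over cells where growth is preferred;
# growth spills outside `allowed` only when the frontier inside it is empty.
grow_blobs <- function(n_total, nx, target, n_seeds, allowed = NULL,
                       p_accept = 0.65, forbidden = NULL) {
  target <- as.integer(target)
  blob <- logical(n_total)
  if (target <= 0L) return(blob)
  ok <- if (is.null(allowed)) rep(TRUE, n_total) else allowed
  if (!is.null(forbidden)) ok <- ok & !forbidden
  pool <- which(ok)
  if (!length(pool)) pool <- seq_len(n_total)
  seeds <- pool[sample.int(length(pool), min(n_seeds, length(pool)))]
  blob[seeds] <- TRUE
  size <- sum(blob)
  relax <- FALSE
  while (size < target) {
    cur <- which(blob)
    nb <- c(cur - 1L, cur + 1L, cur - nx, cur + nx)
    # row wrap guard for +-1 neighbours
    same_row <- c((cur - 1L - 1L) %/% nx == (cur - 1L) %/% nx,
                  (cur + 1L - 1L) %/% nx == (cur - 1L) %/% nx,
                  rep(TRUE, 2L * length(cur)))
    nb <- nb[same_row & nb >= 1L & nb <= n_total]
    nb <- unique(nb)
    frontier <- nb[!blob[nb]]
    if (!relax) frontier <- frontier[ok[frontier]]
    if (!is.null(forbidden)) frontier <- frontier[!forbidden[frontier]]
    if (!length(frontier)) {
      if (!relax) { relax <- TRUE; next }  # allow spillover outside `allowed`
      # disconnected pool exhausted: reseed
      rest <- which(!blob & (is.null(forbidden) | !forbidden))
      if (!length(rest)) break
      blob[rest[sample.int(length(rest), 1L)]] <- TRUE
      size <- size + 1L
      next
    }
    take <- frontier[runif(length(frontier)) < p_accept]
    if (!length(take)) next
    if (size + length(take) > target)
      take <- take[sample.int(length(take), target - size)]
    blob[take] <- TRUE
    size <- size + length(take)
  }
  blob
}

# smooth random field over the grid: bilinear interpolation of a coarse
# lattice of N(0,1) values, returned as ranks rescaled to (0, 1)
smooth_field <- function(col, row, nx, ny, coarse = 8L, noise_sd = 0.4) {
  gx <- pmax(1, ceiling(nx / coarse)); gy <- pmax(1, ceiling(ny / coarse))
  lat <- matrix(rnorm((gx + 1) * (gy + 1)), gy + 1, gx + 1)
  fx <- (col - 0.5) / nx * gx; fy <- (row - 0.5) / ny * gy
  ix <- pmin(floor(fx), gx - 1); iy <- pmin(floor(fy), gy - 1)
  tx <- fx - ix; ty <- fy - iy
  v <- lat[cbind(iy + 1, ix + 1)] * (1 - tx) * (1 - ty) +
    lat[cbind(iy + 1, ix + 2)] * tx * (1 - ty) +
    lat[cbind(iy + 2, ix + 1)] * (1 - tx) * ty +
    lat[cbind(iy + 2, ix + 2)] * tx * ty
  v <- v + rnorm(length(v), 0, noise_sd)
  rank(v, ties.method = "first") / (length(v) + 1)
}

NATURE_ORG_ID <- 0L

FARMER_TYPES <- c("expansionist", "conventional",
                  "diversified_multifunctional", "hobby")

#' Generate a synthetic multifunctional region
#'
#' Builds a full synthetic region — 1-ha grid parcels with policy zones,
#' productivity and aesthetic scores, landscape-element lengths, a farmer
#' population with management types, ages and farm sizes, rural residents and
#' a nature organisation — whose baseline indicators equal the configured
#' targets: farmer and resident counts exactly, areas to within rounding.
#' Generation is a pure function of `(config, seed)`.
#'
#' @param config A [region_config()] object.
#' @param seed Integer seed; identical `(config, seed)` yields a bit-identical
#'   region.
#' @return An object of class `region`: a list with data.tables `parcels`,
#'   `farmers`, `residents`, the current `year`, the `tourism_demand` index
#'   (1 at baseline), baseline summaries and the generating config.
#' @examples
#' r <- generate_region(region_config(n_farmers = 40, agri_area_ha = 1000,
#'                                    semi_natural_ha = 120, n_villages = 3),
#'                      seed = 1)
#' nrow(r$farmers)
#' @export
generate_region <- function(config = region_config(), seed = 1L) {
  if (!inherits(config, "region_config")) {
    config <- do.call(region_config, as.list(config))
  }
  validate_region_config(config)
  set.seed(mix_seed(seed))
  cfg <- config

  n_res <- resident_count(cfg)
  n_agri <- as.integer(round(cfg$agri_area_ha))
  n_semi <- as.integer(round(cfg$semi_natural_ha))
  n_resid_cells <- n_res * cfg$resident_parcels
  n_total <- n_agri + n_semi + n_resid_cells

  if (is.null(cfg$nx)) {
    ny <- as.integer(floor(sqrt(n_total)))
    nx <- as.integer(ceiling(n_total / ny))
  } else {
    nx <- as.integer(cfg$nx); ny <- as.integer(cfg$ny)
  }

  id <- seq_len(n_total)
  col <- (id - 1L) %% nx + 1L
  row <- (id - 1L) %/% nx + 1L
  x <- (col - 0.5) * cfg$cell_m
  y <- (row - 0.5) * cfg$cell_m

  # --- policy zones ----------------------------------------------------------
  zf <- cfg$zone_fracs
  z_protect <- grow_blobs(n_total, nx, zf[["landscape_protection"]] * n_total,
                          n_seeds = 3L)
  z_habitat <- grow_blobs(n_total, nx, zf[["habitat_directive"]] * n_total,
                          n_seeds = 2L, allowed = z_protect)
  z_agridev <- grow_blobs(n_total, nx, zf[["agri_development"]] * n_total,
                          n_seeds = 4L, forbidden = z_protect | z_habitat)
  z_leader <- grow_blobs(n_total, nx, zf[["leader"]] * n_total, n_seeds = 3L)
  z_pilot <- grow_blobs(n_total, nx, zf[["pilot"]] * n_total, n_seeds = 1L,
                        p_accept = 0.8)

  # --- land use --------------------------------------------------------------
  land_use <- rep("agriculture", n_total)
  semi <- grow_blobs(n_total, nx, n_semi, n_seeds = max(3L, n_semi %/% 600L),
                     allowed = z_habitat | z_protect, p_accept = 0.6)
  land_use[semi] <- "semi_natural"

  free <- which(!semi)
  resid_cells <- integer(0)
  if (n_resid_cells > 0L) {
    centers <- free[sample.int(length(free), min(cfg$n_villages, length(free)))]
    per <- apportion(rep(1, length(centers)), n_resid_cells)
    taken <- logical(n_total); taken[semi] <- TRUE
    for (i in seq_along(centers)) {
      if (per[i] == 0L) next
      cand <- which(!taken)
      d2v <- dist2(x[centers[i]], y[centers[i]], x[cand], y[cand])
      k <- min(per[i], length(cand))
      kth <- sort(d2v, partial = k)[k]
      sel <- cand[which(d2v <= kth)][seq_len(k)]
      taken[sel] <- TRUE
      resid_cells <- c(resid_cells, sel)
    }
    land_use[resid_cells] <- "residential"
  }
  agri_cells <- which(land_use == "agriculture")
  stopifnot(length(agri_cells) == n_agri)

  # --- scores ----------------------------------------------------------------
  productivity <- smooth_field(col, row, nx, ny)
  productivity <- clamp(productivity + 0.15 * z_agridev - 0.10 * z_habitat)
  aesthetic <- smooth_field(col, row, nx, ny)
  aesthetic <- clamp(0.65 * aesthetic + 0.25 * (z_protect | z_habitat) +
                       runif(n_total, 0, 0.15))

  # --- landscape elements ----------------------------------------------------
  g <- rgamma(n_total, shape = cfg$element_gamma_shape, rate = 1)
  g <- g * (1 + (cfg$element_protect_mult - 1) * z_protect)
  g[land_use == "semi_natural"] <- g[land_use == "semi_natural"] * 0.3
  element_m <- g / sum(g) * cfg$element_total_km * 1000

  # --- attractions -----------------------------------------------------------
  z_attraction <- logical(n_total)
  n_attr <- as.integer(round(cfg$attraction_frac * n_total))
  if (n_attr > 0L) {
    wts <- 1 + 2 * (z_protect | z_leader)
    z_attraction[sample.int(n_total, n_attr, prob = wts)] <- TRUE
  }

  # --- farmers ---------------------------------------------------------------
  nf <- cfg$n_farmers
  type_counts <- apportion(cfg$type_mix[FARMER_TYPES], nf)
  types <- sample(rep(FARMER_TYPES, type_counts))
  farmsteads <- agri_cells[sample.int(n_agri, nf)]
  ages <- round(rtruncnorm(nf, cfg$age_mean, cfg$age_sd, cfg$age_min, cfg$age_max))
  retire_ages <- round(clamp(rnorm(nf, cfg$retire_age_mean, cfg$retire_age_sd),
                             55, 90))
  dsu <- stats::rlnorm(nf, cfg$dsu_meanlog, cfg$dsu_sdlog)

  farmers <- data.table(id = seq_len(nf), type = types, age = as.numeric(ages),
                        dsu = dsu, x = x[farmsteads], y = y[farmsteads],
                        farmstead_id = farmsteads, retire_age = retire_ages,
                        active = TRUE)

  # --- farm parcel allocation ------------------------------------------------
  sizes <- apportion(stats::rlnorm(nf, 0, 0.7), n_agri)
  # every farm needs at least its farmstead parcel
  while (any(sizes < 1L)) {
    i <- which.min(sizes); j <- which.max(sizes)
    sizes[i] <- sizes[i] + 1L; sizes[j] <- sizes[j] - 1L
  }
  owner_id <- rep(NA_integer_, n_total)
  owner_id[farmsteads] <- farmers$id
  # shrinking free pool of unassigned agricultural cells
  pool <- setdiff(agri_cells, farmsteads)
  px <- x[pool]; py <- y[pool]; pid <- pool
  n_free <- length(pool)
  drop_idx <- function(idx) {
    # swap-with-tail removal, preserves O(1) deletes
    keep <- setdiff(seq_len(n_free), idx)
    last <- seq(n_free - length(idx) + 1L, n_free)
    pid[seq_along(keep)] <<- pid[keep]
    px[seq_along(keep)] <<- px[keep]
    py[seq_along(keep)] <<- py[keep]
    n_free <<- n_free - length(idx)
  }
  for (f in sample.int(nf)) {
    extra <- sizes[f] - 1L
    if (extra <= 0L || n_free == 0L) next
    extra <- min(extra, n_free)
    n_cont <- ceiling(cfg$contiguous_frac * extra)
    n_scat <- extra - n_cont
    sel <- integer(0)
    d2v <- dist2(farmers$x[f], farmers$y[f], px[seq_len(n_free)], py[seq_len(n_free)])
    if (n_cont > 0L) {
      kth <- sort(d2v, partial = n_cont)[n_cont]
      sel <- which(d2v <= kth)[seq_len(n_cont)]
    }
    if (n_scat > 0L) {
      # scattered holdings drawn within the scatter radius (tunes the mean
      # farmstead-to-farthest-parcel distance); nearest fallback beyond it
      rest <- setdiff(which(d2v <= cfg$scatter_radius_m^2), sel)
      if (length(rest) < n_scat) {
        far <- setdiff(order(d2v), c(sel, rest))
        rest <- c(rest, far[seq_len(n_scat - length(rest))])
      }
      sel <- c(sel, if (length(rest) > n_scat)
        rest[sample.int(length(rest), n_scat)] else rest)
    }
    owner_id[pid[sel]] <- farmers$id[f]
    drop_idx(sel)
  }

  # --- residents -------------------------------------------------------------
  residents <- data.table(id = integer(), x = numeric(), y = numeric(),
                          residence_id = integer(), migrant = logical())
  if (n_res > 0L) {
    res_ids <- nf + seq_len(n_res)
    assign_res <- split(resid_cells, apportion_groups(length(resid_cells), n_res))
    residence <- vapply(assign_res, `[`, integer(1), 1L)
    for (i in seq_len(n_res)) owner_id[assign_res[[i]]] <- res_ids[i]
    residents <- data.table(id = res_ids, x = x[residence], y = y[residence],
                            residence_id = residence, migrant = FALSE)
  }

  owner_class <- rep("none", n_total)
  owner_class[land_use == "agriculture"] <- "farmer"
  owner_class[land_use == "residential"] <- "resident"
  # semi-natural: split between the nature organisation and unowned commons
  nat <- land_use == "semi_natural" & runif(n_total) < 0.5
  owner_class[nat] <- "nature"
  owner_id[nat] <- NATURE_ORG_ID

  parcels <- data.table(id = id, x = x, y = y, area_ha = 1,
                        land_use = land_use, productivity = productivity,
                        aesthetic = aesthetic, element_m = element_m,
                        z_protect = z_protect, z_habitat = z_habitat,
                        z_agridev = z_agridev, z_leader = z_leader,
                        z_pilot = z_pilot, z_attraction = z_attraction,
                        owner_id = owner_id, owner_class = owner_class)

  region <- structure(list(
    parcels = parcels, farmers = farmers, residents = residents,
    year = cfg$start_year, start_year = cfg$start_year,
    tourism_demand = 1.0,
    grid = list(nx = nx, ny = ny, cell_m = cfg$cell_m),
    total_area_ha = sum(parcels$area_ha),
    baseline = list(element_total_m = sum(parcels$element_m),
                    semi_natural_ha = sum(parcels$area_ha[parcels$land_use == "semi_natural"]),
                    attraction_n = sum(parcels$z_attraction)),
    config = cfg
  ), class = "region")
  region
}

# split n items into g roughly equal consecutive groups
apportion_groups <- function(n, g) {
  rep(seq_len(g), apportion(rep(1, g), n))
}

#' @export
print.region <- function(x, ...) {
  p <- x$parcels
  cat(sprintf("<region> year %d | %d parcels (%.0f ha) | %d active farmers | %d residents\n",
              x$year, nrow(p), sum(p$area_ha), sum(x$farmers$active),
              nrow(x$residents)))
  cat(sprintf("  agriculture %.0f ha, semi-natural %.0f ha, residential %.0f ha; elements %.0f km; tourism index %.3f\n",
              sum(p$area_ha[p$land_use == "agriculture"]),
              sum(p$area_ha[p$land_use == "semi_natural"]),
              sum(p$area_ha[p$land_use == "residential"]),
              sum(p$element_m) / 1000, x$tourism_demand))
  invisible(x)
}

#' Validate the structural invariants of a region
#'
#' Checks ownership consistency, land-use/owner correspondence, score ranges,
#' area conservation against the generated total, and agent invariants.
#' This is a reporting operation: it never throws.
#'
#' @param region A `region` object.
#' @return A data.table with one row per violation (columns `check`, `entity`,
#'   `id`, `message`); zero rows if and only if the region is valid.
#' @export
validate_region <- function(region) {
  bad <- list()
  note <- function(check, entity, ids, msg) {
    if (length(ids))
      bad[[length(bad) + 1L]] <<- data.table(check = check, entity = entity,
                                             id = as.integer(ids), message = msg)
  }
  p <- region$parcels
  note("duplicate_parcel", "parcel", p$id[duplicated(p$id)],
       "parcel id appears more than once (multiple ownership rows)")
  note("area_positive", "parcel", p$id[p$area_ha <= 0], "area must be > 0")
  note("element_nonneg", "parcel", p$id[p$element_m < 0],
       "element length must be >= 0")
  note("score_range", "parcel",
       p$id[p$productivity < 0 | p$productivity > 1 |
              p$aesthetic < 0 | p$aesthetic > 1],
       "productivity/aesthetic must lie in [0, 1]")
  note("land_use", "parcel",
       p$id[!p$land_use %in% c("agriculture", "semi_natural", "residential")],
       "unknown land use")
  semi_ok <- (p$land_use == "semi_natural") ==
    (p$owner_class %in% c("nature", "none"))
  note("semi_natural_owner", "parcel", p$id[!semi_ok],
       "semi-natural iff owned by the nature organisation or nobody")
  note("agri_owner", "parcel",
       p$id[p$land_use == "agriculture" & p$owner_class != "farmer"],
       "agricultural parcels must be farmer-owned")
  note("res_owner", "parcel",
       p$id[p$land_use == "residential" & p$owner_class != "resident"],
       "residential parcels must be resident-owned")
  f <- region$farmers
  own_f <- p[owner_class == "farmer"]
  note("owner_exists", "parcel",
       own_f$id[!own_f$owner_id %in% f$id[f$active]],
       "owner is not an active farmer")
  own_r <- p[owner_class == "resident"]
  note("owner_exists", "parcel",
       own_r$id[!own_r$owner_id %in% region$residents$id],
       "owner is not a known resident")
  holdings <- own_f[, .N, by = owner_id]
  act <- f[f$active]
  has_stead <- p$owner_id[match(act$farmstead_id, p$id)] == act$id
  note("farmstead_in_holdings", "farmer", act$id[!has_stead %in% TRUE],
       "active farmer's farmstead parcel is not among his holdings")
  inact <- f[!f$active]
  note("inactive_holdings", "farmer",
       inact$id[inact$id %in% own_f$owner_id],
       "inactive farmer still owns parcels")
  note("dsu_nonneg", "farmer", f$id[f$dsu < 0], "DSU must be >= 0")
  note("age_range", "farmer", act$id[act$age < 18 | act$age > 100],
       "active farmer age outside [18, 100]")
  tot <- sum(p$area_ha)
  if (abs(tot - region$total_area_ha) > 1e-6)
    bad[[length(bad) + 1L]] <- data.table(
      check = "area_conservation", entity = "region", id = NA_integer_,
      message = sprintf("land-use areas sum to %.3f ha, expected %.3f ha",
                        tot, region$total_area_ha))
  if (region$year < region$start_year)
    bad[[length(bad) + 1L]] <- data.table(
      check = "year", entity = "region", id = NA_integer_,
      message = "year before start year")
  if (length(bad)) rbindlist(bad) else
    data.table(check = character(), entity = character(), id = integer(),
               message = character())
}

zone_cols <- c("z_protect", "z_habitat", "z_agridev", "z_leader", "z_pilot",
               "z_attraction")
zone_labels <- c(z_protect = "landscape_protection",
                 z_habitat = "habitat_directive",
                 z_agridev = "agri_development",
                 z_leader = "leader", z_pilot = "pilot",
                 z_attraction = "tourist_asset")

#' Write a region to plain-text files
#'
#' Writes `parcels.csv` (zones as a semicolon-joined label column),
#' `farmers.csv`, `residents.csv` and `meta.yaml` into `dir`.
#'
#' @param region A `region` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_region <- function(region, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- copy(region$parcels)
  zl <- apply(as.matrix(p[, zone_cols, with = FALSE]), 1L,
              function(z) paste(zone_labels[zone_cols[z]], collapse = ";"))
  out <- p[, .(id, x, y, area_ha, land_use, productivity, aesthetic,
               element_m, owner_id, owner_class)]
  out[, zones := zl]
  fwrite(out, file.path(dir, "parcels.csv"))
  fwrite(region$farmers, file.path(dir, "farmers.csv"))
  fwrite(region$residents, file.path(dir, "residents.csv"))
  yaml::write_yaml(list(year = region$year, start_year = region$start_year,
                        tourism_demand = region$tourism_demand,
                        grid = region$grid,
                        total_area_ha = region$total_area_ha,
                        baseline = region$baseline,
                        config = unclass(region$config)),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Read a region written by [write_region()]
#'
#' @param dir Directory containing the region files.
#' @return A `region` object.
#' @export
read_region <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  p <- fread(file.path(dir, "parcels.csv"))
  zl <- strsplit(p$zones, ";", fixed = TRUE)
  for (zc in zone_cols)
    p[, (zc) := vapply(zl, function(z) zone_labels[[zc]] %in% z, logical(1))]
  p[, zones := NULL]
  setorder(p, id)
  data.table::setcolorder(p, c("id", "x", "y", "area_ha", "land_use",
                               "productivity", "aesthetic", "element_m",
                               zone_cols, "owner_id", "owner_class"))
  farmers <- fread(file.path(dir, "farmers.csv"))
  residents <- fread(file.path(dir, "residents.csv"),
                     colClasses = list(integer = c("id", "residence_id"),
                                       numeric = c("x", "y"),
                                       logical = "migrant"))
  cfg <- meta$config
  for (nm in c("type_mix", "zone_fracs")) cfg[[nm]] <- unlist(cfg[[nm]])
  structure(list(parcels = p, farmers = farmers, residents = residents,
                 year = meta$year, start_year = meta$start_year,
                 tourism_demand = meta$tourism_demand,
                 grid = meta$grid, total_area_ha = meta$total_area_ha,
                 baseline = meta$baseline,
                 config = structure(cfg, class = "region_config")),
            class = "region")
}
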