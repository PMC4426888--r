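#' Create a decision context for simulation
#'
#' Bundles the scenario, the intervention settings and the RNG stream
#' identity. Every year simulated under a given `(run_seed, replicate)` pair
#' reseeds deterministically from `(run_seed, replicate, year)`, so whole
#' trajectories are reproducible bit for bit and replicates are independent.
#'
#' @param scenario A `scenario_params` object (see [load_scenario()]).
#' @param intervention An [intervention_spec()].
#' @param run_seed Integer master seed of the run.
#' @param replicate Replicate index (>= 1).
#' @param year Calendar year the context applies to (`NULL` = take it from
#'   the region at each step).
#' @param validate Run the full structural validation before each step.
#' @return A list of class `decision_context`.
#' @export
decision_context <- function(scenario, intervention = intervention_spec(),
                             run_seed = 1L, replicate = 1L, year = NULL,
                             validate = TRUE) {
  if (!inherits(scenario, "scenario_params"))
    stopf("`scenario` must be a scenario_params object (see load_scenario())")
  if (!inherits(intervention, "intervention_spec"))
    intervention <- do.call(intervention_spec, intervention)
  structure(list(scenario = scenario, intervention = intervention,
                 run_seed = as.integer(run_seed),
                 replicate = as.integer(replicate), year = year,
                 validate = isTRUE(validate)),
            class = "decision_context")
}

# --- cessation / retirement --------------------------------------------------

# Vectorised three-outcome probabilities {cease, retire_with_successor,
# continue}. Retirement is hazard-driven once the personal retirement age is
# reached; a retiring farmer hands over to a successor with the type's
# succession probability (zero where zoning blocks bequeathing); independent
# business cessation follows the (type, age-class) base table times the
# scenario multipliers.
cessation_probabilities <- function(type, age, dsu, retire_age, scenario,
                                    farm_productivity = NA_real_,
                                    in_leader = FALSE, succ_allowed = TRUE) {
  ces <- scenario$cessation
  ret <- scenario$retirement
  n <- length(type)
  miss <- setdiff(unique(type), names(ces$base))
  if (length(miss))
    stopf("cessation base-rate table has no entry for management type `%s`",
          miss[1])
  acl <- age_class(age)
  base <- vapply(seq_len(n), function(i) ces$base[[type[i]]][[acl[i]]],
                 numeric(1))
  mult <- rep(ces$scenario_mult, n)
  mult <- mult * fifelse(dsu < 10, ces$small_farm_subsidy, 1)
  lowp <- !is.na(farm_productivity) &
    farm_productivity < ces$low_productivity_threshold
  mult <- mult * fifelse(lowp, ces$low_productivity_mult, 1)
  mult <- mult * fifelse(type == "diversified_multifunctional" & in_leader,
                         ces$leader_diversified_mult, 1)
  p_base <- pmin(1, base * mult)
  p_ret <- fifelse(age >= retire_age + ret$age_shift, ret$hazard, 0)
  p_succ <- ret$succession[type] * as.numeric(succ_allowed)
  p_cease <- p_ret * (1 - p_succ) + (1 - p_ret) * p_base
  p_retsucc <- p_ret * p_succ
  list(cease = p_cease, retire_with_successor = p_retsucc,
       continue = pmax(0, 1 - p_cease - p_retsucc))
}

#' Decide cessation, succession or continuation for one farmer
#'
#' Draws one of `continue`, `retire_with_successor` or `cease` from the
#' categorical distribution given by the (management type, age class) base
#' rates, the retirement hazard past the personal retirement age, and the
#' scenario multipliers (the small-farm subsidy multiplier applies only below
#' 10 DSU).
#'
#' @param farmer A one-row data.frame/list with `type`, `age`, `dsu`,
#'   `retire_age`.
#' @param ctx A [decision_context()].
#' @param farm_productivity Mean productivity of the farm's holdings (used by
#'   the low-productivity squeeze; `NA` disables it).
#' @param in_leader Is the farmstead inside a LEADER zone?
#' @param u Optional uniform draw (for common-random-number experiments).
#' @return One of `"continue"`, `"retire_with_successor"`, `"cease"`.
#' @export
decide_cessation <- function(farmer, ctx, farm_productivity = NA_real_,
                             in_leader = FALSE, u = runif(1)) {
  p <- cessation_probabilities(farmer$type, farmer$age, farmer$dsu,
                               farmer$retire_age, ctx$scenario,
                               farm_productivity, in_leader)
  # cease occupies [0, p_cease): raising any cessation multiplier can only
  # grow that interval, so outcomes are monotone under common random numbers
  if (u < p$cease) "cease"
  else if (u < p$cease + p$retire_with_successor) "retire_with_successor"
  else "continue"
}

# --- expansion bids ----------------------------------------------------------

expansion_propensity <- function(type, scenario) {
  ex <- scenario$expansion
  pr <- ex$propensity[type]
  unname(pr * fifelse(type == "expansionist", ex$propensity_mult, 1))
}

parcel_zone_multiplier <- function(parcels_rows, scenario) {
  zm <- scenario$expansion$zone_mult
  m <- rep(1, nrow(parcels_rows))
  m <- m * fifelse(parcels_rows$z_agridev, zm[["agri_development"]], 1)
  m <- m * fifelse(parcels_rows$z_habitat, zm[["habitat_directive"]], 1)
  m <- m * fifelse(parcels_rows$z_protect, zm[["landscape_protection"]], 1)
  m
}

#' Rank a farmer's expansion bids over offered parcels
#'
#' Bid score = expansion propensity (type, scenario) x parcel productivity x
#' proximity weight x zone multiplier (agricultural development zones up,
#' habitat-directive/protection zones down, per scenario). Parcels below the
#' scenario's productivity floor or beyond the search radius receive no bid.
#' Bids are sorted by decreasing score, ties broken by parcel id.
#'
#' @param farmer One-row farmer (needs `type`, `x`, `y`, `id`).
#' @param offers Parcel table rows currently on offer.
#' @param ctx A [decision_context()].
#' @return data.table of `parcel_id`, `score`, ordered best-first (zero rows
#'   for a farmer with zero propensity).
#' @export
decide_expansion_bids <- function(farmer, offers, ctx) {
  sc <- ctx$scenario
  ex <- sc$expansion
  prop <- expansion_propensity(farmer$type, sc)
  if (prop <= 0 || nrow(offers) == 0L)
    return(data.table(parcel_id = integer(), score = numeric()))
  d <- sqrt(dist2(farmer$x, farmer$y, offers$x, offers$y))
  w_prox <- 1 / (1 + d / ex$proximity_scale_m)
  score <- prop * offers$productivity * w_prox *
    parcel_zone_multiplier(offers, sc)
  keep <- offers$productivity >= ex$productivity_floor & d <= ex$radius_m
  out <- data.table(parcel_id = offers$id[keep], score = score[keep])
  setorder(out, -score, parcel_id)
  out
}

# --- market allocation -------------------------------------------------------

#' Allocate offered parcels among bidders, residents and the nature
#' organisation
#'
#' Each offered parcel is resolved in parcel-id order: (a) the highest-scored
#' farmer bid with remaining purchase capacity wins; otherwise (b) a
#' resident/urban-migrant buys with probability `p_estate` when the parcel
#' qualifies as a small aesthetic estate; otherwise (c) the nature
#' organisation buys with probability `p_nature` when the parcel lies in a
#' habitat-directive or landscape-protection zone; otherwise (d) the parcel
#' is abandoned. Forced offers (zoning intervention) accept only
#' multifunctional-farmer bids, residents or the nature organisation.
#'
#' @param offers data.table `parcel_id`, `seller_id`, `forced` (logical).
#' @param bids data.table `parcel_id`, `bidder_id`, `bidder_type`, `score`.
#' @param ctx A [decision_context()].
#' @param parcels Parcel table of the region (attribute lookup).
#' @param capacity Named integer: remaining purchase capacity per bidder
#'   (default: scenario capacity for every bidder).
#' @return data.table of land transfers: `parcel_id`, `seller_id`,
#'   `buyer_id`, `buyer_class` in `farmer`/`resident`/`nature`/`abandon`,
#'   `price_rank` (the winning bid's rank, NA for non-farmer outcomes), plus
#'   a `qualifying_estate` flag used by the in-migration accounting.
#' @export
allocate_market <- function(offers, bids, ctx, parcels,
                            capacity = NULL) {
  if (anyDuplicated(offers$parcel_id))
    stopf("parcel %d offered twice in the same year",
          offers$parcel_id[duplicated(offers$parcel_id)][1])
  sc <- ctx$scenario
  market <- apply_inmigration(ctx$intervention, sc$market)
  offers <- offers[order(offers$parcel_id)]
  n <- nrow(offers)
  if (n == 0L)
    return(data.table(parcel_id = integer(), seller_id = integer(),
                      buyer_id = integer(), buyer_class = character(),
                      price_rank = integer(), qualifying_estate = logical()))
  prow <- parcels[match(offers$parcel_id, parcels$id)]
  u_estate <- runif(n); u_nature <- runif(n)
  if (nrow(bids)) {
    bids <- bids[order(bids$parcel_id, -bids$score, bids$bidder_id)]
    bid_split <- split(seq_len(nrow(bids)), bids$parcel_id)
  } else bid_split <- list()
  cap_ids <- unique(bids$bidder_id)
  cap <- if (is.null(capacity))
    rep(as.integer(sc$expansion$capacity), length(cap_ids))
  else as.integer(capacity[as.character(cap_ids)])
  bidder_slot <- match(bids$bidder_id, cap_ids)
  buyer_id <- rep(NA_integer_, n)
  buyer_class <- rep("abandon", n)
  price_rank <- rep(NA_integer_, n)
  qualifies <- prow$area_ha <= market$estate_max_ha &
    prow$aesthetic >= market$estate_aesthetic_min
  p_nat <- pmax(fifelse(prow$z_habitat, sc$market$p_nature[["habitat_directive"]], 0),
                fifelse(prow$z_protect, sc$market$p_nature[["landscape_protection"]], 0))
  for (i in seq_len(n)) {
    rows <- bid_split[[as.character(offers$parcel_id[i])]]
    if (!is.null(rows)) {
      if (offers$forced[i]) {
        rows <- rows[bids$bidder_type[rows] == "diversified_multifunctional"]
      }
      for (rk in seq_along(rows)) {
        slot <- bidder_slot[rows[rk]]
        if (cap[slot] > 0L) {
          cap[slot] <- cap[slot] - 1L
          buyer_id[i] <- bids$bidder_id[rows[rk]]
          buyer_class[i] <- "farmer"
          price_rank[i] <- rk
          break
        }
      }
    }
    if (buyer_class[i] != "farmer") {
      if (qualifies[i] && u_estate[i] < market$p_estate) {
        buyer_class[i] <- "resident"
      } else if (u_nature[i] < p_nat[i]) {
        buyer_class[i] <- "nature"
        buyer_id[i] <- NATURE_ORG_ID
      }
    }
  }
  data.table(parcel_id = offers$parcel_id, seller_id = offers$seller_id,
             buyer_id = buyer_id, buyer_class = buyer_class,
             price_rank = price_rank, qualifying_estate = qualifies)
}

# --- landscape elements ------------------------------------------------------

# cut/keep/plant probabilities for owner classes, zone-modified and
# stewardship-boosted; keep absorbs the remainder after clamping
element_probs <- function(owner_class, in_protect, in_habitat, scenario) {
  el <- scenario$elements
  miss <- setdiff(unique(owner_class), names(el$base))
  if (length(miss))
    stopf("element action table has no entry for owner class `%s`", miss[1])
  cut_by <- vapply(el$base, `[[`, numeric(1), "cut")
  plant_by <- vapply(el$base, `[[`, numeric(1), "plant")
  p_cut <- cut_by[owner_class] * fifelse(in_protect, el$protect_cut_mult, 1)
  p_plant <- plant_by[owner_class] * fifelse(in_protect, el$protect_plant_mult, 1) +
    fifelse(in_habitat, el$stewardship_plant_bonus, 0)
  over <- p_cut + p_plant
  scale <- fifelse(over > 1, 1 / over, 1)
  p_cut <- p_cut * scale; p_plant <- p_plant * scale
  list(cut = unname(p_cut), plant = unname(p_plant),
       keep = unname(pmax(0, 1 - p_cut - p_plant)))
}

#' Decide the landscape-element action on one parcel
#'
#' Draws cut/keep/plant for the parcel's manager and updates the element
#' length: cutting removes `cut_fraction` of the present length, planting
#' adds `plant_increment_m_ha` metres per hectare, keeping leaves it
#' unchanged. Protection/habitat zones modify the cut and plant
#' probabilities per scenario; the element length can never become negative.
#'
#' @param owner Owner class: a farmer management type or `"resident"`.
#' @param parcel One-row parcel (needs `element_m`, `area_ha`, `z_protect`,
#'   `z_habitat`).
#' @param ctx A [decision_context()].
#' @param u Optional uniform draw.
#' @return List with `action` (`"cut"`, `"keep"` or `"plant"`) and the
#'   updated `element_m`.
#' @export
decide_element_action <- function(owner, parcel, ctx, u = runif(1)) {
  el <- ctx$scenario$elements
  pr <- element_probs(owner, parcel$z_protect | parcel$z_habitat,
                      parcel$z_habitat, ctx$scenario)
  action <- if (u < pr$cut) "cut" else if (u < pr$cut + pr$plant) "plant" else "keep"
  new_len <- switch(action,
                    cut = parcel$element_m * (1 - el$cut_fraction),
                    plant = parcel$element_m + el$plant_increment_m_ha * parcel$area_ha,
                    keep = parcel$element_m)
  list(action = action, element_m = max(0, new_len))
}

# --- tourism demand ----------------------------------------------------------

region_metrics <- function(region) {
  p <- region$parcels
  c(elements = sum(p$element_m),
    semi_natural = sum(p$area_ha[p$land_use == "semi_natural"]),
    attractions = sum(p$z_attraction))
}

#' Update the tourism-demand index from landscape change
#'
#' The index multiplies by `1 + g * delta`, where `delta` is the weighted
#' relative year-on-year change in total element length, semi-natural area
#' and attraction count, and `g` the scenario's tourism gain (0 disables the
#' feedback entirely).
#'
#' @param region A `region`; its `last_metrics` field holds the previous
#'   year's values (baseline metrics are used on the first call).
#' @param ctx A [decision_context()].
#' @return The new index value (> 0).
#' @export
update_tourism_demand <- function(region, ctx) {
  g <- ctx$scenario$tourism$gain
  if (g == 0) return(region$tourism_demand)
  w <- ctx$scenario$tourism$weights
  now <- region_metrics(region)
  prev <- region$last_metrics %||%
    c(elements = region$baseline$element_total_m,
      semi_natural = region$baseline$semi_natural_ha,
      attractions = region$baseline$attraction_n)
  rel <- ifelse(prev > 0, (now - prev[names(now)]) / prev[names(now)], 0)
  delta <- sum(w[names(now)] * rel)
  max(1e-9, region$tourism_demand * (1 + g * delta))
}

# --- one simulated year ------------------------------------------------------

#' Advance a region by one simulated year
#'
#' Executes the fixed annual phase order: (1) ageing, (2)
#' cessation/retirement and succession, (3) contraction and cessation offers,
#' (4) expansion bids, (5) market allocation (farmer buyers, estate
#' purchases, nature organisation, abandonment), (6) landscape-element
#' actions, (7) the cooperation adoption sub-model if enabled, (8) the
#' tourism-demand update. Total area is conserved; an invalid region is
#' rejected before any mutation.
#'
#' @param region A valid `region`.
#' @param ctx A [decision_context()]; if it names a `year` it must match the
#'   region's.
#' @return The advanced region (year + 1), carrying per-year event `counters`
#'   and an agent-level `events` log.
#' @export
step_year <- function(region, ctx) {
  if (!is.null(ctx$year) && ctx$year != region$year)
    stopf("decision context is for year %d but region is at year %d",
          ctx$year, region$year)
  if (ctx$validate) {
    v <- validate_region(region)
    if (nrow(v))
      stopf("region invalid before step (first violation: %s / %s)",
            v$check[1], v$message[1])
  }
  sc <- ctx$scenario
  iv <- ctx$intervention
  set.seed(mix_seed(ctx$run_seed, ctx$replicate, region$year))

  p <- copy(region$parcels)
  f <- copy(region$farmers)
  res <- copy(region$residents)
  events <- list()
  log_ev <- function(ids, ev, parcel = NA_integer_) {
    if (length(ids))
      events[[length(events) + 1L]] <<- data.table(
        year = region$year, agent_id = as.integer(ids), event = ev,
        parcel_id = as.integer(parcel))
  }

  # (1) ageing (bounded by the agent age invariant)
  f[active == TRUE, age := pmin(age + 1, 100)]

  # (2) cessation / retirement / succession
  farm_prod <- p[owner_class == "farmer",
                 .(mean_prod = mean(productivity)), by = owner_id]
  fp <- farm_prod$mean_prod[match(f$id, farm_prod$owner_id)]
  in_leader <- p$z_leader[match(f$farmstead_id, p$id)]
  restricted <- if (iv$zoning$enabled) restricted_parcels(p, iv) else
    logical(nrow(p))
  succ_allowed <- !(iv$zoning$enabled & f$type == "expansionist" &
                      restricted[match(f$farmstead_id, p$id)])
  pr <- cessation_probabilities(f$type, f$age, f$dsu, f$retire_age, sc,
                                fp, in_leader, succ_allowed)
  u <- runif(nrow(f))  # indexed by farmer row: robust common random numbers
  cease <- f$active & u < pr$cease
  retsucc <- f$active & !cease & u < pr$cease + pr$retire_with_successor
  if (any(retsucc)) {
    k <- sum(retsucc)
    f$age[retsucc] <- round(clamp(rnorm(k, sc$retirement$successor_age_mean,
                                        sc$retirement$successor_age_sd), 25, 60))
    f$retire_age[retsucc] <- round(clamp(
      rnorm(k, region$config$retire_age_mean %||% 65,
            region$config$retire_age_sd %||% 5) + sc$retirement$age_shift, 55, 90))
    log_ev(f$id[retsucc], "retire")
  }
  forced_farm <- cease & !succ_allowed
  f$active[cease] <- FALSE
  log_ev(f$id[cease], "cease")

  # (3) offers: full dissolution of ceasing farms + contraction of continuers
  off_cease <- p[owner_class == "farmer" & owner_id %in% f$id[cease],
                 .(parcel_id = id, seller_id = owner_id)]
  off_cease[, forced := seller_id %in% f$id[forced_farm]]
  cont <- f$active & runif(nrow(f)) < sc$contraction[f$type]
  off_contr <- data.table(parcel_id = integer(), seller_id = integer(),
                          forced = logical())
  if (any(cont)) {
    own <- p[owner_class == "farmer" & owner_id %in% f$id[cont] &
               !(id %in% f$farmstead_id)]
    if (nrow(own)) {
      own[, d2 := (x - f$x[match(owner_id, f$id)])^2 +
            (y - f$y[match(owner_id, f$id)])^2]
      far <- own[own[, .I[which.max(d2)], by = owner_id]$V1]
      off_contr <- far[, .(parcel_id = id, seller_id = owner_id,
                           forced = FALSE)]
    }
  }
  offers <- rbindlist(list(off_cease, off_contr))

  transfers <- NULL
  if (nrow(offers)) {
    orow <- p[match(offers$parcel_id, p$id)]
    # (4) expansion bids
    expanders <- which(f$active &
                         runif(nrow(f)) <
                         sc$expansion$participation[f$type] *
                         sc$expansion$participation_mult &
                         expansion_propensity(f$type, sc) > 0)
    bids <- data.table(parcel_id = integer(), bidder_id = integer(),
                       bidder_type = character(), score = numeric())
    if (length(expanders)) {
      nb <- nrow(orow)
      eb <- data.table(bi = rep(expanders, each = nb),
                       oi = rep(seq_len(nb), length(expanders)))
      eb[, dist_m := sqrt((orow$x[oi] - f$x[bi])^2 + (orow$y[oi] - f$y[bi])^2)]
      eb <- eb[dist_m <= sc$expansion$radius_m &
                 orow$productivity[oi] >= sc$expansion$productivity_floor &
                 orow$owner_id[oi] != f$id[bi]]
      if (nrow(eb)) {
        prop <- expansion_propensity(f$type, sc)
        zm <- parcel_zone_multiplier(orow, sc)
        eb[, score := prop[bi] * orow$productivity[oi] *
             (1 / (1 + dist_m / sc$expansion$proximity_scale_m)) * zm[oi]]
        bids <- eb[, .(parcel_id = orow$id[oi], bidder_id = f$id[bi],
                       bidder_type = f$type[bi], score = score)]
      }
    }
    if (iv$zoning$enabled) bids <- restrict_bids_zoning(bids, iv, p)$bids
    # (5) market allocation
    transfers <- allocate_market(offers, bids, ctx, p)
    tf <- transfers[buyer_class == "farmer"]
    if (nrow(tf)) {
      pi <- match(tf$parcel_id, p$id)
      p$owner_id[pi] <- tf$buyer_id
      add <- rowsum(p$area_ha[pi], tf$buyer_id)
      bi <- match(as.integer(rownames(add)), f$id)
      f$dsu[bi] <- f$dsu[bi] + sc$market$dsu_per_ha * add[, 1L]
      log_ev(tf$buyer_id, "expand", tf$parcel_id)
    }
    tr <- transfers[buyer_class == "resident"]
    if (nrow(tr)) {
      new_ids <- max(c(f$id, res$id, 0L)) + seq_len(nrow(tr))
      pi <- match(tr$parcel_id, p$id)
      res <- rbindlist(list(res, data.table(
        id = new_ids, x = p$x[pi], y = p$y[pi],
        residence_id = tr$parcel_id, migrant = TRUE)))
      p$owner_id[pi] <- new_ids
      p$owner_class[pi] <- "resident"
      p$land_use[pi] <- "residential"
      log_ev(new_ids, "transfer", tr$parcel_id)
    }
    tn <- transfers[buyer_class == "nature"]
    if (nrow(tn)) {
      pi <- match(tn$parcel_id, p$id)
      p$owner_id[pi] <- NATURE_ORG_ID
      p$owner_class[pi] <- "nature"
      p$land_use[pi] <- "semi_natural"
      log_ev(tn$seller_id, "transfer", tn$parcel_id)
    }
    ta <- transfers[buyer_class == "abandon"]
    if (nrow(ta)) {
      pi <- match(ta$parcel_id, p$id)
      p$owner_id[pi] <- NA_integer_
      p$owner_class[pi] <- "none"
      p$land_use[pi] <- "semi_natural"
      log_ev(ta$seller_id, "abandon", ta$parcel_id)
    }
  }

  # (6) landscape-element actions by the parcel's manager
  mgr <- rep(NA_character_, nrow(p))
  isf <- p$owner_class == "farmer"
  mgr[isf] <- f$type[match(p$owner_id[isf], f$id)]
  mgr[p$owner_class == "resident"] <- "resident"
  act_idx <- which(!is.na(mgr))
  u_el <- runif(nrow(p))
  if (length(act_idx)) {
    pe <- element_probs(mgr[act_idx],
                        p$z_protect[act_idx] | p$z_habitat[act_idx],
                        p$z_habitat[act_idx], sc)
    uu <- u_el[act_idx]
    cut_i <- act_idx[uu < pe$cut]
    plant_i <- act_idx[uu >= pe$cut & uu < pe$cut + pe$plant]
    p$element_m[cut_i] <- p$element_m[cut_i] * (1 - sc$elements$cut_fraction)
    p$element_m[plant_i] <- p$element_m[plant_i] +
      sc$elements$plant_increment_m_ha * p$area_ha[plant_i]
  } else {
    cut_i <- plant_i <- integer(0)
  }

  out <- region
  out$parcels <- p
  out$farmers <- f
  out$residents <- res

  # (7) cooperation adoption (simultaneous switch at year end)
  adopted <- integer(0)
  if (iv$cooperation$enabled) {
    out <- freeze_asset_threshold(out, iv)
    adopted <- cooperation_adoption_step(out, iv, ctx)
    if (length(adopted)) {
      out$farmers$type[match(adopted, out$farmers$id)] <-
        "diversified_multifunctional"
      log_ev(adopted, "adopt")
    }
  }

  # (8) tourism demand
  out$tourism_demand <- update_tourism_demand(out, ctx)
  out$last_metrics <- region_metrics(out)
  out$year <- region$year + 1L

  out$counters <- list(
    cessations = sum(cease), successions = sum(retsucc),
    offers = nrow(offers),
    transfers_farmer = if (is.null(transfers)) 0L else sum(transfers$buyer_class == "farmer"),
    purchases_estate = if (is.null(transfers)) 0L else sum(transfers$buyer_class == "resident"),
    qualifying_estate = if (is.null(transfers)) 0L else sum(transfers$qualifying_estate &
                                                              transfers$buyer_class != "farmer"),
    purchases_nature = if (is.null(transfers)) 0L else sum(transfers$buyer_class == "nature"),
    abandoned = if (is.null(transfers)) 0L else sum(transfers$buyer_class == "abandon"),
    cut_actions = length(cut_i), plant_actions = length(plant_i),
    adopted = length(adopted))
  out$events <- if (length(events)) rbindlist(events) else
    data.table(year = integer(), agent_id = integer(), event = character(),
               parcel_id = integer())
  out
}
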