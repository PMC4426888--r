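#' Specify the stakeholder-derived policy interventions
#'
#' Three interventions can be layered on any scenario: (i) `zoning` —
#' intensive expansionist farmers may neither expand into nor bequeath farms
#' inside restricted zones; their parcels must go to multifunctional farmers,
#' rural residents or the nature organisation; (ii) `cooperation` — farmers
#' assess their `k` nearest neighbours and, where at least `threshold` of
#' them are diversified/multifunctional and tourist assets (nature,
#' hedgerows, attractions) lie nearby, adopt multifunctional farming with
#' probability `rate`, amplified by a tourism-demand increase; (iii)
#' `inmigration` — urban migrants buy any qualifying small estate with
#' probability `purchase_prob`, with a relaxed aesthetic requirement.
#'
#' @param zoning List: `enabled`, `restricted_zones` (subset of
#'   `"landscape_protection"`, `"habitat_directive"`, `"agri_development"`,
#'   `"leader"`, `"pilot"`).
#' @param cooperation List: `enabled`, `rate`, `k`, `threshold`,
#'   `tourism_increase`, `radius_m` (tourist-asset search radius) and
#'   `element_density_quantile` (baseline quantile of 1-km cell element
#'   density above which a cell counts as a hedgerow asset).
#' @param inmigration List: `enabled`, `purchase_prob`, `aesthetic_threshold`.
#' @return A validated list of class `intervention_spec`.
#' @export
intervention_spec <- function(zoning = list(),
                              cooperation = list(),
                              inmigration = list()) {
  spec <- list(
    zoning = modifyList(list(enabled = FALSE,
                             restricted_zones = c("landscape_protection",
                                                  "habitat_directive",
                                                  "pilot")), zoning),
    cooperation = modifyList(list(enabled = FALSE, rate = 0.10, k = 10L,
                                  threshold = 4L, tourism_increase = 0.10,
                                  radius_m = 250,
                                  element_density_quantile = 0.99,
                                  nature_min_frac = 0.9),
                             cooperation),
    inmigration = modifyList(list(enabled = FALSE, purchase_prob = 1.0,
                                  aesthetic_threshold = 0.30), inmigration))
  co <- spec$cooperation
  if (!is_prob(co$rate)) stopf("cooperation rate must be a probability")
  if (co$threshold > co$k) stopf("cooperation threshold must be <= k")
  if (!is_prob(spec$inmigration$purchase_prob))
    stopf("inmigration purchase_prob must be a probability")
  zl <- setdiff(spec$zoning$restricted_zones, unname(zone_labels))
  if (length(zl)) stopf("unknown restricted zone(s): %s", paste(zl, collapse = ", "))
  structure(spec, class = "intervention_spec")
}

# logical over parcels: inside any restricted zone of the zoning intervention
restricted_parcels <- function(parcels, spec) {
  cols <- names(zone_labels)[zone_labels %in% spec$zoning$restricted_zones]
  if (!length(cols)) return(logical(nrow(parcels)))
  Reduce(`|`, lapply(cols, function(cn) parcels[[cn]]))
}

#' Apply the zoning intervention to a bid table
#'
#' Removes bids by expansionist farmers on parcels inside the restricted
#' zones, and reports which parcels are restricted (the decision engine uses
#' that to disallow expansionist succession there and to limit the eligible
#' buyers of forced sales).
#'
#' @param bids data.table with at least `parcel_id`, `bidder_id`,
#'   `bidder_type`.
#' @param spec An [intervention_spec()] with zoning enabled.
#' @param parcels The region's parcel table.
#' @return List with `bids` (filtered table) and `restricted` (logical over
#'   the rows of `parcels`).
#' @export
restrict_bids_zoning <- function(bids, spec, parcels) {
  restricted <- restricted_parcels(parcels, spec)
  if (nrow(bids)) {
    rpid <- parcels$id[restricted]
    drop <- bids$bidder_type == "expansionist" & bids$parcel_id %in% rpid
    bids <- bids[!drop]
  }
  list(bids = bids, restricted = restricted)
}

# --- k-nearest-neighbour machinery ------------------------------------------

# Candidate neighbour lists over farmstead locations, computed once per
# region geometry: for each farmer the `m` nearest other farmers by Euclidean
# farmstead distance, ties broken by id.
knn_candidates <- function(farmers, m = 40L) {
  n <- nrow(farmers)
  m <- min(m, n - 1L)
  out <- matrix(NA_integer_, n, max(m, 0L))
  if (m < 1L) return(out)
  xs <- farmers$x; ys <- farmers$y; ids <- farmers$id
  for (i in seq_len(n)) {
    d2v <- (xs - xs[i])^2 + (ys - ys[i])^2
    d2v[i] <- Inf
    ord <- order(d2v, ids)[seq_len(m)]
    out[i, ] <- ids[ord]
  }
  rownames(out) <- as.character(ids)
  out
}

ensure_knn <- function(region, m = 40L) {
  if (is.null(region$knn) || ncol(region$knn) < min(m, nrow(region$farmers) - 1L))
    region$knn <- knn_candidates(region$farmers, m)
  region
}

# 1-km summed-area table of tourist assets: coarse cells holding a
# semi-natural parcel, an attraction, or element density above the fixed
# baseline threshold. Returns a function(x, y) -> any asset within radius.
asset_lookup <- function(region, spec) {
  p <- region$parcels
  cell <- max(250, spec$cooperation$radius_m)
  ci <- pmax(1L, ceiling(p$x / cell)); cj <- pmax(1L, ceiling(p$y / cell))
  ni <- max(ci); nj <- max(cj)
  idx <- (cj - 1L) * ni + ci
  el <- numeric(ni * nj)
  agg <- rowsum(p$element_m, idx)
  el[as.integer(rownames(agg))] <- agg[, 1L]
  thr <- region$baseline$element_cell_threshold
  if (is.null(thr)) thr <- quantile(el, spec$cooperation$element_density_quantile)
  asset <- el > thr
  # a cell counts as a nature asset only when semi-natural land dominates it
  # (a scattered abandoned parcel is not a tourist draw)
  cell_ha <- (cell / 100)^2
  semi_ha <- numeric(ni * nj)
  sa <- rowsum(p$area_ha * (p$land_use == "semi_natural"), idx)
  semi_ha[as.integer(rownames(sa))] <- sa[, 1L]
  asset <- asset | semi_ha >= spec$cooperation$nature_min_frac * cell_ha
  w <- unique(idx[p$z_attraction])
  asset[w] <- TRUE
  A <- matrix(as.numeric(asset), ni, nj)
  # summed-area table for O(1) window queries (dim-safe for 1-row/col grids)
  S <- matrix(apply(A, 2, cumsum), ni, nj)
  S <- matrix(t(apply(S, 1, cumsum)), ni, nj)
  r <- as.integer(ceiling(spec$cooperation$radius_m / cell))
  function(x, y) {
    i <- pmin(pmax(1L, ceiling(x / cell)), ni)
    j <- pmin(pmax(1L, ceiling(y / cell)), nj)
    i0 <- pmax(i - r, 1L); i1 <- pmin(i + r, ni)
    j0 <- pmax(j - r, 1L); j1 <- pmin(j + r, nj)
    at <- function(ii, jj) {
      v <- numeric(length(ii))
      ok <- ii >= 1L & jj >= 1L
      v[ok] <- S[cbind(ii[ok], jj[ok])]
      v
    }
    (at(i1, j1) - at(i0 - 1L, j1) - at(i1, j0 - 1L) + at(i0 - 1L, j0 - 1L)) > 0
  }
}

# fixed baseline threshold for the hedgerow-density asset criterion, frozen
# at region generation time so that landscape degradation (or restoration)
# moves cells across it over the simulation
freeze_asset_threshold <- function(region, spec) {
  if (!is.null(region$baseline$element_cell_threshold)) return(region)
  p <- region$parcels
  cell <- max(250, spec$cooperation$radius_m)
  ci <- pmax(1L, ceiling(p$x / cell)); cj <- pmax(1L, ceiling(p$y / cell))
  ni <- max(ci); nj <- max(cj)
  idx <- (cj - 1L) * ni + ci
  el <- numeric(ni * nj)
  agg <- rowsum(p$element_m, idx)
  el[as.integer(rownames(agg))] <- agg[, 1L]
  region$baseline$element_cell_threshold <-
    unname(quantile(el, spec$cooperation$element_density_quantile))
  region
}

#' One year of the cooperation/tourism adoption sub-model
#'
#' Each active non-multifunctional farmer censuses his `k` nearest active
#' farmers (Euclidean farmstead distance, ties by id; all available farmers
#' if fewer than `k` exist). If at least `threshold` of them are
#' diversified/multifunctional and a tourist asset (semi-natural parcel,
#' attraction, or above-threshold hedgerow density) lies within the search
#' radius of his farmstead, he adopts multifunctional farming with
#' probability `rate * (1 + tourism_increase) * tourism_demand`. The census
#' uses start-of-year management types only; adopters switch type
#' simultaneously at year end.
#'
#' @param region A `region` (with up-to-date farmer activity).
#' @param spec An [intervention_spec()] with cooperation enabled.
#' @param ctx A [decision_context()]; only used for its RNG stream when
#'   called standalone.
#' @return Integer vector of adopting farmer ids (possibly empty).
#' @export
cooperation_adoption_step <- function(region, spec, ctx = NULL) {
  co <- spec$cooperation
  f <- region$farmers
  region <- ensure_knn(region)
  cand <- region$knn
  act <- f$active
  is_mult <- f$type == "diversified_multifunctional"
  eligible <- which(act & !is_mult)
  if (!length(eligible)) return(integer(0))
  has_asset <- asset_lookup(region, spec)(f$x[eligible], f$y[eligible])
  active_by_id <- act; mult_by_id <- is_mult  # farmer ids are row numbers 1..n
  idmap <- match(seq_len(max(f$id)), f$id)
  n_mult_near <- vapply(seq_along(eligible), function(e) {
    i <- eligible[e]
    cs <- cand[i, ]
    cs <- cs[!is.na(cs)]
    ridx <- idmap[cs]
    a <- ridx[active_by_id[ridx]]
    a <- head(a, co$k)
    sum(mult_by_id[a])
  }, integer(1))
  p_adopt <- min(1, co$rate * (1 + co$tourism_increase) * region$tourism_demand)
  u <- runif(length(eligible))
  adopting <- eligible[n_mult_near >= co$threshold & has_asset & u < p_adopt]
  f$id[adopting]
}

#' Apply the in-migration intervention to market parameters
#'
#' Raises the estate purchase probability to the intervention's
#' `purchase_prob` and lowers the aesthetic qualification threshold. The
#' supply side is untouched: migrant purchases remain bounded by the
#' qualifying offers of each year.
#'
#' @param spec An [intervention_spec()] with inmigration enabled.
#' @param market The `market` parameter block of a scenario.
#' @return The modified market block.
#' @export
apply_inmigration <- function(spec, market) {
  if (!isTRUE(spec$inmigration$enabled)) return(market)
  market$p_estate <- spec$inmigration$purchase_prob
  market$estate_aesthetic_min <- spec$inmigration$aesthetic_threshold
  market
}
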