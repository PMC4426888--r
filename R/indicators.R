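INDICATOR_FIELDS <- c("year", "total_farmers", "avg_farm_size", "total_agri",
                      "pct_multifunctional", "pct_residents",
                      "element_pct_change", "semi_natural",
                      "avg_max_distance")

#' Compute the yearly indicator record of a region
#'
#' The indicator suite tracked per simulated year: total farmer count,
#' average farm size (agricultural area / farmer count, ha), total
#' agricultural area (ha), percentage of diversified/multifunctional
#' farmers, rural residents as a percentage of (farmers + residents), the
#' percentage change in total landscape-element length against the baseline,
#' semi-natural area (ha) and the mean over farmers of the straight-line
#' distance from farmstead to the farthest held parcel (km).
#'
#' @param region A `region`.
#' @param baseline The baseline `region` of the same generated geometry
#'   (supplies the reference element length).
#' @return One-row data.table with the nine indicator fields.
#' @export
compute_indicators <- function(region, baseline = region) {
  p <- region$parcels
  f <- region$farmers[region$farmers$active]
  nf <- nrow(f)
  nr <- nrow(region$residents)
  agri <- sum(p$area_ha[p$land_use == "agriculture"])
  l0 <- sum(baseline$parcels$element_m)
  lt <- sum(p$element_m)
  own <- p[owner_class == "farmer"]
  dmax <- NA_real_
  if (nrow(own) && nf) {
    fx <- f$x[match(own$owner_id, f$id)]
    fy <- f$y[match(own$owner_id, f$id)]
    d <- sqrt((own$x - fx)^2 + (own$y - fy)^2)
    dmax <- mean(tapply(d, own$owner_id, max)) / 1000
  }
  data.table(
    year = region$year,
    total_farmers = nf,
    avg_farm_size = if (nf) agri / nf else NA_real_,
    total_agri = agri,
    pct_multifunctional = if (nf)
      100 * sum(f$type == "diversified_multifunctional") / nf else NA_real_,
    pct_residents = if (nf + nr) 100 * nr / (nf + nr) else 0,
    element_pct_change = if (l0 > 0) 100 * (lt - l0) / l0 else NA_real_,
    semi_natural = sum(p$area_ha[p$land_use == "semi_natural"]),
    avg_max_distance = dmax)
}

#' Compare two indicator series
#'
#' Per-year signed differences (`a - b`) for every indicator, plus a
#' final-year summary row. Antisymmetric: `compare_runs(a, b)` equals
#' `-compare_runs(b, a)` in all difference columns.
#'
#' @param records_a,records_b data.tables of indicator records covering the
#'   same years (e.g. stacked [compute_indicators()] rows or an experiment's
#'   mean series).
#' @return data.table of per-year differences with attribute `"final"`
#'   holding the final-year difference row.
#' @export
compare_runs <- function(records_a, records_b) {
  a <- as.data.table(records_a); b <- as.data.table(records_b)
  if (!identical(sort(a$year), sort(b$year)))
    stopf("indicator series cover different year ranges")
  setorder(a, year); setorder(b, year)
  cols <- setdiff(intersect(names(a), names(b)), "year")
  cols <- cols[vapply(cols, function(cn) is.numeric(a[[cn]]), logical(1))]
  d <- data.table(year = a$year)
  for (cn in cols) d[[cn]] <- a[[cn]] - b[[cn]]
  structure(d, final = d[nrow(d)])
}

# --- map export --------------------------------------------------------------

LAND_USE_CODES <- c(agriculture = 1, semi_natural = 2, residential = 3)

region_grid_values <- function(region, layer, baseline = NULL) {
  p <- region$parcels
  switch(layer,
         land_use = unname(LAND_USE_CODES[p$land_use]),
         element_density = p$element_m / p$area_ha,
         zones = (p$z_protect * 1 + p$z_habitat * 2 + p$z_agridev * 4 +
                    p$z_leader * 8 + p$z_pilot * 16 + p$z_attraction * 32),
         change_vs = {
           if (is.null(baseline)) stopf("layer `change_vs` needs a baseline region")
           p$element_m - baseline$parcels$element_m[match(p$id, baseline$parcels$id)]
         },
         stopf("unknown map layer `%s`", layer))
}

write_esri_ascii <- function(values, region, path) {
  g <- region$grid
  m <- matrix(NA_real_, g$ny, g$nx)
  p <- region$parcels
  col <- as.integer(round(p$x / g$cell_m + 0.5))
  row <- as.integer(round(p$y / g$cell_m + 0.5))
  m[cbind(row, col)] <- values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", g$nx), sprintf("nrows %d", g$ny),
               "xllcorner 0", "yllcorner 0",
               sprintf("cellsize %.17g", g$cell_m),
               "NODATA_value -9999"), con)
  # ESRI ASCII rows run north to south; %.17g keeps doubles exact round-trip
  for (r in rev(seq_len(g$ny))) {
    row_v <- m[r, ]
    row_v[is.na(row_v)] <- -9999
    writeLines(paste(sprintf("%.17g", row_v), collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid written by [export_map()]
#'
#' @param path File path.
#' @return A numeric matrix (rows south to north, as stored in the region
#'   grid), with `NA` for NODATA cells, and attributes `cellsize`.
#' @export
read_esri_ascii <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(hdr, "\\s+"))
  meta <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  dat <- scan(path, skip = 6L, quiet = TRUE)
  m <- matrix(dat, nrow = meta[["nrows"]], ncol = meta[["ncols"]],
              byrow = TRUE)
  m[m == meta[["nodata_value"]]] <- NA_real_
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]  # back to south-to-north rows
  attr(m, "cellsize") <- meta[["cellsize"]]
  m
}

#' Export a region layer as a map file
#'
#' Grid layers (`land_use`, `element_density`, `zones`, `change_vs`) are
#' written as ESRI ASCII grids (plain text, exact round-trip); the parcel
#' table can be written as GeoJSON square polygons or CSV.
#'
#' @param region A `region`.
#' @param layer One of `"land_use"`, `"element_density"`, `"zones"`,
#'   `"change_vs"` (element change against `baseline`).
#' @param path Output file path.
#' @param format `"asc"` (ESRI ASCII grid), `"geojson"` or `"csv"`.
#' @param baseline Baseline region, required for `layer = "change_vs"`.
#' @return `path`, invisibly.
#' @export
export_map <- function(region, layer, path,
                       format = c("asc", "geojson", "csv"), baseline = NULL) {
  format <- match.arg(format)
  values <- region_grid_values(region, layer, baseline)
  if (format == "asc") return(write_esri_ascii(values, region, path))
  p <- region$parcels
  if (format == "csv") {
    fwrite(data.table(id = p$id, x = p$x, y = p$y, value = values), path)
    return(invisible(path))
  }
  h <- region$grid$cell_m / 2
  feats <- lapply(seq_len(nrow(p)), function(i) {
    ring <- list(c(p$x[i] - h, p$y[i] - h), c(p$x[i] + h, p$y[i] - h),
                 c(p$x[i] + h, p$y[i] + h), c(p$x[i] - h, p$y[i] + h),
                 c(p$x[i] - h, p$y[i] - h))
    list(type = "Feature",
         properties = list(id = p$id[i], layer = layer, value = values[i]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
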