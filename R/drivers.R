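#' Indicator metadata
#'
#' Each degradation driver indicator carries a name, a driver group, a
#' measurement unit and an orientation. Orientation states how the raw
#' indicator relates to degradation pressure: `direct` indicators read
#' "larger value = stronger influence"; `inverse` indicators (e.g. annual
#' total precipitation, distances to built-up features) read the opposite
#' and are flipped by [orient()] after normalization.
#'
#' [default_indicators()] returns the twelve-indicator set used by default:
#' two natural (annual mean temperature, annual total precipitation), two
#' human-activity (population density, sheep density), four economic
#' (primary/secondary/tertiary/total GDP density) and four urbanisation
#' indicators (distance to urban land, rural settlements, roads, other
#' built-up land). The inverse set is precipitation plus the four
#' distances.
#'
#' @param name,group,unit,orientation Character vectors of equal length;
#'   `group` must be one of `natural`, `human`, `economic`, `urbanisation`;
#'   `orientation` one of `direct`, `inverse`.
#' @return A tibble of class `indicator_meta`.
#' @export
indicator_meta <- function(name, group, unit = NA_character_,
                           orientation = "direct") {
  groups <- c("natural", "human", "economic", "urbanisation")
  orientations <- c("direct", "inverse")
  out <- tibble::tibble(
    name = as.character(name),
    group = as.character(group),
    unit = rep_len(as.character(unit), length(name)),
    orientation = rep_len(as.character(orientation), length(name))
  )
  if (anyDuplicated(out$name)) abort("indicator names must be unique")
  if (!all(out$group %in% groups)) abort("invalid driver group")
  if (!all(out$orientation %in% orientations)) abort("orientation must be direct or inverse")
  class(out) <- c("indicator_meta", class(out))
  out
}

#' @rdname indicator_meta
#' @export
default_indicators <- function() {
  indicator_meta(
    name = c("annual_mean_temperature", "annual_total_precipitation",
             "population_density", "sheep_density",
             "primary_gdp_density", "secondary_gdp_density",
             "tertiary_gdp_density", "gdp_density",
             "dist_to_urban_land", "dist_to_rural_settlements",
             "dist_to_roads", "dist_to_other_builtup"),
    group = c("natural", "natural", "human", "human",
              "economic", "economic", "economic", "economic",
              "urbanisation", "urbanisation", "urbanisation", "urbanisation"),
    unit = c("degC", "mm", "persons km-2", "heads km-2",
             "1e4 CNY km-2", "1e4 CNY km-2", "1e4 CNY km-2", "1e4 CNY km-2",
             "km", "km", "km", "km"),
    orientation = c("direct", "inverse", "direct", "direct",
                    "direct", "direct", "direct", "direct",
                    "inverse", "inverse", "inverse", "inverse")
  )
}

#' Units-by-indicators driver tables
#'
#' A driver table holds one row per areal unit (banner/county) and one
#' column per indicator, with indicator metadata and an epoch label
#' attached. It is the tabular input of the partial-order pipeline.
#'
#' @param data A data frame with a `unit_id` column and one numeric column
#'   per indicator in `meta`.
#' @param meta An [indicator_meta()] describing the indicator columns.
#' @param epoch Period label (free text, e.g. `"1990-2000"`).
#' @return A tibble of class `driver_table`.
#' @export
driver_table <- function(data, meta = default_indicators(), epoch = NA_character_) {
  data <- tibble::as_tibble(data)
  if (!"unit_id" %in% names(data)) abort("data must have a unit_id column")
  if (anyDuplicated(data$unit_id)) abort("unit ids must be unique")
  missing <- setdiff(meta$name, names(data))
  if (length(missing)) {
    abort(paste0("indicator columns missing from data: ", paste(missing, collapse = ", ")))
  }
  out <- data[, c("unit_id", meta$name)]
  attr(out, "meta") <- meta
  attr(out, "epoch") <- epoch
  class(out) <- c("driver_table", class(out))
  out
}

indicator_names <- function(table) attr(table, "meta")$name

#' @export
print.driver_table <- function(x, ...) {
  cat(sprintf("<%s> %d units x %d indicators, epoch %s%s\n",
              class(x)[1], nrow(x), length(indicator_names(x)),
              attr(x, "epoch") %||% "?",
              if (isTRUE(attr(x, "oriented"))) ", oriented" else ""))
  NextMethod()
}

#' Zonal mean of a raster over administrative units
#'
#' Averages a continuous raster within each zone of an integer zone map,
#' ignoring `NA` cells — the standard "zonal statistics" step that turns a
#' driver surface into one value per county.
#'
#' @param raster Numeric matrix.
#' @param zones Integer matrix of the same shape; each cell holds the id of
#'   the unit it belongs to.
#' @param unit_ids Units to report (default: all ids present in `zones`).
#'   Every requested unit must occur in the zone map.
#' @return A tibble with columns `unit_id` and `value`.
#' @export
zonal_mean <- function(raster, zones, unit_ids = NULL) {
  if (!identical(dim(raster), dim(zones))) abort("raster and zone map differ in shape")
  if (is.null(unit_ids)) unit_ids <- sort(unique(c(zones)))
  absent <- setdiff(unit_ids, c(zones))
  if (length(absent)) {
    abort(paste0("units absent from zone map: ", paste(absent, collapse = ", ")))
  }
  vals <- purrr::map_dbl(unit_ids, function(u) {
    v <- raster[zones == u]
    v <- v[!is.na(v)]
    if (!length(v)) abort(paste0("zone ", u, " has no valid raster cells"))
    mean(v)
  })
  tibble::tibble(unit_id = unit_ids, value = vals)
}

#' Inverse-distance-weighted interpolation of station samples
#'
#' Fills a regular grid from scattered point samples with the classic IDW
#' estimator: the value at a cell centre is the weighted mean of all sample
#' values with weights `d^-power`, where `d` is the distance to each
#' sample. A cell whose centre coincides with a sample point takes the
#' sample value exactly.
#'
#' @param samples Data frame with columns `x`, `y`, `value` (>= 1 row,
#'   finite coordinates).
#' @param nrow,ncol Grid dimensions.
#' @param cellsize Cell side length (same units as `x`, `y`).
#' @param xmin,ymin Coordinates of the grid's lower-left corner. Cell
#'   centres sit at `xmin + (col - 0.5) * cellsize` and
#'   `ymin + (row - 0.5) * cellsize`, with row 1 the top row.
#' @param power IDW power (> 0); 2 is the conventional default.
#' @return A numeric `nrow` x `ncol` matrix.
#' @export
idw_interpolate <- function(samples, nrow, ncol, cellsize = 1,
                            xmin = 0, ymin = 0, power = 2) {
  samples <- tibble::as_tibble(samples)
  if (nrow(samples) < 1) abort("need at least one sample")
  if (!all(is.finite(samples$x)) || !all(is.finite(samples$y))) {
    abort("sample coordinates must be finite")
  }
  if (power <= 0) abort("power must be positive")
  cx <- xmin + (seq_len(ncol) - 0.5) * cellsize
  cy <- ymin + (nrow - seq_len(nrow) + 0.5) * cellsize
  out <- matrix(NA_real_, nrow, ncol)
  for (i in seq_len(nrow)) {
    for (j in seq_len(ncol)) {
      d <- sqrt((samples$x - cx[j])^2 + (samples$y - cy[i])^2)
      hit <- which(d == 0)
      if (length(hit)) {
        out[i, j] <- samples$value[hit[1]]
      } else {
        w <- d^(-power)
        out[i, j] <- sum(w * samples$value) / sum(w)
      }
    }
  }
  out
}

#' Min-max normalization of a driver table
#'
#' Rescales every indicator column to `[0, 1]` by
#' `(v - min) / (max - min)`, so the column minimum maps to 0 and the
#' maximum to 1. A constant column, which carries no ordering information,
#' maps to 0.5 everywhere (a neutral value that leaves pairwise
#' comparisons unaffected).
#'
#' @param table A [driver_table()].
#' @return A `normalized_table` (a driver table whose values lie in
#'   `[0, 1]`, with `oriented = FALSE`).
#' @export
normalize <- function(table) {
  if (nrow(table) < 1) abort("table is empty")
  out <- table
  for (col in indicator_names(table)) {
    v <- table[[col]]
    rng <- range(v)
    out[[col]] <- if (rng[1] == rng[2]) rep(0.5, length(v)) else (v - rng[1]) / (rng[2] - rng[1])
  }
  attr(out, "oriented") <- FALSE
  class(out) <- c("normalized_table", class(table))
  out
}

#' Orient a normalized table so larger always means stronger influence
#'
#' Flips every inverse-orientation indicator by `v -> 1 - v`, after which
#' every column reads "larger value = stronger degradation influence".
#' Orienting an already-oriented table is an error, since the flip is an
#' involution and a second application would silently undo it.
#'
#' @param table A `normalized_table` from [normalize()].
#' @param meta Indicator metadata; defaults to the table's own.
#' @return The oriented `normalized_table` (`oriented = TRUE`).
#' @export
orient <- function(table, meta = attr(table, "meta")) {
  if (!inherits(table, "normalized_table")) abort("orient() expects a normalized table")
  if (isTRUE(attr(table, "oriented"))) abort("table is already oriented")
  out <- table
  for (col in meta$name[meta$orientation == "inverse"]) {
    out[[col]] <- 1 - out[[col]]
  }
  attr(out, "oriented") <- TRUE
  out
}

#' Pearson collinearity screen between two driver groups
#'
#' Computes pairwise Pearson correlations between every indicator of one
#' group and every indicator of another, flagging pairs at or above a
#' threshold (0.7 by default, the conventional point where collinearity
#' starts to distort joint rankings). Pairs involving a zero-variance
#' column have undefined `r` and are flagged.
#'
#' @param table A [driver_table()] (raw or normalized).
#' @param group_a,group_b Driver group names.
#' @param threshold Absolute correlation at or above which a pair is
#'   flagged.
#' @return A tibble with columns `indicator_a`, `indicator_b`, `r`,
#'   `flagged`.
#' @export
collinearity_screen <- function(table, group_a, group_b, threshold = 0.7) {
  meta <- attr(table, "meta")
  cols_a <- meta$name[meta$group == group_a]
  cols_b <- meta$name[meta$group == group_b]
  if (!length(cols_a) || !length(cols_b)) abort("both groups must be present in the table")
  if (nrow(table) < 3) abort("need at least 3 units for a correlation screen")
  tidyr::expand_grid(indicator_a = cols_a, indicator_b = cols_b) |>
    dplyr::mutate(
      r = purrr::map2_dbl(.data$indicator_a, .data$indicator_b, function(a, b) {
        va <- table[[a]]; vb <- table[[b]]
        if (stats::sd(va) == 0 || stats::sd(vb) == 0) NA_real_ else cor(va, vb)
      }),
      flagged = is.na(.data$r) | abs(.data$r) >= threshold
    )
}

#' Read and write driver tables as CSV with a JSON metadata sidecar
#'
#' The CSV holds units as rows (`unit_id` first) and indicators as
#' columns; the sidecar (`<path>.meta.json`) stores the indicator
#' metadata, the epoch, and the normalized/oriented state.
#'
#' @param table A [driver_table()] or `normalized_table`.
#' @param path CSV file path.
#' @return `read_driver_table()` returns the reconstructed table;
#'   `write_driver_table()` returns `path` invisibly.
#' @export
write_driver_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  meta <- attr(table, "meta")
  jsonlite::write_json(
    list(
      epoch = attr(table, "epoch"),
      normalized = inherits(table, "normalized_table"),
      oriented = isTRUE(attr(table, "oriented")),
      indicators = as.data.frame(meta)
    ),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_driver_table
#' @export
read_driver_table <- function(path) {
  data <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  side <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  meta <- indicator_meta(side$indicators$name, side$indicators$group,
                         side$indicators$unit, side$indicators$orientation)
  out <- driver_table(data, meta = meta, epoch = side$epoch %||% NA_character_)
  if (isTRUE(side$normalized)) {
    attr(out, "oriented") <- isTRUE(side$oriented)
    class(out) <- c("normalized_table", class(out))
  }
  out
}
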