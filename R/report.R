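#' Export a Hasse diagram as Graphviz DOT
#'
#' Writes the cover DAG in DOT format with one `rank = same` cluster per
#' level (top level first), edges drawn from the lower to the higher
#' element, and isolated elements styled with a dashed outline.
#'
#' @param h A [hasse_diagram()].
#' @param path Output file.
#' @param name Graph name.
#' @return `path`, invisibly.
#' @export
write_dot <- function(h, path, name = "hasse") {
  q <- function(x) paste0("\"", x, "\"")
  lines <- c(
    paste0("digraph ", q(name), " {"),
    "  rankdir=BT;",
    "  node [shape=box, style=rounded];"
  )
  for (e in h$poset$elements) {
    attrs <- sprintf("label=\"%s\\nlevel %d\"", e, h$levels[[e]])
    if (e %in% h$isolated) attrs <- paste0(attrs, ", style=\"rounded,dashed\"")
    lines <- c(lines, sprintf("  %s [%s];", q(e), attrs))
  }
  for (l in rev(seq_len(h$L))) {
    at <- names(h$levels)[h$levels == l]
    lines <- c(lines, sprintf("  { rank=same; %s }", paste(q(at), collapse = "; ")))
  }
  if (nrow(h$covers)) {
    lines <- c(lines, sprintf("  %s -> %s;", q(h$covers$from), q(h$covers$to)))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' Write Hasse diagram cover edges as CSV
#'
#' @param h A [hasse_diagram()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cover_edges <- function(h, path) {
  write.csv(as.data.frame(h$covers), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration files
#'
#' Reads a YAML run configuration and fills unset fields with package
#' defaults. Recognised fields: `seed`, `n_units`, `grid_shape`, `delta`,
#' `sigma`, `tol` (comparison tie tolerance), `method` (dominance scoring
#' method), `tie_tol` (dominance tie tolerance), `power` (IDW power) and
#' `out_dir`. Explicit function arguments override config values, which
#' override the defaults.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return A named list of configuration values.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(seed = 1L, n_units = 20L, grid_shape = c(50L, 50L),
                   delta = 0.5, sigma = 0.05, tol = 0,
                   method = "level_height", tie_tol = 0, power = 2,
                   out_dir = ".")
  if (is.null(path)) return(defaults)
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg), names(defaults))
  if (length(bad)) abort(paste0("unknown config fields: ", paste(bad, collapse = ", ")))
  utils::modifyList(defaults, cfg)
}

# internal Esri ASCII primitives shared by land grids and zone maps
write_esri_ascii <- function(values, path, cellsize = 1, nodata = -9999L,
                             xll = 0, yll = 0) {
  hdr <- c(paste("ncols", ncol(values)), paste("nrows", nrow(values)),
           paste("xllcorner", xll), paste("yllcorner", yll),
           paste("cellsize", cellsize), paste("NODATA_value", nodata))
  writeLines(c(hdr, apply(values, 1, paste, collapse = " ")), path)
  invisible(path)
}

read_ascii_grid_raw <- function(path) {
  lines <- readLines(path)
  hdr <- list(); i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  for (key in c("ncols", "nrows", "cellsize")) {
    if (is.null(hdr[[key]])) abort(paste0("missing ASCII grid header field: ", key))
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    abort("ASCII grid body does not match header dimensions")
  }
  list(values = matrix(as.integer(vals), nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE),
       cellsize = hdr$cellsize, nodata = as.integer(hdr[["nodata_value"]] %||% -9999))
}

#' Generate and write a synthetic bundle
#'
#' Runs the synthetic-data generators for a scenario and writes the
#' bundle to `out_dir` in the same formats the pipeline reads: the zone
#' map and both land-cover epochs as Esri ASCII grids, the raw driver
#' table as CSV with its JSON metadata sidecar, the unit -> region map as
#' CSV (regions are the row bands of the zone layout) and the ground
#' truth as JSON. Reruns with the same seed produce byte-identical files.
#'
#' @param cfg A [scenario_config()].
#' @param out_dir Output directory (created if missing).
#' @return The [gen_bundle()] result, invisibly.
#' @export
run_simulate <- function(cfg = scenario_config(), out_dir = ".") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- gen_bundle(cfg)
  cs <- sqrt(cfg$cell_area)
  write_esri_ascii(bundle$zone_map, file.path(out_dir, "zones.asc"), cellsize = cs)
  write_ascii_grid(bundle$landcover$a,
                   file.path(out_dir, sprintf("landcover_%d.asc", cfg$period[1])))
  write_ascii_grid(bundle$landcover$b,
                   file.path(out_dir, sprintf("landcover_%d.asc", cfg$period[2])))
  write_driver_table(bundle$drivers, file.path(out_dir, "drivers.csv"))
  write.csv(data.frame(unit_id = cfg$unit_ids,
                       region = region_bands(bundle$zone_map, cfg$unit_ids)),
            file.path(out_dir, "regions.csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(bundle$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(bundle)
}

# label units by the row band of the zone layout; a stand-in for the
# league/prefecture grouping above counties
region_bands <- function(zones, unit_ids) {
  first_row <- purrr::map_int(seq_along(unit_ids),
                              \(u) which(apply(zones == u, 1, any))[1])
  band <- as.integer(factor(first_row))
  sprintf("R%d", band)
}

#' Land-cover change accounting from grid files
#'
#' Reads two land-cover epochs (Esri ASCII), optionally reclassifies them
#' with a fine-to-major CSV map, and writes the transition matrix (CSV
#' and JSON), the per-cell change map (ASCII grid coded 0 stable, 1
#' degradation, 2 restoration, 3 other change), the degradation and
#' restoration areas/annual rates (CSV) and a headline loss/gain summary
#' (JSON).
#'
#' @param path_a,path_b ASCII grid files, earlier epoch first.
#' @param out_dir Output directory.
#' @param reclass Optional path to a reclassification CSV
#'   (see [read_reclass_map()]).
#' @param scheme A [class_scheme()].
#' @param epochs Length-2 integer vector of epoch years.
#' @return The [change_rates()] tibble, invisibly.
#' @export
run_change <- function(path_a, path_b, out_dir = ".", reclass = NULL,
                       scheme = default_scheme(), epochs = c(NA, NA)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  a <- read_ascii_grid(path_a, scheme = scheme, epoch = epochs[1])
  b <- read_ascii_grid(path_b, scheme = scheme, epoch = epochs[2])
  if (!is.null(reclass)) {
    map <- read_reclass_map(reclass, scheme = scheme)
    a <- reclassify(a, map, scheme = scheme)
    b <- reclassify(b, map, scheme = scheme)
  }
  tm <- transition_matrix(a, b)
  cm <- classify_change(a, b)
  rates <- change_rates(cm)
  write_transition_matrix(tm, file.path(out_dir, "transition_matrix.csv"))
  write_transition_matrix(tm, file.path(out_dir, "transition_matrix.json"))
  codes <- c(stable = 0L, degradation = 1L, restoration = 2L,
             other_change = 3L, nodata = -9999L)
  write_esri_ascii(matrix(codes[unclass(cm)], nrow(cm)),
                   file.path(out_dir, "change_map.asc"),
                   cellsize = sqrt(attr(cm, "cell_area")))
  write.csv(as.data.frame(rates), file.path(out_dir, "change_rates.csv"),
            row.names = FALSE, quote = FALSE)
  jsonlite::write_json(summarize_transitions(tm),
                       file.path(out_dir, "transition_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(rates)
}

#' Partial-order ranking and dominant-driver attribution from a table file
#'
#' Reads a raw driver table (CSV plus JSON sidecar), normalizes and
#' orients it, builds one Hasse diagram per driver group and writes, per
#' group, the normalized column values, the rank table (level, S/P/U
#' counts, LPOM0 average rank) and the diagram as DOT and edge-list CSV.
#' Unit-level group scores, the dominant group(s) per unit and — when a
#' unit -> region map is supplied — the region-by-group dominance counts
#' are written alongside.
#'
#' @param drivers_csv Driver table CSV written by [write_driver_table()].
#' @param out_dir Output directory.
#' @param region_csv Optional CSV with columns `unit_id`, `region`.
#' @param tol Comparison tie tolerance (see [build_poset()]).
#' @param method Dominance scoring method (see [group_height_scores()]).
#' @param tie_tol Dominance tie tolerance (see [dominant_groups()]).
#' @return A list with `diagrams`, `scores` and `dominance`, invisibly.
#' @export
run_rank <- function(drivers_csv, out_dir = ".", region_csv = NULL,
                     tol = 0, method = "level_height", tie_tol = 0) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  raw <- read_driver_table(drivers_csv)
  oriented <- if (inherits(raw, "normalized_table")) {
    if (isTRUE(attr(raw, "oriented"))) raw else orient(raw)
  } else {
    orient(normalize(raw))
  }
  write_driver_table(oriented, file.path(out_dir, "drivers_oriented.csv"))
  diagrams <- group_diagrams(oriented, tol = tol)
  for (g in names(diagrams)) {
    h <- diagrams[[g]]
    write.csv(as.data.frame(rank_table(h)),
              file.path(out_dir, sprintf("rank_%s.csv", g)),
              row.names = FALSE, quote = FALSE)
    write_dot(h, file.path(out_dir, sprintf("hasse_%s.dot", g)), name = g)
    write_cover_edges(h, file.path(out_dir, sprintf("covers_%s.csv", g)))
  }
  scores <- group_height_scores(diagrams, method = method)
  dom <- dominant_groups(scores, tie_tol = tie_tol)
  write.csv(as.data.frame(scores), file.path(out_dir, "group_scores.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(as.data.frame(dom[, c("unit_id", "dominant_label")]),
            file.path(out_dir, "dominance.csv"), row.names = FALSE, quote = FALSE)
  if (!is.null(region_csv)) {
    region_map <- read.csv(region_csv, stringsAsFactors = FALSE)
    counts <- region_summary(dom, region_map,
                             groups = unique(attr(raw, "meta")$group))
    write.csv(as.data.frame(counts), file.path(out_dir, "region_dominance.csv"),
              row.names = FALSE, quote = FALSE)
  }
  invisible(list(diagrams = diagrams, scores = scores, dominance = dom))
}
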