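#' Reclassify a land-cover grid to major categories
#'
#' Applies a fine-to-major [reclass_map()] cell-by-cell. Nodata cells are
#' preserved, and the epoch and cell area carry over unchanged.
#'
#' @param grid A [land_grid()] holding fine class codes. Its scheme is the
#'   fine scheme (or the major scheme itself for an identity map).
#' @param map A [reclass_map()]; every non-nodata code in `grid` must have
#'   an entry.
#' @param scheme The major [class_scheme()] of the output.
#'
#' @return A [land_grid()] over `scheme`.
#' @export
reclassify <- function(grid, map, scheme = default_scheme()) {
  v <- grid$values
  valid <- v != grid$nodata
  idx <- match(v[valid], map$fine_code)
  if (anyNA(idx)) {
    missing <- v[valid][is.na(idx)]
    tab <- sort(table(missing), decreasing = TRUE)
    abort(paste0(
      "unmapped fine codes: ",
      paste(sprintf("%s (%d cells)", names(tab), as.integer(tab)), collapse = ", ")
    ))
  }
  out <- v
  out[valid] <- map$major_code[idx]
  land_grid(out, scheme = scheme, nodata = grid$nodata,
            cell_area = grid$cell_area, epoch = grid$epoch)
}

#' Land-cover transition matrix between two epochs
#'
#' Cross-tabulates the two grids cell-by-cell: entry (i, j) is the area (in
#' km^2) that moved from class i in the first epoch to class j in the
#' second. Cells that are nodata in either epoch are excluded everywhere,
#' so row sums equal the first-epoch class areas over jointly valid cells
#' and the grand total equals the jointly valid area.
#'
#' @param a,b [land_grid()]s sharing shape, scheme and cell area;
#'   `a` is the earlier epoch.
#'
#' @return An object of class `transition_matrix`: a list with `areas`
#'   (named n x n matrix, km^2), `scheme`, and `period = c(a$epoch, b$epoch)`.
#' @export
#' @examples
#' g1 <- land_grid(matrix(c(3L, 3L, 3L, 2L), 2), epoch = 1990)
#' g2 <- land_grid(matrix(c(3L, 1L, 3L, 2L), 2), epoch = 2000)
#' transition_matrix(g1, g2)$areas
transition_matrix <- function(a, b) {
  check_grid_pair(a, b)
  ok <- grid_valid(a) & grid_valid(b)
  f <- factor(a$values[ok], levels = a$scheme$code)
  t <- factor(b$values[ok], levels = a$scheme$code)
  areas <- table(f, t) * a$cell_area
  areas <- matrix(as.numeric(areas), nrow = nrow(a$scheme),
                  dimnames = list(from = a$scheme$name, to = a$scheme$name))
  structure(
    list(areas = areas, scheme = a$scheme, period = c(a$epoch, b$epoch)),
    class = "transition_matrix"
  )
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %s-%s, total %g km2\n",
              x$period[1], x$period[2], sum(x$areas)))
  print(round(x$areas, 3))
  invisible(x)
}

#' Tidy a transition matrix into long form
#'
#' @param x A [transition_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `from`, `to`, `area_km2`.
#' @export
tidy.transition_matrix <- function(x, ...) {
  as.data.frame.table(x$areas, responseName = "area_km2") |>
    tibble::as_tibble() |>
    dplyr::mutate(from = as.character(.data$from), to = as.character(.data$to))
}

#' Classify per-cell change as degradation, restoration or other
#'
#' Labels every jointly valid cell by comparing its class in the two
#' epochs: `degradation` when a degradation source class (grassland, forest
#' or water bodies under the default scheme) converts to a degradation
#' target class (cropland, bare areas or impervious surfaces);
#' `restoration` when cropland or bare areas convert to grassland, forest
#' or water bodies; `stable` when the class is unchanged; `other_change`
#' otherwise. Cells nodata in either epoch are `nodata`.
#'
#' @inheritParams transition_matrix
#' @return An object of class `change_map`: a character matrix of labels
#'   plus `cell_area` and `period` attributes.
#' @export
classify_change <- function(a, b) {
  check_grid_pair(a, b)
  sch <- a$scheme
  ld_src <- scheme_code(sch, attr(sch, "ld_sources"))
  ld_tgt <- scheme_code(sch, attr(sch, "ld_targets"))
  lr_src <- scheme_code(sch, attr(sch, "lr_sources"))
  lr_tgt <- scheme_code(sch, attr(sch, "lr_targets"))
  va <- a$values; vb <- b$values
  ok <- grid_valid(a) & grid_valid(b)
  lab <- matrix("other_change", nrow(va), ncol(va))
  lab[va == vb] <- "stable"
  lab[(va %in% ld_src) & (vb %in% ld_tgt)] <- "degradation"
  lab[(va %in% lr_src) & (vb %in% lr_tgt)] <- "restoration"
  lab[!ok] <- "nodata"
  structure(lab, class = "change_map", cell_area = a$cell_area,
            period = c(a$epoch, b$epoch))
}

#' @export
print.change_map <- function(x, ...) {
  cat(sprintf("<change_map> %d x %d cells, cell area %g km2\n",
              nrow(x), ncol(x), attr(x, "cell_area")))
  print(table(unclass(x)))
  invisible(x)
}

#' Degradation and restoration areas and annual change rates
#'
#' Aggregates a [classify_change()] map into period totals. The annual rate
#' is the changed fraction of the jointly valid area, spread evenly over
#' the period:
#' `rate = 100 * (changed area / total valid area) / period_years` (% per
#' year). Areas are gross totals for the period; no netting between the
#' two directions is applied.
#'
#' @param cm A `change_map`.
#' @param cell_area Cell area in km^2; defaults to the map's own.
#' @param period_years Period length in years (>= 1); defaults to the
#'   difference of the map's epochs when known.
#'
#' @return A one-row tibble of class `change_rates` with columns `ld_area`,
#'   `lr_area` (km^2), `ld_annual_rate`, `lr_annual_rate` (% per year),
#'   `period_years` and `total_area` (jointly valid, km^2).
#' @export
change_rates <- function(cm, cell_area = attr(cm, "cell_area"),
                         period_years = NULL) {
  if (is.null(period_years)) {
    p <- attr(cm, "period")
    if (is.null(p) || anyNA(p)) abort("period_years must be given when the map has no epochs")
    period_years <- diff(p)
  }
  if (period_years < 1) abort("period_years must be >= 1")
  lab <- unclass(cm)
  n_valid <- sum(lab != "nodata")
  if (n_valid == 0) abort("change map holds no valid cells")
  total <- n_valid * cell_area
  ld <- sum(lab == "degradation") * cell_area
  lr <- sum(lab == "restoration") * cell_area
  out <- tibble::tibble(
    ld_area = ld, lr_area = lr,
    ld_annual_rate = 100 * (ld / total) / period_years,
    lr_annual_rate = 100 * (lr / total) / period_years,
    period_years = as.integer(period_years),
    total_area = total
  )
  class(out) <- c("change_rates", class(out))
  out
}

#' Euclidean distance to the nearest cell of a class
#'
#' For every cell, the straight-line distance (km) from its centre to the
#' centre of the nearest cell holding `code`. Distances are planar,
#' cell-centre to cell-centre, with cell side `sqrt(cell_area)` km; source
#' cells get 0. Computed with an exact Euclidean distance transform.
#'
#' @param grid A [land_grid()].
#' @param code A class code present in the grid.
#' @return A numeric matrix of distances in km, same shape as the grid.
#' @export
distance_to_class <- function(grid, code) {
  code <- as.integer(code)
  if (!code %in% grid$scheme$code) abort("code is not in the grid's scheme")
  src <- grid$values == code
  if (!any(src)) abort(paste0("code ", code, " is absent from the grid"))
  mask <- matrix(1, nrow(src), ncol(src))
  mask[src] <- 0
  d <- EBImage::distmap(mask, metric = "euclidean")
  matrix(as.numeric(d), nrow(src)) * sqrt(grid$cell_area)
}

#' Summarize the largest class loss and gain of a period
#'
#' Reduces a [transition_matrix()] to the headline shape of a land-change
#' report row: the class with the largest net loss and the one with the
#' largest net gain, each with its change as a percentage of the jointly
#' valid area, plus that class's main transition partners.
#'
#' @param tm A [transition_matrix()].
#' @param n_partners How many main transition partners to list per class.
#' @return A list (JSON-ready) with elements `period`,
#'   `most_decreased` and `most_increased`; each class entry carries
#'   `name`, `change_percent`, and `main_transitions` (partner name and
#'   area in km^2).
#' @export
summarize_transitions <- function(tm, n_partners = 2) {
  A <- tm$areas
  total <- sum(A)
  net <- colSums(A) - rowSums(A)  # gain - loss per class
  dec <- which.min(net)
  inc <- which.max(net)
  partner <- function(i, outgoing) {
    v <- if (outgoing) A[i, ] else A[, i]
    v[i] <- 0
    v <- sort(v[v > 0], decreasing = TRUE)
    v <- head(v, n_partners)
    purrr::map2(names(v), unname(v), \(n, a) list(class = n, area_km2 = a))
  }
  list(
    period = as.list(tm$period),
    most_decreased = list(
      name = names(net)[dec],
      change_percent = 100 * net[[dec]] / total,
      main_transitions = partner(dec, outgoing = TRUE)
    ),
    most_increased = list(
      name = names(net)[inc],
      change_percent = 100 * net[[inc]] / total,
      main_transitions = partner(inc, outgoing = FALSE)
    )
  )
}

#' Write a transition matrix to CSV or JSON
#'
#' @param tm A [transition_matrix()].
#' @param path Output file; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_transition_matrix <- function(tm, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(period = tm$period, classes = tm$scheme$name,
           areas_km2 = unname(apply(tm$areas, 1, as.list))),
      path, auto_unbox = TRUE, digits = NA
    )
  } else {
    df <- cbind(from = rownames(tm$areas), as.data.frame(tm$areas))
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
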