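#' Build one Hasse diagram per driver group
#'
#' Splits an oriented normalized table by driver group and builds a
#' [hasse_diagram()] from each group's indicator columns — the per-group
#' partial orders whose level structure feeds dominant-driver scoring.
#'
#' @param table An oriented `normalized_table` with indicator metadata.
#' @param tol Tie tolerance passed to [build_poset()].
#' @return A named list of `hasse_diagram`s, one per driver group present
#'   in the metadata.
#' @export
group_diagrams <- function(table, tol = 0) {
  meta <- attr(table, "meta")
  if (is.null(meta)) abort("table has no indicator metadata")
  groups <- unique(meta$group)
  setNames(
    purrr::map(groups, \(g) hasse_diagram(table, group = g, tol = tol)),
    groups
  )
}

#' Per-unit influence scores from group Hasse diagrams
#'
#' Scores every unit's position in each driver group's Hasse diagram on a
#' common `[0, 1]` scale: units at higher levels are dominated by fewer
#' units and are read as more strongly influenced by that driver group.
#'
#' Two methods are available: `level_height` rescales the top-down level,
#' `(level - 1) / (L - 1)`; `lpom_norm` rescales the LPOM0 average rank,
#' `(Rav - 1) / (N - 1)`. A degenerate diagram (a single level, or a
#' single element) carries no ordering information and scores 0.5 for
#' every unit, so a structureless group neither wins nor loses.
#'
#' @param diagrams Named list of [hasse_diagram()]s (one per driver
#'   group) over an identical unit universe, e.g. from [group_diagrams()].
#' @param method `"level_height"` (default) or `"lpom_norm"`.
#' @return A tibble of class `group_scores` with a `unit_id` column and
#'   one score column per group; all scores in `[0, 1]`.
#' @export
group_height_scores <- function(diagrams, method = c("level_height", "lpom_norm")) {
  method <- match.arg(method)
  units <- sort(unlist(diagrams[[1]]$poset$members, use.names = FALSE))
  for (g in names(diagrams)) {
    ug <- sort(unlist(diagrams[[g]]$poset$members, use.names = FALSE))
    if (!identical(ug, units)) abort(paste0("group ", g, " covers a different unit set"))
  }
  out <- tibble::tibble(unit_id = units)
  for (g in names(diagrams)) {
    h <- diagrams[[g]]
    if (method == "level_height") {
      elem_score <- if (h$L == 1) {
        setNames(rep(0.5, length(h$levels)), names(h$levels))
      } else {
        (h$levels - 1) / (h$L - 1)
      }
    } else {
      rk <- lpom_average_rank(h$poset)
      N <- nrow(rk)
      elem_score <- if (N == 1) {
        setNames(0.5, rk$element)
      } else {
        setNames((rk$Rav - 1) / (N - 1), rk$element)
      }
    }
    ms <- h$poset$members
    unit_score <- setNames(unname(elem_score[rep(names(ms), lengths(ms))]),
                           unlist(ms, use.names = FALSE))
    out[[g]] <- unname(unit_score[units])
  }
  attr(out, "method") <- method
  class(out) <- c("group_scores", class(out))
  out
}

#' Dominant driver group(s) per unit
#'
#' A driver group is dominant for a unit when its score is within
#' `tie_tol` of the unit's best score; with `tie_tol = 0` this is the
#' argmax set, and co-dominance arises only from exact score ties.
#'
#' @param gs A [group_height_scores()] result.
#' @param tie_tol Non-negative tolerance below the maximum score within
#'   which a group still counts as dominant.
#' @return A tibble of class `dominance_result` with columns `unit_id`,
#'   `dominant` (list of group names, always non-empty) and
#'   `dominant_label` (groups joined with `"+"`).
#' @export
dominant_groups <- function(gs, tie_tol = 0) {
  if (tie_tol < 0) abort("tie_tol must be >= 0")
  groups <- setdiff(names(gs), "unit_id")
  scores <- as.matrix(as.data.frame(gs)[, groups, drop = FALSE])
  dom <- purrr::map(seq_len(nrow(scores)), function(i) {
    s <- scores[i, ]
    groups[s >= max(s) - tie_tol]
  })
  out <- tibble::tibble(
    unit_id = gs$unit_id,
    dominant = dom,
    dominant_label = purrr::map_chr(dom, paste, collapse = "+")
  )
  class(out) <- c("dominance_result", class(out))
  out
}

#' Count dominant driver groups per region
#'
#' Tallies, for each region, how many units have each driver group in
#' their dominant set. Units with several dominant groups contribute one
#' count to each, so a region's counts sum to at least its unit count.
#'
#' @param dr A [dominant_groups()] result.
#' @param region_map Data frame with columns `unit_id`, `region` (or a
#'   named character vector unit -> region) covering every unit.
#' @param groups Column order of the output; defaults to the groups seen
#'   in `dr`.
#' @return A tibble with one row per region and one count column per
#'   group.
#' @export
region_summary <- function(dr, region_map, groups = NULL) {
  if (!is.data.frame(region_map)) {
    region_map <- tibble::tibble(unit_id = names(region_map),
                                 region = unname(region_map))
  }
  unmapped <- setdiff(dr$unit_id, region_map$unit_id)
  if (length(unmapped)) {
    abort(paste0("units missing from region map: ", paste(unmapped, collapse = ", ")))
  }
  if (is.null(groups)) groups <- sort(unique(unlist(dr$dominant)))
  long <- dr |>
    dplyr::select("unit_id", "dominant") |>
    tidyr::unnest_longer("dominant", values_to = "group") |>
    dplyr::left_join(region_map, by = "unit_id") |>
    dplyr::count(.data$region, .data$group)
  out <- tidyr::pivot_wider(long, names_from = "group", values_from = "n",
                            values_fill = 0L)
  for (g in setdiff(groups, names(out))) out[[g]] <- 0L
  out[, c("region", groups)]
}
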