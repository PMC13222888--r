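#' Componentwise comparison of two oriented indicator vectors
#'
#' Two areal units are compared through their oriented, normalized
#' indicator vectors: `x` is greater than `y` when every component of `x`
#' is at least the matching component of `y` and at least one is strictly
#' larger; `less` is the mirror case; `equal` when the vectors coincide;
#' otherwise the pair is `incomparable`. An optional tolerance treats
#' components within `tol` of each other as tied (vectors are snapped to a
#' `tol`-grid so that the induced relation remains a valid partial order).
#'
#' @param x,y Numeric vectors of equal length with values in `[0, 1]`.
#' @param tol Non-negative tie tolerance (0 = exact comparison).
#' @return One of `"less"`, `"greater"`, `"equal"`, `"incomparable"`.
#' @export
#' @examples
#' compare_vectors(c(0.5, 0.4), c(0.1, 0.2))
#' compare_vectors(c(0.5, 0.1), c(0.1, 0.5))
compare_vectors <- function(x, y, tol = 0) {
  if (length(x) != length(y)) abort("vectors differ in length")
  if (tol > 0) {
    x <- round(x / tol) * tol
    y <- round(y / tol) * tol
  }
  if (all(x == y)) return("equal")
  if (all(x >= y)) return("greater")
  if (all(x <= y)) return("less")
  "incomparable"
}

#' Build the partial order over areal units
#'
#' Constructs the componentwise ("product") order over the units of an
#' oriented normalized table, restricted to a subset of indicator columns
#' (typically one driver group). Units with identical indicator vectors
#' are collapsed into one equivalence class before ordering — the strict
#' relation is then irreflexive, antisymmetric and transitive by
#' construction — and every member unit inherits its representative's
#' position.
#'
#' @param table A `normalized_table` with `oriented = TRUE` (see
#'   [normalize()] and [orient()]), or any data frame with a `unit_id`
#'   column and numeric indicator columns in `[0, 1]`.
#' @param columns Indicator columns to use; default all indicator columns.
#' @param group Convenience filter: use the columns of this driver group
#'   (requires indicator metadata on `table`).
#' @param tol Tie tolerance passed to [compare_vectors()].
#' @return An object of class `ld_poset`: a list with `elements`
#'   (representative unit ids), `members` (named list of unit ids per
#'   equivalence class), `vectors` (representative indicator matrix) and
#'   `below` (logical matrix; `below[a, b]` means a < b).
#' @export
build_poset <- function(table, columns = NULL, group = NULL, tol = 0) {
  meta <- attr(table, "meta")
  if (!is.null(group)) {
    if (is.null(meta)) abort("group selection needs indicator metadata on the table")
    columns <- meta$name[meta$group == group]
  }
  if (is.null(columns)) {
    columns <- if (!is.null(meta)) meta$name else setdiff(names(table), "unit_id")
  }
  if (!length(columns)) abort("no indicator columns selected")
  if (inherits(table, "normalized_table") && !isTRUE(attr(table, "oriented"))) {
    abort("orient() the table before building a poset")
  }
  V <- as.matrix(as.data.frame(table)[, columns, drop = FALSE])
  rownames(V) <- table$unit_id
  W <- if (tol > 0) round(V / tol) * tol else V
  key <- apply(W, 1, paste, collapse = "\r")
  reps <- !duplicated(key)
  elements <- rownames(V)[reps]
  members <- split(rownames(V), factor(key, levels = key[reps]))
  names(members) <- elements
  M <- W[reps, , drop = FALSE]
  n <- length(elements)
  below <- matrix(FALSE, n, n, dimnames = list(elements, elements))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (all(M[i, ] <= M[j, ])) below[i, j] <- TRUE
        else if (all(M[i, ] >= M[j, ])) below[j, i] <- TRUE
      }
    }
  }
  structure(
    list(elements = elements, members = members, vectors = M,
         below = below, columns = columns, tol = tol),
    class = "ld_poset"
  )
}

#' @export
print.ld_poset <- function(x, ...) {
  cat(sprintf("<ld_poset> %d elements (%d units), %d strict relations, %d indicators\n",
              length(x$elements), sum(lengths(x$members)), sum(x$below),
              length(x$columns)))
  invisible(x)
}

#' Cover relations (transitive reduction) of a poset
#'
#' A pair `a < b` is a cover when no third element sits strictly between
#' them; the cover relation is the transitive reduction of the strict
#' order and forms the edge set of the Hasse diagram.
#'
#' @param p An [build_poset()] result.
#' @return A tibble of directed edges with columns `from`, `to`
#'   (`from < to`).
#' @export
transitive_reduction <- function(p) {
  B <- p$below
  covers <- B & !((B %*% B) > 0)
  idx <- which(covers, arr.ind = TRUE)
  tibble::tibble(from = p$elements[idx[, 1]], to = p$elements[idx[, 2]])
}

#' Assign Hasse diagram levels
#'
#' Levels are counted top-down: maximal (undominated) elements occupy the
#' top level `L`, and every element sits at `L - depth`, where depth is
#' the longest upward cover-path from the element to a maximal element.
#' Under this convention a unit's level reflects how strongly the driver
#' group influences it relative to the other units.
#'
#' @param elements Character vector of element ids.
#' @param covers Tibble of cover edges (`from`, `to`) as returned by
#'   [transitive_reduction()].
#' @return A named integer vector of levels in `[1, L]`.
#' @export
assign_levels <- function(elements, covers) {
  n <- length(elements)
  depth <- setNames(rep(0L, n), elements)
  if (nrow(covers)) {
    changed <- TRUE
    iter <- 0
    while (changed) {
      changed <- FALSE
      iter <- iter + 1
      if (iter > n + 1) abort("cycle detected: relation is not a valid partial order")
      for (k in seq_len(nrow(covers))) {
        a <- covers$from[k]; b <- covers$to[k]
        if (depth[a] < depth[b] + 1L) {
          depth[a] <- depth[b] + 1L
          changed <- TRUE
        }
      }
    }
  }
  L <- 1L + max(depth)
  L - depth
}

#' Elements incomparable with every other element
#'
#' @param p An [build_poset()] result.
#' @return Character vector of isolated element ids.
#' @export
isolated_elements <- function(p) {
  B <- p$below
  p$elements[rowSums(B) + colSums(B) == 0]
}

#' Hasse diagram of a unit poset
#'
#' Bundles the derived structure of a poset: cover edges, top-down level
#' assignment, maximal chains and isolated elements. Accepts either a
#' poset from [build_poset()] or an oriented normalized table (in which
#' case the poset is built first with the same arguments).
#'
#' @inheritParams build_poset
#' @param x An `ld_poset` or an oriented `normalized_table`.
#' @return An object of class `hasse_diagram`: a list with `poset`,
#'   `covers` (tibble `from`, `to`), `levels` (named integer vector), `L`
#'   (number of levels), `isolated` (character) and `chains` (list of
#'   element-id vectors, each a maximal chain of length >= 2).
#' @export
#' @examples
#' tab <- tibble::tibble(unit_id = c("a", "b", "c"),
#'                       f1 = c(0, 0.5, 1), f2 = c(0, 0.5, 1))
#' h <- hasse_diagram(tab)
#' h$levels
hasse_diagram <- function(x, columns = NULL, group = NULL, tol = 0) {
  p <- if (inherits(x, "ld_poset")) x else build_poset(x, columns = columns, group = group, tol = tol)
  covers <- transitive_reduction(p)
  levels <- assign_levels(p$elements, covers)
  structure(
    list(poset = p, covers = covers, levels = levels, L = max(levels),
         isolated = isolated_elements(p),
         chains = enumerate_chains(p$elements, covers)),
    class = "hasse_diagram"
  )
}

# All maximal source-to-sink paths (>= 2 elements) in the cover DAG.
enumerate_chains <- function(elements, covers) {
  if (!nrow(covers)) return(list())
  succ <- split(covers$to, factor(covers$from, levels = elements))
  has_in <- elements %in% covers$to
  has_out <- elements %in% covers$from
  sources <- elements[!has_in & has_out]
  chains <- list()
  walk <- function(path) {
    nxt <- succ[[path[length(path)]]]
    if (is.null(nxt) || !length(nxt)) {
      chains[[length(chains) + 1]] <<- path
    } else {
      for (v in nxt) walk(c(path, v))
    }
  }
  for (s in sources) walk(s)
  chains
}

#' @rdname hasse_diagram
#' @param h A `hasse_diagram`.
#' @export
maximal_chains <- function(h) h$chains

#' @export
print.hasse_diagram <- function(x, ...) {
  cat(sprintf("<hasse_diagram> %d elements, %d levels, %d cover edges, %d chains, %d isolated\n",
              length(x$poset$elements), x$L, nrow(x$covers),
              length(x$chains), length(x$isolated)))
  for (l in rev(seq_len(x$L))) {
    at <- names(x$levels)[x$levels == l]
    cat(sprintf("  level %d: %s\n", l, paste(at, collapse = ", ")))
  }
  if (length(x$isolated)) cat("  isolated:", paste(x$isolated, collapse = ", "), "\n")
  invisible(x)
}

#' LPOM0 average ranks of a poset
#'
#' The local partial order model (LPOM0) estimates each element's mean
#' rank over all linear extensions from local counts only:
#' `Rav = (S + 1) * (N + 1) / (N + 1 - U)`, where `S` counts elements
#' strictly below, `U` counts incomparable elements and `N` is the number
#' of elements. On chains and antichains the estimate is exact.
#'
#' @param p An [build_poset()] result.
#' @return A tibble with columns `element`, `S` (below), `P` (above), `U`
#'   (incomparable) and `Rav`; `S + P + U = N - 1` on every row and
#'   `Rav` lies in `[1, N]`.
#' @export
lpom_average_rank <- function(p) {
  B <- p$below
  N <- length(p$elements)
  S <- colSums(B)
  P <- rowSums(B)
  U <- N - 1 - S - P
  tibble::tibble(
    element = p$elements,
    S = as.integer(S), P = as.integer(P), U = as.integer(U),
    Rav = (S + 1) * (N + 1) / (N + 1 - U)
  )
}

#' Per-element rank table of a Hasse diagram
#'
#' Joins the level assignment with the LPOM0 rank estimate; one row per
#' equivalence-class element, with the member unit ids spelled out.
#'
#' @param h A [hasse_diagram()].
#' @return A tibble with columns `element`, `members`, `level`, `S`, `P`,
#'   `U`, `Rav`.
#' @export
rank_table <- function(h) {
  lpom_average_rank(h$poset) |>
    dplyr::mutate(
      members = purrr::map_chr(h$poset$members[.data$element], paste, collapse = ";"),
      level = as.integer(h$levels[.data$element]),
      .after = "element"
    )
}

#' @export
tidy.hasse_diagram <- function(x, ...) rank_table(x)

#' @export
glance.hasse_diagram <- function(x, ...) {
  tibble::tibble(
    n_units = sum(lengths(x$poset$members)),
    n_elements = length(x$poset$elements),
    n_levels = x$L,
    n_covers = nrow(x$covers),
    n_chains = length(x$chains),
    n_isolated = length(x$isolated)
  )
}
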