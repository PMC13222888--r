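#' Land-cover grids
#'
#' A `land_grid` is an integer category raster for one epoch: a matrix of
#' class codes plus a nodata code, the area of one cell (km^2) and the epoch
#' year. Cells are square; the cell side is `sqrt(cell_area)` km.
#'
#' @param values Integer matrix of class codes (rows = grid rows).
#' @param scheme A [class_scheme()]; every non-nodata value must be one of
#'   its codes.
#' @param nodata Integer nodata code (must not collide with a class code).
#' @param cell_area Positive cell area in km^2.
#' @param epoch Epoch year.
#'
#' @return An object of class `land_grid`.
#' @export
#' @examples
#' g <- land_grid(matrix(c(1L, 3L, 3L, 3L), 2), epoch = 1990)
#' g
land_grid <- function(values, scheme = default_scheme(), nodata = -9999L,
                      cell_area = 1, epoch = NA_integer_) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (nrow(values) < 1 || ncol(values) < 1) abort("grid must be at least 1x1")
  if (!is.numeric(cell_area) || cell_area <= 0) abort("cell_area must be positive")
  nodata <- as.integer(nodata)
  if (nodata %in% scheme$code) abort("nodata code collides with a class code")
  vals <- values[!is.na(values) & values != nodata]
  bad <- setdiff(unique(vals), scheme$code)
  if (length(bad)) {
    abort(paste0("grid holds codes outside the scheme: ", paste(sort(bad), collapse = ", ")))
  }
  values[is.na(values)] <- nodata
  structure(
    list(values = values, scheme = scheme, nodata = nodata,
         cell_area = as.numeric(cell_area), epoch = as.integer(epoch)),
    class = "land_grid"
  )
}

#' @export
print.land_grid <- function(x, ...) {
  cat(sprintf("<land_grid> %d x %d cells, cell area %g km2, epoch %s\n",
              nrow(x$values), ncol(x$values), x$cell_area,
              ifelse(is.na(x$epoch), "?", x$epoch)))
  counts <- table(factor(x$values[x$values != x$nodata],
                         levels = x$scheme$code, labels = x$scheme$name))
  print(counts)
  invisible(x)
}

#' @export
dim.land_grid <- function(x) dim(x$values)

grid_valid <- function(g) g$values != g$nodata

check_grid_pair <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values))) abort("grids differ in shape")
  if (!identical(a$scheme$code, b$scheme$code) ||
      !identical(a$scheme$name, b$scheme$name)) abort("grids use different class schemes")
  if (!isTRUE(all.equal(a$cell_area, b$cell_area))) abort("grids differ in cell area")
  if (!is.na(a$epoch) && !is.na(b$epoch) && a$epoch >= b$epoch) {
    abort("first grid must be the earlier epoch")
  }
  invisible(TRUE)
}

#' Tidy a land grid into per-cell records
#'
#' @param x A [land_grid()].
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `code`, `name` (nodata cells
#'   carry `NA`).
#' @export
tidy.land_grid <- function(x, ...) {
  v <- x$values
  tibble::tibble(
    row = rep(seq_len(nrow(v)), times = ncol(v)),
    col = rep(seq_len(ncol(v)), each = nrow(v)),
    code = ifelse(c(v) == x$nodata, NA_integer_, c(v))
  ) |>
    dplyr::mutate(name = x$scheme$name[match(.data$code, x$scheme$code)])
}

#' Read or write a grid as Esri ASCII
#'
#' Plain-text Esri ASCII grid ("Arc/Info ASCII"): a six-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`)
#' followed by rows of values, top row first. `cellsize` is stored in km, so
#' a cell covers `cellsize^2` km^2.
#'
#' @param path File path.
#' @param scheme A [class_scheme()] for the values in the file.
#' @param epoch Epoch year to attach to the grid.
#' @param grid A [land_grid()].
#' @param xll,yll Lower-left corner coordinates written to the header.
#' @return `read_ascii_grid()` returns a [land_grid()];
#'   `write_ascii_grid()` returns `path` invisibly.
#' @export
read_ascii_grid <- function(path, scheme = default_scheme(), epoch = NA_integer_) {
  raw <- read_ascii_grid_raw(path)
  land_grid(raw$values, scheme = scheme, nodata = raw$nodata,
            cell_area = raw$cellsize^2, epoch = epoch)
}

#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(grid, path, xll = 0, yll = 0) {
  v <- grid$values
  hdr <- c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", xll),
    paste("yllcorner", yll),
    paste("cellsize", sqrt(grid$cell_area)),
    paste("NODATA_value", grid$nodata)
  )
  body <- apply(v, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}
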