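#' Land-cover class schemes
#'
#' A class scheme lists the integer category codes of a land-cover
#' classification together with their labels. [default_scheme()] returns the
#' six-category scheme used throughout the package: cropland, forest,
#' grassland, water bodies, bare areas and impervious surfaces, coded 1 to 6.
#'
#' The degradation/restoration semantics attached to the default scheme
#' follow the operational definitions used in county-scale land-change
#' studies of agro-pastoral ecotones: land degradation is the conversion of
#' grassland, forest or water bodies into cropland, bare areas or impervious
#' surfaces; land restoration is the conversion of cropland or bare areas
#' into grassland, forest or water bodies.
#'
#' @param codes Integer vector of unique category codes.
#' @param names Character vector of labels, one per code.
#' @param ld_sources,ld_targets Labels whose conversion
#'   (source -> target) counts as land degradation.
#' @param lr_sources,lr_targets Labels whose conversion counts as land
#'   restoration.
#'
#' @return A tibble of class `class_scheme` with columns `code` and `name`,
#'   carrying the degradation/restoration label sets as attributes.
#' @export
#' @examples
#' default_scheme()
class_scheme <- function(codes, names,
                         ld_sources = character(), ld_targets = character(),
                         lr_sources = character(), lr_targets = character()) {
  codes <- as.integer(codes)
  if (anyDuplicated(codes)) abort("class codes must be unique")
  if (length(codes) != length(names) || length(codes) < 2) {
    abort("need one name per code and at least 2 classes")
  }
  for (s in list(ld_sources, ld_targets, lr_sources, lr_targets)) {
    if (!all(s %in% names)) abort("degradation/restoration sets must use scheme names")
  }
  out <- tibble::tibble(code = codes, name = as.character(names))
  attr(out, "ld_sources") <- ld_sources
  attr(out, "ld_targets") <- ld_targets
  attr(out, "lr_sources") <- lr_sources
  attr(out, "lr_targets") <- lr_targets
  class(out) <- c("class_scheme", class(out))
  out
}

#' @rdname class_scheme
#' @export
default_scheme <- function() {
  class_scheme(
    codes = 1:6,
    names = c("cropland", "forest", "grassland", "water bodies",
              "bare areas", "impervious surfaces"),
    ld_sources = c("grassland", "forest", "water bodies"),
    ld_targets = c("cropland", "bare areas", "impervious surfaces"),
    lr_sources = c("cropland", "bare areas"),
    lr_targets = c("grassland", "forest", "water bodies")
  )
}

scheme_code <- function(scheme, name) scheme$code[match(name, scheme$name)]

#' Read and write fine-to-major reclassification tables
#'
#' A reclassification map sends every fine land-cover code to a major
#' category code of a [class_scheme()]. On disk it is a CSV with columns
#' `fine_code`, `fine_name`, `major_code`.
#'
#' @param entries Named integer vector or two-column data frame
#'   (`fine_code`, `major_code`); names/`fine_name` optional.
#' @param scheme A [class_scheme()]; every target code must belong to it.
#' @param path File path for CSV I/O.
#' @param map A `reclass_map`.
#'
#' @return `reclass_map()` and `read_reclass_map()` return a tibble of class
#'   `reclass_map` with columns `fine_code`, `fine_name`, `major_code`.
#' @export
reclass_map <- function(entries, scheme = default_scheme()) {
  if (is.data.frame(entries)) {
    fine <- as.integer(entries$fine_code)
    major <- as.integer(entries$major_code)
    fine_name <- if ("fine_name" %in% names(entries)) {
      as.character(entries$fine_name)
    } else {
      as.character(fine)
    }
  } else {
    fine <- as.integer(names(entries) %||% seq_along(entries))
    if (is.null(names(entries))) abort("entries must be named by fine code or be a data frame")
    fine <- as.integer(names(entries))
    major <- as.integer(entries)
    fine_name <- as.character(fine)
  }
  if (anyDuplicated(fine)) abort("every fine code must appear exactly once")
  bad <- setdiff(major, scheme$code)
  if (length(bad)) abort(paste0("major codes not in scheme: ", paste(bad, collapse = ", ")))
  out <- tibble::tibble(fine_code = fine, fine_name = fine_name, major_code = major)
  class(out) <- c("reclass_map", class(out))
  out
}

#' @rdname reclass_map
#' @export
read_reclass_map <- function(path, scheme = default_scheme()) {
  reclass_map(read.csv(path, stringsAsFactors = FALSE), scheme = scheme)
}

#' @rdname reclass_map
#' @export
write_reclass_map <- function(map, path) {
  write.csv(as.data.frame(map), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
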