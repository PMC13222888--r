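#' Construct an oriented normalized table from prepared values
#'
#' Wraps already-normalized, already-oriented indicator values (every
#' value in `[0, 1]`, larger = stronger degradation influence) as a
#' `normalized_table`, bypassing [normalize()] and [orient()]. Useful for
#' feeding externally prepared scores straight into [build_poset()].
#'
#' @param data Data frame with `unit_id` and one column per indicator in
#'   `meta`, all values in `[0, 1]`.
#' @param meta An [indicator_meta()].
#' @param epoch Period label.
#' @return An oriented `normalized_table`.
#' @export
oriented_table <- function(data, meta, epoch = NA_character_) {
  out <- driver_table(data, meta = meta, epoch = epoch)
  vals <- as.matrix(as.data.frame(out)[, meta$name, drop = FALSE])
  if (any(vals < 0) || any(vals > 1)) abort("oriented values must lie in [0, 1]")
  attr(out, "oriented") <- TRUE
  class(out) <- c("normalized_table", class(out))
  out
}

#' Six-county natural-driver worked example
#'
#' A small synthetic table of six banner/county units (AES, TQ, KYQ, WL,
#' KYZ, ZLT) with two oriented natural-driver indicators (annual mean
#' temperature; annual total precipitation, already flipped). The values
#' are a synthetic reconstruction chosen so the induced partial order has
#' the published six-county structure of the method's worked example:
#' three levels grouped AES below \{TQ, KYQ, WL\} below KYZ, cover edges
#' KYQ-KYZ, AES-TQ, TQ-KYZ and WL-KYZ (so TQ-KYZ is a cover), maximal
#' chains AES-TQ-KYZ, KYQ-KYZ and WL-KYZ, and ZLT isolated through its
#' extreme temperature/precipitation combination.
#'
#' @return An oriented `normalized_table` of 6 units x 2 indicators.
#' @export
#' @examples
#' h <- hasse_diagram(six_county_example())
#' h
six_county_example <- function() {
  meta <- indicator_meta(
    name = c("annual_mean_temperature", "annual_total_precipitation"),
    group = c("natural", "natural"),
    unit = c("degC", "mm"),
    orientation = c("direct", "inverse")
  )
  data <- tibble::tribble(
    ~unit_id, ~annual_mean_temperature, ~annual_total_precipitation,
    "AES",    0.10,                     0.20,
    "TQ",     0.30,                     0.40,
    "KYQ",    0.05,                     0.50,
    "WL",     0.50,                     0.05,
    "KYZ",    0.90,                     0.90,
    "ZLT",    1.00,                     0.00
  )
  oriented_table(data, meta, epoch = "1990-2000")
}
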