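#' Scenario configuration for the synthetic-data generator
#'
#' Describes a desk-scale study scenario with known ground truth: a county
#' (unit) layout, a twelve-indicator driver table with one planted dominant
#' driver group per unit, and a land-cover grid pair with planted per-class
#' transition probabilities. Every generator draws from its own seed
#' substream derived from `seed`, so outputs are reproducible and adding a
#' generator never perturbs another's draws.
#'
#' @param n_units Number of areal units (default 20).
#' @param grid_shape `c(rows, cols)` of the synthetic grids (default
#'   50 x 50).
#' @param meta [indicator_meta()] for the driver table (default the
#'   twelve-indicator, four-group set of [default_indicators()]).
#' @param delta Planted effect size: the latent-scale offset added to a
#'   unit's planted-group indicators (default 0.5).
#' @param sigma Indicator noise standard deviation on the latent scale
#'   (default 0.05).
#' @param planted_dominant Named character vector unit -> group; default
#'   assigns groups round-robin across units.
#' @param class_mix Named probability vector over scheme class names for
#'   the first-epoch land-cover draw; defaults to a grassland-dominated
#'   agro-pastoral mixture.
#' @param transition_probs Data frame `from`, `to`, `prob` of per-cell
#'   class-flip probabilities between the epochs; rows not listed stay
#'   put. Default regime: grassland/forest reclamation to cropland, some
#'   cropland/bare recovery to grassland, and minor impervious expansion.
#' @param period `c(year1, year2)` of the land-cover pair (default
#'   1990, 2000).
#' @param cell_area Cell area in km^2 (default 1).
#' @param scheme A [class_scheme()].
#' @param seed Integer master seed.
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(n_units = 20, grid_shape = c(50, 50),
                            meta = default_indicators(),
                            delta = 0.5, sigma = 0.05,
                            planted_dominant = NULL,
                            class_mix = NULL, transition_probs = NULL,
                            period = c(1990, 2000), cell_area = 1,
                            scheme = default_scheme(), seed = 1) {
  if (!is.finite(delta) || delta < 0) abort("delta must be finite and >= 0")
  if (!is.finite(sigma) || sigma < 0) abort("sigma must be finite and >= 0")
  if (n_units < 1 || n_units > prod(grid_shape)) {
    abort("n_units must be between 1 and the number of grid cells")
  }
  groups <- unique(meta$group)
  unit_ids <- sprintf("U%02d", seq_len(n_units))
  if (is.null(planted_dominant)) {
    planted_dominant <- setNames(rep_len(groups, n_units), unit_ids)
  }
  if (!all(names(planted_dominant) == unit_ids) ||
      !all(planted_dominant %in% groups)) {
    abort("planted_dominant must map every unit id to a known group")
  }
  if (is.null(class_mix)) {
    class_mix <- c("cropland" = 0.15, "forest" = 0.25, "grassland" = 0.45,
                   "water bodies" = 0.04, "bare areas" = 0.08,
                   "impervious surfaces" = 0.03)
  }
  if (!all(names(class_mix) %in% scheme$name) || abs(sum(class_mix) - 1) > 1e-8) {
    abort("class_mix must be a probability vector over scheme class names")
  }
  if (is.null(transition_probs)) {
    transition_probs <- tibble::tribble(
      ~from,        ~to,                    ~prob,
      "grassland",  "cropland",             0.05,
      "forest",     "cropland",             0.01,
      "grassland",  "impervious surfaces",  0.005,
      "cropland",   "grassland",            0.03,
      "bare areas", "grassland",            0.02
    )
  }
  transition_probs <- tibble::as_tibble(transition_probs)
  if (!all(transition_probs$from %in% scheme$name) ||
      !all(transition_probs$to %in% scheme$name) ||
      any(transition_probs$prob < 0) || any(transition_probs$prob > 1)) {
    abort("transition_probs must map scheme classes with probabilities in [0, 1]")
  }
  rowsum_ok <- tapply(transition_probs$prob, transition_probs$from, sum)
  if (any(rowsum_ok > 1 + 1e-12)) {
    abort(paste0("transition probabilities out of a class must sum to <= 1; offending: ",
                 paste(names(rowsum_ok)[rowsum_ok > 1 + 1e-12], collapse = ", ")))
  }
  structure(
    list(n_units = as.integer(n_units), grid_shape = as.integer(grid_shape),
         meta = meta, delta = delta, sigma = sigma,
         unit_ids = unit_ids, planted_dominant = planted_dominant,
         class_mix = class_mix, transition_probs = transition_probs,
         period = as.integer(period), cell_area = cell_area,
         scheme = scheme, seed = as.integer(seed)),
    class = "scenario_config"
  )
}

# independent substreams: one derived seed per generator, restoring the
# caller's RNG state afterwards
sub_seed <- function(seed, k) {
  (as.numeric(seed) * 7919 + k * 104729) %% 2147483647
}

with_substream <- function(seed, k, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(sub_seed(seed, k))
  force(code)
}

#' Generate a zone (county) map of contiguous rectangular blocks
#'
#' Partitions the grid into `n_units` rectangular blocks: the rows are cut
#' into bands and each band into column blocks, so every unit is one
#' non-empty connected rectangle.
#'
#' @param cfg A [scenario_config()].
#' @return An integer matrix of unit indices (1..n_units); unit `i`
#'   corresponds to `cfg$unit_ids[i]`.
#' @export
gen_zone_map <- function(cfg) {
  rows <- cfg$grid_shape[1]; cols <- cfg$grid_shape[2]
  n <- cfg$n_units
  bands <- min(max(1L, floor(sqrt(n))), rows)
  per_band <- diff(round(seq(0, n, length.out = bands + 1)))
  if (max(per_band) > cols) abort("infeasible partition: too many units per row band")
  row_cut <- round(seq(0, rows, length.out = bands + 1))
  z <- matrix(NA_integer_, rows, cols)
  u <- 0L
  for (b in seq_len(bands)) {
    r <- (row_cut[b] + 1):row_cut[b + 1]
    col_cut <- round(seq(0, cols, length.out = per_band[b] + 1))
    for (k in seq_len(per_band[b])) {
      u <- u + 1L
      z[r, (col_cut[k] + 1):col_cut[k + 1]] <- u
    }
  }
  z
}

#' Generate a raw driver table with planted dominant groups
#'
#' For unit `u` with planted group `g*`, every indicator in `g*` is drawn
#' on a latent influence scale as `delta + Normal(0, sigma)` and every
#' other indicator as `Normal(0, sigma)`. Each latent value is then mapped
#' onto the indicator's raw measurement scale by a fixed affine transform
#' — increasing for direct indicators and decreasing for inverse ones, so
#' the raw table is on the uninverted scale and [orient()] is genuinely
#' exercised downstream. Min-max normalization removes the affine maps
#' again, so the planted structure survives the pipeline exactly.
#'
#' @param cfg A [scenario_config()].
#' @return A raw [driver_table()] with one row per unit.
#' @export
gen_drivers <- function(cfg) {
  meta <- cfg$meta
  n <- cfg$n_units
  with_substream(cfg$seed, 1, {
    latent <- matrix(rnorm(n * nrow(meta), 0, cfg$sigma), n, nrow(meta))
    for (j in seq_len(nrow(meta))) {
      planted <- cfg$planted_dominant == meta$group[j]
      latent[planted, j] <- latent[planted, j] + cfg$delta
    }
    data <- tibble::tibble(unit_id = cfg$unit_ids)
    for (j in seq_len(nrow(meta))) {
      a <- raw_scale(meta$name[j])
      data[[meta$name[j]]] <- if (meta$orientation[j] == "direct") {
        a$offset + a$scale * latent[, j]
      } else {
        a$offset - a$scale * latent[, j]
      }
    }
    driver_table(data, meta = meta,
                 epoch = paste(cfg$period, collapse = "-"))
  })
}

# plausible measurement scales per default indicator; unknown names get a
# generic positive scale
raw_scale <- function(name) {
  scales <- list(
    annual_mean_temperature = list(offset = 2, scale = 6),
    annual_total_precipitation = list(offset = 600, scale = 400),
    population_density = list(offset = 40, scale = 80),
    sheep_density = list(offset = 80, scale = 120),
    primary_gdp_density = list(offset = 150, scale = 300),
    secondary_gdp_density = list(offset = 250, scale = 600),
    tertiary_gdp_density = list(offset = 200, scale = 500),
    gdp_density = list(offset = 600, scale = 1200),
    dist_to_urban_land = list(offset = 40, scale = 30),
    dist_to_rural_settlements = list(offset = 15, scale = 10),
    dist_to_roads = list(offset = 10, scale = 8),
    dist_to_other_builtup = list(offset = 25, scale = 20)
  )
  scales[[name]] %||% list(offset = 10, scale = 5)
}

#' Generate a land-cover grid pair with planted transition probabilities
#'
#' Draws the first epoch cell-by-cell from `class_mix`, then flips each
#' cell of class `i` to class `j` with probability
#' `transition_probs[i, j]`, independently across cells; unlisted
#' transitions have probability zero and the cell stays put.
#'
#' @param cfg A [scenario_config()].
#' @return A list of two [land_grid()]s, `a` (first epoch) and `b`
#'   (second epoch).
#' @export
gen_landcover_pair <- function(cfg) {
  sch <- cfg$scheme
  rows <- cfg$grid_shape[1]; cols <- cfg$grid_shape[2]
  mix <- setNames(rep(0, nrow(sch)), sch$name)
  mix[names(cfg$class_mix)] <- cfg$class_mix
  with_substream(cfg$seed, 2, {
    v1 <- matrix(sample(sch$code, rows * cols, replace = TRUE, prob = mix),
                 rows, cols)
    v2 <- v1
    for (from in unique(cfg$transition_probs$from)) {
      tp <- cfg$transition_probs[cfg$transition_probs$from == from, ]
      src <- which(v1 == scheme_code(sch, from))
      if (!length(src)) next
      stay <- max(0, 1 - sum(tp$prob))
      dest <- sample(c(scheme_code(sch, tp$to), NA_integer_), length(src),
                     replace = TRUE, prob = c(tp$prob, stay))
      moved <- !is.na(dest)
      v2[src[moved]] <- dest[moved]
    }
    list(
      a = land_grid(v1, scheme = sch, cell_area = cfg$cell_area, epoch = cfg$period[1]),
      b = land_grid(v2, scheme = sch, cell_area = cfg$cell_area, epoch = cfg$period[2])
    )
  })
}

#' Expected degradation/restoration outcomes implied by a scenario
#'
#' Closed-form expectations under the planted transition regime: the
#' expected degraded (restored) fraction is the mixture-weighted sum of
#' the transition probabilities from degradation (restoration) source
#' classes into the corresponding target classes.
#'
#' @param cfg A [scenario_config()].
#' @return A list with `expected_ld_fraction`, `expected_lr_fraction`,
#'   expected areas (km^2) and expected annual rates (% per year).
#' @export
expected_change <- function(cfg) {
  sch <- cfg$scheme
  block_fraction <- function(sources, targets) {
    tp <- cfg$transition_probs
    sel <- tp$from %in% sources & tp$to %in% targets & tp$from != tp$to
    if (!any(sel)) return(0)
    sum(purrr::map2_dbl(tp$from[sel], tp$prob[sel], function(f, p) {
      mf <- unname(cfg$class_mix[f])
      if (is.na(mf)) 0 else mf * p
    }))
  }
  ld_f <- block_fraction(attr(sch, "ld_sources"), attr(sch, "ld_targets"))
  lr_f <- block_fraction(attr(sch, "lr_sources"), attr(sch, "lr_targets"))
  total <- prod(cfg$grid_shape) * cfg$cell_area
  years <- diff(cfg$period)
  list(
    expected_ld_fraction = ld_f,
    expected_lr_fraction = lr_f,
    expected_ld_area = ld_f * total,
    expected_lr_area = lr_f * total,
    expected_ld_annual_rate = 100 * ld_f / years,
    expected_lr_annual_rate = 100 * lr_f / years
  )
}

#' Generate a full synthetic bundle with ground truth
#'
#' Runs every generator of a scenario and packages the results with a
#' truth record: the planted dominant group per unit and the expected
#' degradation/restoration outcomes. Per-indicator rasters paint each
#' unit's raw value over its zone block, so zonal averaging reproduces
#' the driver table exactly.
#'
#' @param cfg A [scenario_config()].
#' @return A list of class `synthetic_bundle` with elements `config`,
#'   `zone_map`, `drivers`, `driver_rasters`, `landcover` (list `a`, `b`)
#'   and `truth`.
#' @export
gen_bundle <- function(cfg) {
  zones <- gen_zone_map(cfg)
  drivers <- gen_drivers(cfg)
  rasters <- purrr::map(
    setNames(indicator_names(drivers), indicator_names(drivers)),
    function(col) matrix(drivers[[col]][zones], nrow(zones), ncol(zones))
  )
  lc <- gen_landcover_pair(cfg)
  truth <- c(
    list(planted_dominant = as.list(cfg$planted_dominant),
         period_years = diff(cfg$period), seed = cfg$seed),
    expected_change(cfg)
  )
  structure(
    list(config = cfg, zone_map = zones, drivers = drivers,
         driver_rasters = rasters, landcover = lc, truth = truth),
    class = "synthetic_bundle"
  )
}
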