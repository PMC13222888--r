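# fine scheme for reclassification tests: a handful of fine codes mapping
# onto the six major categories
fine_scheme <- class_scheme(
  codes = c(10L, 51L, 120L, 181L, 190L),
  names = c("rainfed cropland", "shrubland", "grassland", "marsh", "impervious")
)
fine_map <- reclass_map(
  data.frame(
    fine_code = c(10L, 51L, 120L, 181L, 190L),
    fine_name = c("rainfed cropland", "shrubland", "grassland", "marsh", "impervious"),
    major_code = c(1L, 2L, 3L, 4L, 6L)
  )
)

test_that("reclassify maps fine codes onto major categories", {
  g <- land_grid(matrix(c(51L, 181L, 10L, 120L), 2), scheme = fine_scheme,
                 epoch = 1990, cell_area = 0.25)
  out <- reclassify(g, fine_map)
  # shrubland folds into forest, marsh into water bodies
  expect_equal(out$values, matrix(c(2L, 4L, 1L, 3L), 2))
  expect_equal(out$epoch, 1990L)
  expect_equal(out$cell_area, 0.25)
})

test_that("identity reclassification is a no-op and repeat application idempotent", {
  sch <- default_scheme()
  id_map <- reclass_map(data.frame(fine_code = sch$code, major_code = sch$code))
  g <- land_grid(matrix(sample(c(sch$code, -9999L), 30, replace = TRUE), 5),
                 epoch = 2000)
  once <- reclassify(g, id_map)
  expect_identical(once$values, g$values)
  expect_identical(reclassify(once, id_map)$values, g$values)
})

test_that("reclassify preserves nodata and reports unmapped codes with counts", {
  g <- land_grid(matrix(c(51L, -9999L, 120L, 120L), 2), scheme = fine_scheme)
  out <- reclassify(g, fine_map)
  expect_equal(out$values[2, 1], -9999L)
  partial <- reclass_map(data.frame(fine_code = 51L, major_code = 2L))
  expect_error(reclassify(g, partial), "unmapped.*120 \\(2 cells\\)")
})

test_that("transition matrix counts per-cell class moves as areas", {
  sch <- default_scheme()
  # one grassland cell becomes cropland, everything else stays
  a <- land_grid(matrix(c(3L, 3L, 2L, 1L), 2), epoch = 1990)
  b <- land_grid(matrix(c(3L, 1L, 2L, 1L), 2), epoch = 2000)
  tm <- transition_matrix(a, b)
  expect_equal(tm$areas["grassland", "cropland"], 1)
  expect_equal(tm$areas["grassland", "grassland"], 1)
  expect_equal(sum(tm$areas), 4)

  same <- transition_matrix(a, land_grid(a$values, epoch = 2000))
  expect_true(all(same$areas[upper.tri(same$areas) | lower.tri(same$areas)] == 0))
  expect_equal(diag(same$areas), c(cropland = 1, forest = 1, grassland = 2,
                                   `water bodies` = 0, `bare areas` = 0,
                                   `impervious surfaces` = 0))

  expect_error(transition_matrix(a, land_grid(matrix(1L, 3, 3), epoch = 2000)),
               "shape")
})

test_that("transition matrix conserves area and row sums on random pairs", {
  set.seed(41)
  for (rep in 1:20) {
    g <- random_grid_pair()
    tm <- transition_matrix(g$a, g$b)
    valid <- g$a$values != g$a$nodata & g$b$values != g$b$nodata
    expect_equal(sum(tm$areas), sum(valid) * g$a$cell_area)
    year1 <- vapply(g$a$scheme$code,
                    function(k) sum(g$a$values == k & valid) * g$a$cell_area,
                    numeric(1))
    expect_equal(unname(rowSums(tm$areas)), year1)
  }
})

test_that("change classification follows the degradation/restoration definitions", {
  pairs <- list(
    list(from = "grassland", to = "cropland", label = "degradation"),
    list(from = "forest", to = "impervious surfaces", label = "degradation"),
    list(from = "water bodies", to = "bare areas", label = "degradation"),
    list(from = "cropland", to = "grassland", label = "restoration"),
    list(from = "bare areas", to = "forest", label = "restoration"),
    list(from = "cropland", to = "impervious surfaces", label = "other_change"),
    list(from = "forest", to = "grassland", label = "other_change"),
    list(from = "forest", to = "forest", label = "stable")
  )
  sch <- default_scheme()
  for (p in pairs) {
    a <- land_grid(matrix(sch$code[sch$name == p$from], 1, 1), epoch = 1990)
    b <- land_grid(matrix(sch$code[sch$name == p$to], 1, 1), epoch = 2000)
    expect_equal(unclass(classify_change(a, b))[1, 1], p$label)
  }
})

test_that("change-map label areas reproduce transition-matrix block sums", {
  set.seed(42)
  sch <- default_scheme()
  ld_src <- attr(sch, "ld_sources"); ld_tgt <- attr(sch, "ld_targets")
  lr_src <- attr(sch, "lr_sources"); lr_tgt <- attr(sch, "lr_targets")
  for (rep in 1:15) {
    g <- random_grid_pair()
    tm <- transition_matrix(g$a, g$b)
    cm <- classify_change(g$a, g$b)
    expect_equal(sum(unclass(cm) == "degradation") * g$a$cell_area,
                 sum(tm$areas[ld_src, ld_tgt]))
    expect_equal(sum(unclass(cm) == "restoration") * g$a$cell_area,
                 sum(tm$areas[lr_src, lr_tgt]))
    expect_equal(sum(unclass(cm) == "nodata"),
                 sum(!(g$a$values != g$a$nodata & g$b$values != g$b$nodata)))
  }
})

test_that("annual change rates are changed fraction over period length", {
  sch <- default_scheme()
  # 20 of 100 cells grassland->cropland over 10 years:
  # 100 * (20 / 100) / 10 = 2 % per year
  va <- matrix(3L, 10, 10)
  vb <- va; vb[1:20] <- 1L
  cm <- classify_change(land_grid(va, epoch = 1990), land_grid(vb, epoch = 2000))
  r <- change_rates(cm)
  expect_equal(r$ld_annual_rate, 2)
  expect_equal(r$ld_area, 20)
  expect_equal(r$lr_annual_rate, 0)

  # all cells degraded over 10 years -> 10 % per year
  vb_all <- matrix(1L, 10, 10)
  r_all <- change_rates(classify_change(land_grid(va, epoch = 1990),
                                        land_grid(vb_all, epoch = 2000)))
  expect_equal(r_all$ld_annual_rate, 10)

  # no change -> both rates zero
  r0 <- change_rates(classify_change(land_grid(va, epoch = 1990),
                                     land_grid(va, epoch = 2000)))
  expect_equal(r0$ld_annual_rate, 0)
  expect_equal(r0$lr_annual_rate, 0)

  all_na <- classify_change(
    land_grid(matrix(-9999L, 2, 2), epoch = 1990),
    land_grid(matrix(-9999L, 2, 2), epoch = 2000)
  )
  expect_error(change_rates(all_na), "no valid cells")
})

test_that("distance to class is exact cell-centre Euclidean distance", {
  v <- matrix(3L, 5, 5)
  v[1, 1] <- 1L
  g <- land_grid(v)
  d <- distance_to_class(g, 1L)
  expect_equal(d[1, 1], 0)
  expect_equal(d[4, 5], 5)  # 3 rows down, 4 cols right
  expect_equal(d[1, 3], 2)

  # cell side scales with cell area
  g2 <- land_grid(v, cell_area = 4)
  expect_equal(distance_to_class(g2, 1L)[4, 5], 10)

  expect_error(distance_to_class(g, 6L), "absent")
  expect_error(distance_to_class(g, 99L), "scheme")
})

test_that("distance transform matches brute-force search on random grids", {
  set.seed(43)
  for (rep in 1:10) {
    v <- matrix(sample(c(1L, 3L), 64, replace = TRUE, prob = c(0.15, 0.85)), 8)
    if (!any(v == 1L)) v[3, 3] <- 1L
    g <- land_grid(v, cell_area = 0.25)
    expect_equal(distance_to_class(g, 1L), oracle_distance(g, 1L))
  }
})

test_that("transition summary reports the largest net loss and gain", {
  a <- land_grid(matrix(c(rep(2L, 6), rep(3L, 3), 1L), 2, 5), epoch = 1990)
  vb <- a$values; vb[1:4] <- 1L  # 4 forest cells -> cropland
  b <- land_grid(vb, epoch = 2000)
  s <- summarize_transitions(transition_matrix(a, b))
  expect_equal(s$most_decreased$name, "forest")
  expect_equal(s$most_increased$name, "cropland")
  expect_equal(s$most_decreased$change_percent, -40)
  expect_equal(s$most_increased$main_transitions[[1]]$class, "forest")
  expect_equal(s$most_increased$main_transitions[[1]]$area_km2, 4)
})
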