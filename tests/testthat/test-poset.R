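test_that("componentwise comparison yields exactly one of four outcomes", {
  expect_equal(compare_vectors(c(0.5, 0.4), c(0.1, 0.2)), "greater")
  expect_equal(compare_vectors(c(0.1, 0.2), c(0.5, 0.4)), "less")
  expect_equal(compare_vectors(c(0.5, 0.1), c(0.1, 0.5)), "incomparable")
  expect_equal(compare_vectors(c(0.3, 0.3), c(0.3, 0.3)), "equal")
  expect_error(compare_vectors(c(0.1), c(0.1, 0.2)), "length")

  # mirror symmetry on random pairs
  set.seed(21)
  mirror <- c(less = "greater", greater = "less",
              equal = "equal", incomparable = "incomparable")
  for (rep in 1:50) {
    x <- runif(3); y <- if (rep %% 3 == 0) x else runif(3)
    expect_equal(compare_vectors(x, y), unname(mirror[compare_vectors(y, x)]))
  }
})

test_that("build_poset reproduces exhaustive pairwise comparison", {
  one <- build_poset(random_unit_table(1, 3))
  expect_equal(length(one$elements), 1)
  expect_false(any(one$below))

  two <- oriented_table(
    tibble::tibble(unit_id = c("lo", "hi"), f1 = c(0, 1), f2 = c(0, 1)),
    indicator_meta(c("f1", "f2"), "natural")
  )
  p2 <- build_poset(two)
  expect_true(p2$below["lo", "hi"])
  expect_equal(sum(p2$below), 1)

  set.seed(22)
  for (rep in 1:20) {
    tab <- random_unit_table(8, 3)
    p <- build_poset(tab)
    V <- as.matrix(as.data.frame(tab)[, p$columns])
    rownames(V) <- tab$unit_id
    expect_equal(p$below, oracle_below(V))
  }
})

test_that("units with identical vectors collapse into one equivalence class", {
  tab <- oriented_table(
    tibble::tibble(unit_id = c("a", "b", "c", "d"),
                   f1 = c(0.2, 0.2, 0.9, 0.2), f2 = c(0.1, 0.1, 0.9, 0.1)),
    indicator_meta(c("f1", "f2"), "natural")
  )
  p <- build_poset(tab)
  expect_equal(p$elements, c("a", "c"))
  expect_equal(p$members[["a"]], c("a", "b", "d"))
  # antisymmetry holds by construction: strict relation has no 2-cycles
  expect_false(any(p$below & t(p$below)))
})

make_raw_table <- function() {
  driver_table(tibble::tibble(unit_id = c("a", "b", "c"), f1 = c(1, 5, 9)),
               meta = indicator_meta("f1", "natural"))
}

test_that("build_poset validates its inputs", {
  tab <- random_unit_table(4, 2)
  expect_error(build_poset(tab, columns = character(0)), "no indicator")
  un <- normalize(make_raw_table())
  expect_error(build_poset(un), "orient")
})

test_that("transitive reduction keeps exactly the cover relations", {
  chain <- oriented_table(
    tibble::tibble(unit_id = c("a", "b", "c"), f1 = c(0, 0.5, 1)),
    indicator_meta("f1", "natural")
  )
  cov <- transitive_reduction(build_poset(chain))
  expect_equal(nrow(cov), 2)
  expect_false(any(cov$from == "a" & cov$to == "c"))

  anti <- oriented_table(
    tibble::tibble(unit_id = c("a", "b"), f1 = c(0, 1), f2 = c(1, 0)),
    indicator_meta(c("f1", "f2"), "natural")
  )
  expect_equal(nrow(transitive_reduction(build_poset(anti))), 0)

  set.seed(23)
  for (rep in 1:30) {
    p <- build_poset(random_unit_table(7, 2, values = seq(0, 1, 0.25)))
    cov <- transitive_reduction(p)
    C <- oracle_covers(p$below)
    idx <- which(C, arr.ind = TRUE)
    expect_equal(
      sort(paste(cov$from, cov$to)),
      sort(paste(p$elements[idx[, 1]], p$elements[idx[, 2]]))
    )
  }
})

test_that("transitive closure of the covers rebuilds the strict order", {
  set.seed(24)
  for (rep in 1:20) {
    p <- build_poset(random_unit_table(8, 2, values = seq(0, 1, 0.2)))
    cov <- transitive_reduction(p)
    n <- length(p$elements)
    R <- matrix(FALSE, n, n, dimnames = dimnames(p$below))
    for (k in seq_len(nrow(cov))) R[cov$from[k], cov$to[k]] <- TRUE
    # Warshall closure
    for (m in seq_len(n)) R <- R | (R[, m] %o% R[m, ])
    expect_equal(R, p$below)
  }
})

test_that("levels are counted top-down from the maximal elements", {
  h <- hasse_diagram(six_county_example())
  expect_equal(h$levels[["AES"]], 1)
  expect_equal(unname(h$levels[c("TQ", "KYQ", "WL")]), c(2, 2, 2))
  expect_equal(h$levels[["KYZ"]], 3)
  expect_equal(h$L, 3)

  anti <- build_poset(oriented_table(
    tibble::tibble(unit_id = c("a", "b", "c"),
                   f1 = c(0, 0.5, 1), f2 = c(1, 0.5, 0)),
    indicator_meta(c("f1", "f2"), "natural")
  ))
  h_anti <- hasse_diagram(anti)
  expect_equal(unname(h_anti$levels), c(1, 1, 1))
  expect_equal(h_anti$L, 1)

  # level monotonicity: a < b implies level(a) < level(b)
  set.seed(25)
  for (rep in 1:20) {
    p <- build_poset(random_unit_table(8, 3))
    lev <- hasse_diagram(p)$levels
    idx <- which(p$below, arr.ind = TRUE)
    if (nrow(idx)) {
      expect_true(all(lev[p$elements[idx[, 1]]] < lev[p$elements[idx[, 2]]]))
    }
  }
})

test_that("level assignment matches the exhaustive longest-path oracle", {
  set.seed(26)
  for (rep in 1:30) {
    p <- build_poset(random_unit_table(8, 2, values = seq(0, 1, 0.25)))
    h <- hasse_diagram(p)
    C <- oracle_covers(p$below)
    expect_equal(h$levels[p$elements], oracle_levels(C))
  }
})

test_that("cyclic edge sets are rejected by level assignment", {
  covers <- tibble::tibble(from = c("a", "b"), to = c("b", "a"))
  expect_error(assign_levels(c("a", "b"), covers), "cycle")
})

test_that("maximal chains are all source-to-sink cover paths", {
  h <- hasse_diagram(six_county_example())
  expect_equal(
    chain_key(maximal_chains(h)),
    sort(c("AES>TQ>KYZ", "KYQ>KYZ", "WL>KYZ"))
  )

  edge <- hasse_diagram(oriented_table(
    tibble::tibble(unit_id = c("a", "b"), f1 = c(0, 1)),
    indicator_meta("f1", "natural")
  ))
  expect_equal(maximal_chains(edge), list(c("a", "b")))

  set.seed(27)
  for (rep in 1:25) {
    p <- build_poset(random_unit_table(7, 2, values = seq(0, 1, 0.25)))
    h <- hasse_diagram(p)
    expect_equal(chain_key(h$chains), chain_key(oracle_chains(oracle_covers(p$below))))
  }
})

test_that("isolated elements are those comparable with nothing", {
  p6 <- build_poset(six_county_example())
  expect_equal(isolated_elements(p6), "ZLT")

  chain <- build_poset(oriented_table(
    tibble::tibble(unit_id = c("a", "b", "c"), f1 = c(0, 0.5, 1)),
    indicator_meta("f1", "natural")
  ))
  expect_equal(isolated_elements(chain), character(0))

  anti <- build_poset(oriented_table(
    tibble::tibble(unit_id = c("a", "b", "c"),
                   f1 = c(0, 0.5, 1), f2 = c(1, 0.5, 0)),
    indicator_meta(c("f1", "f2"), "natural")
  ))
  expect_equal(isolated_elements(anti), c("a", "b", "c"))
})

test_that("LPOM0 average rank has exact closed-form behaviour", {
  chain3 <- build_poset(oriented_table(
    tibble::tibble(unit_id = c("a", "b", "c"), f1 = c(0, 0.5, 1)),
    indicator_meta("f1", "natural")
  ))
  rk <- lpom_average_rank(chain3)
  expect_equal(rk$Rav[match(c("a", "b", "c"), rk$element)], c(1, 2, 3))

  anti2 <- build_poset(oriented_table(
    tibble::tibble(unit_id = c("a", "b"), f1 = c(0, 1), f2 = c(1, 0)),
    indicator_meta(c("f1", "f2"), "natural")
  ))
  expect_equal(lpom_average_rank(anti2)$Rav, c(1.5, 1.5))
})

test_that("LPOM0 matches hand values and exact mean-rank order on a 4-poset", {
  # poset a<c, b<c, b<d with all other pairs incomparable
  tab <- oriented_table(
    tibble::tibble(unit_id = c("a", "b", "c", "d"),
                   f1 = c(0.4, 0.0, 0.5, 0.1),
                   f2 = c(0.1, 0.3, 0.4, 0.9)),
    indicator_meta(c("f1", "f2"), "natural")
  )
  p <- build_poset(tab)
  expect_true(p$below["a", "c"] && p$below["b", "c"] && p$below["b", "d"])
  expect_equal(sum(p$below), 3)
  rk <- lpom_average_rank(p)
  rav <- setNames(rk$Rav, rk$element)
  expect_equal(rav[["a"]], 5 / 3)
  expect_equal(rav[["b"]], 1.25)
  expect_equal(rav[["c"]], 3.75)
  expect_equal(rav[["d"]], 10 / 3)
  # ordering agrees with the exact mean rank over all linear extensions
  exact <- oracle_le_mean_rank(p$below)
  expect_equal(order(rav[p$elements]), order(exact[p$elements]))
})

test_that("LPOM0 counts partition every element's co-elements", {
  set.seed(28)
  for (rep in 1:15) {
    p <- build_poset(random_unit_table(8, 3))
    rk <- lpom_average_rank(p)
    N <- length(p$elements)
    expect_true(all(rk$S + rk$P + rk$U == N - 1))
    expect_true(all(rk$Rav >= 1 & rk$Rav <= N))
  }
})

test_that("adding an indicator can only remove comparabilities", {
  set.seed(29)
  for (rep in 1:15) {
    tab <- random_unit_table(8, 3)
    p_sub <- build_poset(tab, columns = c("f1", "f2"))
    p_all <- build_poset(tab, columns = c("f1", "f2", "f3"))
    # no duplicate vectors expected with continuous values; same elements
    expect_equal(p_sub$elements, p_all$elements)
    expect_true(all(p_all$below <= p_sub$below))
  }
})

test_that("tie tolerance snaps near-equal vectors into one class", {
  tab <- oriented_table(
    tibble::tibble(unit_id = c("a", "b", "c"),
                   f1 = c(0.100, 0.101, 0.9)),
    indicator_meta("f1", "natural")
  )
  exact <- build_poset(tab)
  expect_equal(length(exact$elements), 3)
  coarse <- build_poset(tab, tol = 0.01)
  expect_equal(length(coarse$elements), 2)
  expect_equal(coarse$members[[1]], c("a", "b"))
})
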