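# Independent brute-force oracles for the poset machinery, plus small
# fixture generators. Everything here works from first principles
# (exhaustive enumeration) so it stays independent of the package's own
# algorithms.

# random unit table inducing a componentwise order; returns an oriented table
random_unit_table <- function(n, k, values = NULL) {
  ids <- sprintf("u%02d", seq_len(n))
  data <- tibble::tibble(unit_id = ids)
  meta <- indicator_meta(sprintf("f%d", seq_len(k)), rep("natural", k))
  for (j in seq_len(k)) {
    data[[paste0("f", j)]] <- if (is.null(values)) runif(n) else sample(values, n, replace = TRUE)
  }
  oriented_table(data, meta)
}

# strict-below matrix straight from pairwise definition (no collapsing: callers
# use tables without duplicate vectors)
oracle_below <- function(V) {
  n <- nrow(V)
  B <- matrix(FALSE, n, n, dimnames = list(rownames(V), rownames(V)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && all(V[i, ] <= V[j, ]) && any(V[i, ] < V[j, ])) B[i, j] <- TRUE
    }
  }
  B
}

# covers by the middle-element test, O(n^3)
oracle_covers <- function(B) {
  n <- nrow(B)
  C <- matrix(FALSE, n, n, dimnames = dimnames(B))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (!B[i, j]) next
      middle <- FALSE
      for (k in seq_len(n)) {
        if (B[i, k] && B[k, j]) middle <- TRUE
      }
      C[i, j] <- !middle
    }
  }
  C
}

# longest upward path length from each element, by exhaustive path search
oracle_depth <- function(C) {
  n <- nrow(C)
  longest <- function(i) {
    succ <- which(C[i, ])
    if (!length(succ)) return(0L)
    1L + max(vapply(succ, longest, integer(1)))
  }
  vapply(seq_len(n), longest, integer(1))
}

oracle_levels <- function(C) {
  depth <- oracle_depth(C)
  stats::setNames(1L + max(depth) - depth, rownames(C))
}

# maximal source-to-sink cover paths via igraph's exhaustive simple-path search
oracle_chains <- function(C) {
  elements <- rownames(C)
  if (!any(C)) return(list())
  idx <- which(C, arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = elements[idx[, 1]], to = elements[idx[, 2]]),
    vertices = elements
  )
  sources <- elements[igraph::degree(g, mode = "in") == 0 &
                        igraph::degree(g, mode = "out") > 0]
  sinks <- elements[igraph::degree(g, mode = "out") == 0]
  chains <- list()
  for (s in sources) {
    paths <- igraph::all_simple_paths(g, from = s, to = sinks, mode = "out")
    for (p in paths) {
      nm <- names(p)
      last <- nm[length(nm)]
      if (last %in% sinks) chains[[length(chains) + 1]] <- nm
    }
  }
  chains
}

# exact mean rank over all linear extensions (rank 1 = bottom), N <= 8
oracle_le_mean_rank <- function(B) {
  n <- nrow(B)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  total <- rep(0, n)
  count <- 0
  for (p in perms(seq_len(n))) {
    pos <- order(p)  # pos[i] = position of element i in the order p
    ok <- TRUE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (B[i, j] && pos[i] > pos[j]) ok <- FALSE
      }
    }
    if (ok) {
      total <- total + pos
      count <- count + 1
    }
  }
  stats::setNames(total / count, rownames(B))
}

chain_key <- function(chains) sort(vapply(chains, paste, "", collapse = ">"))

# brute-force nearest-source distance (km) for distance_to_class
oracle_distance <- function(grid, code) {
  src <- which(grid$values == code, arr.ind = TRUE)
  side <- sqrt(grid$cell_area)
  out <- matrix(NA_real_, nrow(grid$values), ncol(grid$values))
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(ncol(out))) {
      out[i, j] <- min(sqrt((src[, 1] - i)^2 + (src[, 2] - j)^2)) * side
    }
  }
  out
}

# random valid land-cover grid pair (shared scheme/shape), with some nodata
random_grid_pair <- function(nr = 10, nc = 10, p_nodata = 0.1) {
  sch <- default_scheme()
  mk <- function(epoch) {
    v <- matrix(sample(sch$code, nr * nc, replace = TRUE), nr, nc)
    v[runif(nr * nc) < p_nodata] <- -9999L
    land_grid(v, scheme = sch, nodata = -9999L, cell_area = 0.25, epoch = epoch)
  }
  list(a = mk(1990L), b = mk(2000L))
}
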