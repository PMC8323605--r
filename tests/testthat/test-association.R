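pts <- function(...) {
  m <- rbind(...)
  if (is.null(m)) {
    return(data.frame(frame = integer(), det_id = integer(),
                      x = numeric(), y = numeric()))
  }
  data.frame(frame = 0L, det_id = seq_len(nrow(m)), x = m[, 1], y = m[, 2])
}

test_that("cost matrix entries are Euclidean distances with preserved shape", {
  expect_equal(build_cost_matrix(pts(c(0, 0)), pts(c(0, 0))),
               matrix(0, 1, 1))
  # 3-4-5 triangles
  expect_equal(build_cost_matrix(pts(c(0, 0), c(3, 4)),
                                 pts(c(3, 4), c(0, 0))),
               matrix(c(5, 0, 0, 5), 2, 2))
  expect_equal(build_cost_matrix(pts(c(0, 0)), pts(c(1, 1), c(2, 2))),
               matrix(c(sqrt(2), 2 * sqrt(2)), 1, 2))
  # empty side keeps the recorded shape
  e <- build_cost_matrix(pts(c(0, 0)), pts())
  expect_equal(dim(e), c(1L, 0L))
  # symmetry: d(S_i, T_j) = d(T_j, S_i)
  a <- pts(c(1, 2), c(5, 9)); b <- pts(c(0, 4), c(7, 7), c(2, 2))
  expect_equal(build_cost_matrix(a, b), t(build_cost_matrix(b, a)))
})

test_that("the delta * median gate rejects exactly the isolated sources", {
  # all entries equal: row min = median <= delta * median, nothing rejected
  allsame <- matrix(4, 3, 3)
  g <- reject_noise(allsame, assoc_config(delta = 1))
  expect_length(g$rejected, 0)

  # single entry at the boundary: 10 is not strictly larger than 1 * 10
  g1 <- reject_noise(matrix(10, 1, 1), assoc_config(delta = 1))
  expect_length(g1$rejected, 0)

  # constructed 5x5: four near rows (min 1, entries <= 3), one far row
  cost <- matrix(3, 5, 5)
  diag(cost) <- 1
  cost[5, ] <- 100
  g2 <- reject_noise(cost, assoc_config(delta = 3))
  expect_equal(g2$rejected, 5L)
  expect_equal(g2$kept, 1:4)
  expect_equal(nrow(g2$cost), 4)
  expect_equal(g2$threshold, 3 * median(cost))
})

test_that("assignment matches hand-checked small instances", {
  s <- solve_assignment(matrix(c(0, 5, 5, 0), 2, 2, byrow = TRUE))
  expect_equal(s$matches, cbind(row = 1:2, col = 1:2))
  expect_equal(s$total_cost, 0)

  s2 <- solve_assignment(matrix(c(1, 2, 3, 2, 4, 6), 2, 3, byrow = TRUE))
  expect_equal(s2$matches, cbind(row = 1:2, col = c(2L, 1L)))
  expect_equal(s2$total_cost, 4)
  expect_equal(s2$unmatched_cols, 3L)
})

test_that("assignment equals the brute-force optimum on random rectangular instances", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(1:6, 1); m <- sample(1:6, 1)
    cost <- matrix(stats::runif(n * m), n, m)
    s <- solve_assignment(cost)
    expect_equal(s$total_cost, brute_assignment_cost(cost), tolerance = 1e-12)
    expect_equal(nrow(s$matches), min(n, m))
  }
})

test_that("assignment is equivariant under source permutations", {
  set.seed(55)
  for (i in 1:20) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    cost <- matrix(stats::runif(n * m), n, m)
    perm <- sample(n)
    s1 <- solve_assignment(cost)
    s2 <- solve_assignment(cost[perm, , drop = FALSE])
    expect_equal(s2$total_cost, s1$total_cost, tolerance = 1e-12)
    # row i of the original appears as row match(i, perm) in the permuted
    map1 <- s1$matches[, "col"][order(s1$matches[, "row"])]
    rows1 <- sort(s1$matches[, "row"])
    remapped <- integer(0)
    for (k in seq_len(nrow(s2$matches))) {
      remapped[perm[s2$matches[k, "row"]]] <- s2$matches[k, "col"]
    }
    expect_equal(remapped[rows1], map1)
  }
})

test_that("associate partitions sources and targets", {
  a <- pts(c(0, 0), c(10, 0), c(20, 0))
  # identical sets: all matched at cost zero
  r <- associate(a, a)
  expect_equal(nrow(r$matched), 3)
  expect_equal(r$matched$cost, rep(0, 3))
  expect_equal(nrow(r$unmatched_sources), 0)
  expect_equal(nrow(r$unmatched_targets), 0)

  # 3 sources, 2 nearby targets: one unmatched source
  r2 <- associate(a, pts(c(0, 1), c(10, 1)))
  expect_equal(nrow(r2$matched), 2)
  expect_equal(nrow(r2$unmatched_sources) + nrow(r2$rejected_noise), 1)

  # 2 sources, 3 targets: one unmatched target
  r3 <- associate(pts(c(0, 0), c(10, 0)), a)
  expect_equal(nrow(r3$matched), 2)
  expect_equal(nrow(r3$unmatched_targets), 1)

  # partition invariant on random instances
  set.seed(77)
  for (i in 1:20) {
    n <- sample(0:5, 1); m <- sample(0:5, 1)
    src <- data.frame(frame = rep(0L, n), det_id = seq_len(n),
                      x = stats::runif(n, 0, 50), y = stats::runif(n, 0, 50))
    tgt <- data.frame(frame = rep(1L, m), det_id = seq_len(m),
                      x = stats::runif(m, 0, 50), y = stats::runif(m, 0, 50))
    r <- associate(src, tgt)
    expect_equal(nrow(r$matched) + nrow(r$unmatched_sources) +
                 nrow(r$rejected_noise), n)
    expect_equal(nrow(r$matched) + nrow(r$unmatched_targets), m)
  }
})
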