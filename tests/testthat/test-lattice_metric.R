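# Parametric lattice distance between interval trees

test_that("interval_distance matches the weighted-L1 closed form", {
  expect_equal(interval_distance(c(0.5, 0.5), c(0.5, 0.5), 1), 0)
  expect_equal(interval_distance(c(0, 1), c(0, 1), 3), 0)
  # frozen value: closed form 2 * (|0.2-0.3| + |0.4-0.7|) = 0.8
  expect_equal(interval_distance(c(0.2, 0.4), c(0.3, 0.7), 2), 0.8)
  set.seed(31)
  for (i in 1:200) {
    a <- sort(runif(2, -2, 2)); b <- sort(runif(2, -2, 2))
    lam <- runif(1, 0, 5)
    expect_equal(interval_distance(a, b, lam),
                 lam * (abs(a[1] - b[1]) + abs(a[2] - b[2])))
  }
  expect_error(interval_distance(c(0, 1), c(0, 1), -1), "nonnegative")
})

test_that("a degenerate point inside an interval is at constant distance
           lambda * interval width", {
  set.seed(32)
  for (i in 1:50) {
    iv <- sort(runif(2)); lam <- runif(1, 0, 3)
    x <- runif(1, iv[1], iv[2])
    expect_equal(interval_distance(c(x, x), iv, lam), lam * (iv[2] - iv[1]))
  }
})

test_that("widening a prototype interval away from an outside point never
           decreases the distance, and inside distance grows with width", {
  set.seed(33)
  for (i in 1:50) {
    iv <- sort(runif(2, 0.3, 0.7))
    x <- 0.9  # outside, above the interval
    # widening the far (lower) endpoint moves the envelope away from x
    away <- c(iv[1] - runif(1, 0, 0.2), iv[2])
    expect_gte(interval_distance(c(x, x), away, 1),
               interval_distance(c(x, x), iv, 1))
    # widening toward the point shrinks |x - hi|: distance decreases
    toward <- c(iv[1], iv[2] + runif(1, 0.01, 0.9 - iv[2]))
    expect_lte(interval_distance(c(x, x), toward, 1),
               interval_distance(c(x, x), iv, 1))
    # for an inside point the distance is the (widening) interval width
    xin <- runif(1, iv[1], iv[2])
    expect_gte(interval_distance(c(xin, xin), away, 1),
               interval_distance(c(xin, xin), iv, 1))
  }
})

test_that("branch_distance expands to parent term plus k times children", {
  ta <- rand_trivial_tree()
  tb <- ta
  # one child of primary 1 (node 12) differs by delta in r
  delta <- 0.37
  tb$r[12] <- tb$r[12] + delta
  p1 <- metric_params()
  expect_equal(branch_distance(ta, tb, 1, p1, "r"), 2 * delta)  # |.|+|.| twice
  # doubling the child weight doubles the children's contribution
  p2 <- metric_params(k_r123 = c(2, 1, 1))
  expect_equal(branch_distance(ta, tb, 1, p2, "r"), 4 * delta)
  # a leaf primary contributes only its own term
  tc <- ta; tc$r[5] <- tc$r[5] + delta
  expect_equal(branch_distance(ta, tc, 5, p1, "r"), 2 * delta)
  expect_equal(branch_distance(ta, tc, 5, p2, "r"), 2 * delta)
  expect_equal(branch_distance(ta, ta, 3, p1, "r"), 0)
})

test_that("tree_distance agrees with the flat weighted-L1 oracle on random
           trivial and interval trees", {
  set.seed(34)
  for (i in 1:60) {
    params <- rand_params()
    ta <- if (i %% 2) rand_trivial_tree() else rand_interval_tree()
    tb <- if (i %% 3) rand_trivial_tree() else rand_interval_tree()
    d <- tree_distance(ta, tb, params)
    o <- flat_distance_oracle(ta, tb, params)
    expect_lt(abs(d - o), 1e-9 * max(o, 1))
  }
})

test_that("tree_distance is zero on identical trees and symmetric", {
  set.seed(35)
  for (i in 1:25) {
    ta <- rand_interval_tree(); tb <- rand_trivial_tree()
    params <- rand_params()
    expect_equal(tree_distance(ta, ta, params), 0)
    expect_equal(tree_distance(ta, tb, params), tree_distance(tb, ta, params))
  }
})

test_that("the vectorized distance matrix equals the scalar tree distance", {
  set.seed(36)
  trees <- replicate(6, rand_trivial_tree(), simplify = FALSE)
  protos <- replicate(3, rand_interval_tree(), simplify = FALSE)
  params <- rand_params()
  X <- lcbehave:::.trees_to_matrix(trees)
  lh <- lcbehave:::.lo_hi_matrices(protos)
  D <- lcbehave:::.dist_matrix(X, lh$lo, lh$hi, params)
  for (i in 1:6) for (j in 1:3)
    expect_equal(D[i, j], tree_distance(trees[[i]], protos[[j]], params))
})

test_that("tree_centroid averages coordinates and keeps phi in range", {
  t1 <- rand_trivial_tree()
  expect_equal(tree_centroid(list(t1))$r, t1$r)
  t2 <- t1
  t1$r[7] <- 0.2; t2$r[7] <- 0.4
  expect_equal(tree_centroid(list(t1, t2))$r[7], 0.3)
  set.seed(37)
  trees <- replicate(5, rand_trivial_tree(), simplify = FALSE)
  cen <- tree_centroid(trees)
  expect_true(all(cen$phi >= -pi & cen$phi <= pi))
  expect_error(tree_centroid(list()), "empty")
  # the centroid of a prototype's endpoint trees is its midpoint tree
  proto <- induce_prototype(trees[1:2])
  lo_tree <- structure(list(r = proto$r_lo, phi = proto$phi_lo,
                            provenance = NULL), class = "face_tree")
  hi_tree <- structure(list(r = proto$r_hi, phi = proto$phi_hi,
                            provenance = NULL), class = "face_tree")
  expect_equal(tree_centroid(list(lo_tree, hi_tree))$r,
               prototype_midpoint(proto)$r)
})

test_that("metric params validate, serialize and round-trip", {
  expect_error(metric_params(lambda_r = rep(-1, 59)), "nonnegative")
  expect_error(metric_params(k_r123 = 1:2), "length")
  p <- rand_params()
  f <- withr::local_tempfile(fileext = ".json")
  params_to_json(p, f)
  q <- params_from_json(f)
  expect_equal(unclass(q), unclass(p), tolerance = 0)
})
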