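test_that("square-root transform records its history", {
  m <- toy_matrix(cbind(a = c(4, 9), b = c(0, 1)))
  tr <- sqrt_transform(m)
  expect_equal(unname(unclass(tr)[1, ]), c(2, 0))
  expect_equal(unname(unclass(tr)[2, ]), c(3, 1))
  expect_true("sqrt" %in% attr(tr, "transform"))
  expect_warning(sqrt_transform(tr), "fourth-root")
  # monotone: cell ordering preserved
  v <- unclass(m); v2 <- unclass(tr)
  expect_equal(order(v), order(v2))
})

test_that("Bray-Curtis matches its closed form and properties", {
  expect_equal(bray_curtis(c(1, 0, 3), c(1, 2, 0)), 5 / 7)
  expect_equal(bray_curtis(c(2, 5), c(2, 5)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 4)), 1)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  # scale invariance and label-permutation invariance
  set.seed(1)
  for (i in 1:20) {
    u <- rpois(8, 4); v <- rpois(8, 4)
    if (sum(u) + sum(v) == 0) next
    expect_equal(bray_curtis(3.7 * u, 3.7 * v), bray_curtis(u, v))
    p <- sample(8)
    expect_equal(bray_curtis(u[p], v[p]), bray_curtis(u, v))
  }
})

test_that("distance matrix agrees with a pairwise brute-force oracle", {
  set.seed(7)
  m <- toy_matrix(matrix(rpois(6 * 5, 5) + 1, 6, 5))
  d <- as.matrix(distance_matrix(m, "bray_curtis"))
  for (i in 1:6) for (j in 1:6) {
    want <- if (i == j) 0 else bc_oracle(unclass(m)[i, ], unclass(m)[j, ])
    expect_equal(d[i, j], want, tolerance = 1e-12)
  }
  expect_equal(d, t(d))
  # the C++ engine route agrees too
  dcpp <- depthzone:::.bray_curtis_matrix(unclass(m))
  expect_equal(unname(d), dcpp, tolerance = 1e-12)

  expect_error(distance_matrix(toy_matrix(cbind(a = c(0, 1))), "bray_curtis"),
               "all-zero")
})

test_that("euclidean distance on 1-D data is absolute difference", {
  m <- toy_matrix(cbind(a = c(1, 4, 9)))
  d <- as.matrix(distance_matrix(m, "euclidean"))
  expect_equal(d[1, 2], 3)
  expect_equal(d[1, 3], 8)
  expect_equal(d[2, 3], 5)
})

test_that("beta partition follows the Sorensen/Simpson decomposition", {
  same <- beta_partition(c("x", "y"), c("x", "y"))
  expect_equal(c(same$beta_sor, same$beta_sim, same$beta_nes), c(0, 0, 0))

  disj <- beta_partition(c("x"), c("y", "z"))
  expect_equal(disj$beta_sor, 1)
  expect_equal(disj$beta_sim, 1)
  expect_equal(disj$beta_nes, 0)

  mixed <- beta_partition(c("s", "u1"), c("s", "u2"))
  expect_equal(mixed$a, 1)
  expect_equal(mixed$beta_sor, 0.5)
  expect_equal(mixed$beta_sim, 0.5)
  expect_equal(mixed$beta_nes, 0)

  # strict nesting: no turnover, all dissimilarity is nestedness
  nest <- beta_partition(c("a", "b", "c"), c("a"))
  expect_equal(nest$beta_sim, 0)
  expect_equal(nest$beta_nes, nest$beta_sor)

  expect_error(beta_partition(character(0), character(0)), "empty")
})

test_that("beta indices respect their ordering invariants on random sets", {
  set.seed(42)
  pool <- paste0("sp", 1:15)
  for (i in 1:50) {
    g1 <- sample(pool, sample(1:12, 1))
    g2 <- sample(pool, sample(1:12, 1))
    bp <- beta_partition(g1, g2)
    expect_true(bp$beta_sor >= bp$beta_sim - 1e-12)
    expect_true(bp$beta_nes >= -1e-12 && bp$beta_nes <= bp$beta_sor + 1e-12)
    expect_true(all(c(bp$beta_sor, bp$beta_sim) >= 0 &
                      c(bp$beta_sor, bp$beta_sim) <= 1))
  }
})

test_that("zone beta table aggregates per site with SE across sites", {
  # two sites with identical composition: SE = 0
  cells <- rbind(c(5, 5, 0, 0), c(5, 5, 0, 0), c(0, 0, 5, 5), c(0, 0, 5, 5))
  colnames(cells) <- paste0("sp", 1:4)
  mk <- function(site) depthzone:::new_abundance_matrix(
    `rownames<-`(cells, paste0(site, ":", c(40, 50, 60, 70))),
    rep(site, 4), as.list(c(40, 50, 60, 70)))
  m <- depthzone:::new_abundance_matrix(
    rbind(unclass(mk("A")), unclass(mk("B"))),
    rep(c("A", "B"), each = 4), as.list(rep(c(40, 50, 60, 70), 2)))
  asg <- data.frame(site = rep(c("A", "B"), each = 4),
                    bin_start = rep(c(40, 50, 60, 70), 2),
                    zone = rep(rep(c("upper_mesophotic", "lower_mesophotic"),
                                   each = 2), 2))
  tab <- zone_beta_table(m, asg)
  expect_equal(nrow(tab), 2) # one pair per site
  expect_equal(tab$beta_sor, c(1, 1)) # disjoint zones
  summ <- attr(tab, "summary")
  expect_equal(summ$beta_sor_mean, 1)
  expect_equal(summ$beta_sor_se, 0)

  # single site: SE reported as absent
  tab1 <- zone_beta_table(mk("A"), asg[asg$site == "A", ])
  expect_true(is.na(attr(tab1, "summary")$beta_sor_se))
})
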