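test_that("one-way PERMANOVA on Euclidean distances reproduces classical ANOVA F", {
  # printed 2-group toy data, univariate
  y <- c(3.1, 2.7, 3.5, 5.9, 6.2, 5.4)
  g <- rep(c("low", "high"), each = 3)
  m <- toy_matrix(cbind(y = y))
  d <- distance_matrix(m, "euclidean")
  pm <- permanova(d, g, n_perm = 199, seed = 1)
  f_classic <- summary(aov(y ~ g))[[1]]$`F value`[1]
  expect_equal(pm$pseudo_f[1], f_classic, tolerance = 1e-11)
  # R2 partition sums to one
  expect_equal(sum(pm$r_squared[pm$term != "Total"]), 1)

  # a 2x3 design with three levels
  y2 <- c(1.2, 1.9, 4.4, 4.0, 9.1, 8.6)
  g2 <- rep(c("a", "b", "c"), each = 2)
  pm2 <- permanova(distance_matrix(toy_matrix(cbind(y = y2)), "euclidean"),
                   g2, n_perm = 199, seed = 1)
  f2 <- summary(aov(y2 ~ g2))[[1]]$`F value`[1]
  expect_equal(pm2$pseudo_f[1], f2, tolerance = 1e-11)
})

test_that("PERMANOVA rejects degenerate single-level designs", {
  m <- toy_matrix(matrix(rpois(12, 5) + 1, 4, 3))
  d <- distance_matrix(m, "bray_curtis")
  expect_error(permanova(d, rep("same", 4)), "2 levels")
  expect_warning(permanova(d, c("a", "a", "a", "b"), n_perm = 49, seed = 1),
                 "single sample")
})

test_that("PERMANOVA SS and R2 are seed-invariant; only p changes", {
  set.seed(2)
  m <- toy_matrix(matrix(rpois(8 * 5, 6) + 1, 8, 5))
  d <- distance_matrix(m, "bray_curtis")
  g <- rep(c("x", "y"), each = 4)
  p1 <- permanova(d, g, n_perm = 99, seed = 1)
  p2 <- permanova(d, g, n_perm = 99, seed = 999)
  expect_equal(p1$sum_sq, p2$sum_sq)
  expect_equal(p1$r_squared, p2$r_squared)
})

test_that("two-way PERMANOVA partitions zone, site and interaction", {
  set.seed(3)
  zone <- rep(c("shallow", "deep"), each = 6)
  site <- rep(rep(c("A", "B"), each = 3), 2)
  mu <- ifelse(zone == "shallow", 2, 8) + ifelse(site == "A", 0, 1.5)
  m <- toy_matrix(cbind(s1 = rpois(12, mu) + 1, s2 = rpois(12, rev(mu)) + 1))
  d <- distance_matrix(m, "bray_curtis")
  pm <- permanova(d, zone, groups2 = site, n_perm = 99, seed = 1)
  expect_equal(pm$term[1:3], c("factor1", "factor2", "interaction"))
  expect_equal(sum(pm$r_squared[pm$term != "Total"]), 1)
})

test_that("SIMPER contributions decompose the pair dissimilarity exactly", {
  m <- toy_matrix(rbind(c(1, 0, 3), c(1, 2, 0)))
  st <- simper_analysis(m, c("g1", "g2"), n_perm = 49, seed = 1)
  st <- st[order(st$species), ]
  expect_equal(st$average, c(0, 2 / 7, 3 / 7))
  expect_equal(attr(st, "overall"), 5 / 7)
  expect_equal(sum(st$contribution_pct), 100, tolerance = 1e-9)
})

test_that("SIMPER on identical groups contributes nothing", {
  m <- toy_matrix(rbind(c(2, 3), c(2, 3), c(2, 3), c(2, 3)))
  st <- simper_analysis(m, rep(c("a", "b"), each = 2), n_perm = 49, seed = 1)
  expect_equal(st$average, c(0, 0))
})

test_that("SIMPER agrees with the vegan implementation on random data", {
  set.seed(8)
  m <- toy_matrix(matrix(rpois(10 * 6, 5), 10, 6) + 1)
  grp <- rep(c("a", "b"), each = 5)
  st <- simper_analysis(m, grp, n_perm = 49, seed = 1)
  vg <- summary(vegan::simper(unclass(m), grp, permutations = 0))$a_b
  st <- st[match(rownames(vg), st$species), ]
  expect_equal(st$average, unname(vg$average), tolerance = 1e-10)
})

test_that("a planted strong indicator species is recovered across seeds", {
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    # background community plus one species dominating the shallow group
    base <- matrix(rpois(8 * 6, 3), 8, 6)
    indicator <- c(rpois(4, 40), rpois(4, 1))
    m <- toy_matrix(cbind(base, ind = indicator))
    st <- simper_analysis(sqrt_transform(m), rep(c("shallow", "deep"), each = 4),
                          n_perm = 199, seed = s)
    got <- indicator_species(st)
    if ("ind" %in% got$species &&
        got$higher_in[got$species == "ind"] == "shallow") hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("indicator rule keeps species above 5% contribution and p < 0.05", {
  r <- data.frame(species = c("pass", "low_contrib", "high_p"),
                  average = c(0.3, 0.1, 0.3),
                  contribution_pct = c(6, 4, 30),
                  higher_in = c("shallow", "shallow", "deep"),
                  p_value = c(0.01, 0.001, 0.2))
  got <- indicator_species(r)
  expect_equal(got$species, "pass")
  none <- indicator_species(r, contrib_threshold = 50)
  expect_equal(nrow(none), 0)
  deep_only <- indicator_species(r, p_threshold = 0.5, direction = "deep")
  expect_equal(deep_only$species, "high_p")
})
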