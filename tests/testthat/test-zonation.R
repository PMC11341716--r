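test_that("clusters pool into contiguous named zones at main branches", {
  # hand-constructed: 16 bins in 4 disjoint blocks; cutting at the
  # 3 highest branches gives 4 contiguous zones
  cells2 <- cbind(unclass(block_matrix(4, 3, 60)),
                  matrix(0, 8, 6))
  cells3 <- cbind(matrix(0, 8, 6), unclass(block_matrix(4, 3, 60)))
  big <- toy_matrix(rbind(cells2, cells3), bins = seq(40, 190, by = 10))
  sc <- simprof_clusters(big, alpha = 0.05, n_expected = 99, n_null = 199,
                         seed = 3)
  expect_equal(length(sc$members), 4)
  asg <- pool_clusters_to_zones(sc, sample_meta(big), n_zones = 4)
  expect_equal(unique(asg$zone[order(asg$bin_start)]),
               c("upper_mesophotic", "lower_mesophotic",
                 "upper_rariphotic", "lower_rariphotic"))
  # identity grouping: 4 clusters to 4 zones keeps cluster boundaries
  expect_equal(depth_breaks(asg)$break_depth, c(80, 120, 160))

  # n_zones = 1: everything in one zone, no breaks
  asg1 <- pool_clusters_to_zones(sc, sample_meta(big), n_zones = 1,
                                 zone_names = "all")
  expect_equal(unique(asg1$zone), "all")
  expect_equal(nrow(depth_breaks(asg1)), 0)
})

test_that("depth breaks are labelled by the deeper zone's first bin", {
  asg <- data.frame(site = "A",
                    bin_start = seq(40, 140, by = 10),
                    zone = rep(c("upper_mesophotic", "lower_mesophotic"),
                               c(5, 6)))
  br <- depth_breaks(asg)
  expect_equal(br$break_depth, 90)
  expect_equal(br$shallower_zone, "upper_mesophotic")
})

test_that("non-contiguous zones error unless forced", {
  tree <- hclust(dist(c(1, 10, 2, 11)), method = "complete")
  tree$labels <- c("40", "50", "60", "70")
  sc <- list(tree = tree, clusters = setNames(c(1L, 2L, 1L, 2L),
                                              tree$labels))
  meta <- data.frame(sample = tree$labels, site = "A",
                     bin_start = c(40, 50, 60, 70), n_bins = 1)
  expect_error(pool_clusters_to_zones(sc, meta, n_zones = 2), "non-contiguous")
  expect_warning(pool_clusters_to_zones(sc, meta, n_zones = 2, force = TRUE),
                 "non-contiguous")
})

test_that("two planted zones are recovered with an accurate break", {
  # well-separated niches, ample counts: the planted break at 100 m is
  # found within one bin in most seeds
  hits <- 0
  for (s in 1:5) {
    cfg <- sim_config(n_sites = 1, n_zones = 2, depth_range = c(40, 160),
                      species_per_zone = 20, seed = s)
    sv <- simulate_community(cfg)
    z <- suppressWarnings(depth_zonation(
      sv$observations, site = "site1", window = c(40, 160), n_zones = 2,
      zone_names = c("shallow", "deep"), n_null = 999, seed = s,
      force = TRUE))
    br <- z$breaks$break_depth
    if (length(br) >= 1 && any(abs(br - 100) <= 10)) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("the zonation object carries a consistent analysis state", {
  cfg <- sim_config(n_sites = 1, seed = 8)
  sv <- simulate_community(cfg)
  z <- suppressWarnings(depth_zonation(sv$observations, site = "site1",
                                       n_null = 999, seed = 8, force = TRUE))
  expect_s3_class(z, "depth_zonation")
  expect_equal(nrow(z$assignment), 26)
  expect_true(all(diff(z$assignment$bin_start) > 0))
  expect_true(all(z$assignment$zone %in%
                    c("upper_mesophotic", "lower_mesophotic",
                      "upper_rariphotic", "lower_rariphotic")))
  expect_true("sqrt" %in% attr(z$matrix, "transform"))
  expect_output(print(z), "Depth zonation")
  s <- summary(z)
  expect_output(print(s), "Zones")
  expect_identical(as.hclust(z), z$tree)
})

test_that("cross-site clustering splits by depth before site for identical sites", {
  cfg <- sim_config(n_sites = 2, site_sdlog = 0, seed = 13)
  sv <- simulate_community(cfg)
  cz <- suppressWarnings(crosssite_zonation(sv$observations, n_null = 999,
                                            seed = 13, force = TRUE))
  # the root split separates depths: both sites appear on each side
  merge <- cz$tree$merge
  root_left <- depthzone:::merge_leaves(merge, merge[nrow(merge), 1])
  meta <- sample_meta(cz$matrix)
  expect_equal(length(unique(meta$site[root_left])), 2)
  # and each side spans a depth range, not a site
  left_bins <- meta$bin_start[root_left]
  right_bins <- meta$bin_start[-root_left]
  expect_true(max(left_bins) < min(right_bins) ||
                max(right_bins) < min(left_bins))

  expect_error(crosssite_zonation(
    sv$observations[sv$observations$site == "site1", ]), "at least 2 sites")
})

test_that("Newick export round-trips through ape", {
  set.seed(3)
  m <- toy_matrix(matrix(rpois(5 * 4, 6) + 1, 5, 4))
  tree <- hclust(distance_matrix(m, "bray_curtis"), method = "complete")
  nwk <- dendrogram_newick(tree)
  ph <- ape::read.tree(text = nwk)
  expect_equal(sort(ph$tip.label), sort(tree$labels))
  # root-to-tip distance equals the root merge height for every tip
  depths <- ape::node.depth.edgelength(ph)[seq_along(ph$tip.label)]
  expect_equal(unname(depths), rep(max(tree$height), 5), tolerance = 1e-9)
})
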