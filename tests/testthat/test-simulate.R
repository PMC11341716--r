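test_that("configuration validation rejects impossible designs", {
  expect_error(sim_config(depth_range = c(100, 40)), "lo < hi")
  expect_error(sim_config(depth_range = c(40, 600)), "\\[0, 500\\]")
  expect_error(sim_config(n_zones = 1), "n_zones")
  expect_error(sim_config(bin_width = 0), "bin_width")
  expect_error(sim_config(depth_range = c(45, 300)), "multiples")
})

test_that("effort generation is reproducible and controlled by dispersion", {
  cfg <- sim_config(n_sites = 2, effort_sdlog = 0, effort_mean_hours = 2,
                    seed = 9)
  eff <- simulate_effort(cfg)$effort
  expect_true(all(abs(eff$hours - 2) < 1e-12)) # degenerate noise: exactly 2 h
  expect_equal(nrow(eff), 2 * 26)

  cfg2 <- sim_config(seed = 10)
  e1 <- simulate_effort(cfg2)
  e2 <- simulate_effort(cfg2)
  expect_identical(e1, e2) # same config + seed: identical tables

  # law of large numbers: mean per-bin effort near its target
  cfg3 <- sim_config(n_sites = 5, n_dives = 10, effort_mean_hours = 2,
                     effort_sdlog = 0.5, seed = 11)
  e3 <- simulate_effort(cfg3)$effort
  expect_gt(nrow(e3), 100)
  expect_lt(abs(mean(e3$hours) - 2), 0.2) # within 10% of 2 h
  expect_true(all(e3$hours > 0))
})

test_that("community generation is seed-reproducible with planted truth", {
  cfg <- sim_config(n_sites = 2, seed = 21)
  sv1 <- simulate_community(cfg)
  sv2 <- simulate_community(cfg)
  expect_identical(sv1$observations, sv2$observations)
  expect_identical(sv1$truth$niches, sv2$truth$niches)

  # truth structure
  b <- sv1$truth$zone_boundaries
  expect_true(all(diff(b) > 0))
  expect_equal(length(b), cfg$n_zones + 1)
  expect_true(all(table(sv1$truth$species_zone) == cfg$species_per_zone))
  # every observation validates against the schema
  expect_silent(validate_observations(sv1$observations))
})

test_that("zero intensity yields an empty observation table", {
  cfg <- sim_config(n_sites = 1, base_intensity_meanlog = -30, seed = 2)
  sv <- simulate_community(cfg)
  expect_equal(nrow(sv$observations), 0)
})

test_that("expected counts are unimodal in depth at fixed site and effort", {
  # single species, mu = 100, sigma = 10: lambda(100) > lambda(150)
  lam <- function(x, mu = 100, sd = 10) exp(-(x - mu)^2 / (2 * sd^2))
  expect_gt(lam(100), lam(150))
  # generator's realized means follow the niche ordering
  cfg <- sim_config(n_sites = 1, species_per_zone = 1, n_zones = 2,
                    depth_range = c(40, 160), effort_sdlog = 0,
                    base_intensity_meanlog = log(50), site_sdlog = 0,
                    congener_genera = 0, seed = 31)
  sv <- simulate_community(cfg)
  ni <- sv$truth$niches[1, ]
  obs <- sv$observations[sv$observations$species == ni$species, ]
  obs$bin <- bin_depth(obs$depth_m)
  tot <- tapply(obs$count, obs$bin, sum)
  peak_bin <- as.numeric(names(which.max(tot)))
  expect_lt(abs(peak_bin + 5 - ni$depth_center), 25)
})

test_that("poisson noise gives unit variance-to-mean ratio", {
  # the cell-level count model: replicate draws at a fixed lambda
  set.seed(77)
  lambda <- 3.7
  x <- rpois(2e4, lambda)
  expect_lt(abs(var(x) / mean(x) - 1), 0.05)
  # negative binomial option is overdispersed
  y <- rnbinom(2e4, size = 5, mu = lambda)
  expect_gt(var(y) / mean(y), 1.3)
})

test_that("recovery score matches under optimal label matching", {
  truth <- setNames(rep(1:2, each = 5), seq(40, 130, by = 10))
  asg <- data.frame(site = "A", bin_start = seq(40, 130, by = 10),
                    zone = rep(c("x", "y"), each = 5))
  expect_equal(recovery_score(asg, truth), 1) # identical up to labels

  asg_one <- asg; asg_one$zone <- "x"
  expect_equal(recovery_score(asg_one, truth), 0.5) # all-in-one vs 2 zones

  # random assignment over k zones has expectation about 1/k
  set.seed(12)
  k <- 4
  n_bins <- 2000 # optimal-matching bias shrinks as 1/sqrt(n_bins)
  truth_k <- setNames(rep(1:k, each = n_bins / k), seq_len(n_bins) * 10)
  scores <- replicate(40, {
    a <- data.frame(site = "A", bin_start = seq_len(n_bins) * 10,
                    zone = paste0("z", sample(k, n_bins, replace = TRUE)))
    recovery_score(a, truth_k)
  })
  expect_lt(abs(mean(scores) - 1 / k), 0.04)

  expect_error(recovery_score(
    data.frame(site = "A", bin_start = 999, zone = "x"), truth), "absent")
})

test_that("congener sets relabel species without moving their niches", {
  cfg <- sim_config(n_sites = 1, congener_genera = 2, congener_species = 3,
                    seed = 41)
  sv <- simulate_community(cfg)
  pool <- sv$truth$niches
  for (set in sv$truth$congener_sets) {
    members <- pool[pool$species %in% set, ]
    expect_equal(length(unique(members$genus)), 1)
    expect_equal(nrow(members), 3)
    centers <- sort(members$depth_center)
    # offsets near the configured 40 m
    expect_true(all(diff(centers) > 10))
  }
})
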