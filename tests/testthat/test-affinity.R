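mk_assignment <- function(site = "A") {
  data.frame(site = site,
             bin_start = c(40, 50, 60, 70),
             zone = rep(c("upper_mesophotic", "upper_rariphotic"), each = 2),
             stringsAsFactors = FALSE)
}

test_that("zone proportions pool counts through site-specific breaks", {
  obs <- data.frame(site = "A", dive_id = "d", depth_m = c(45, 52, 65),
                    species = "sp one", family = "F", count = c(4, 4, 2))
  props <- zone_proportions(obs, mk_assignment())
  expect_equal(unname(props["sp one", "upper_mesophotic"]), 0.8)
  expect_equal(unname(props["sp one", "upper_rariphotic"]), 0.2)
  expect_equal(sum(props), 1)

  # two sites with different breaks: each site maps through its own zones
  asg2 <- rbind(mk_assignment("A"),
                data.frame(site = "B", bin_start = c(40, 50, 60, 70),
                           zone = rep(c("upper_mesophotic",
                                        "upper_rariphotic"), c(3, 1))))
  obs2 <- data.frame(site = c("A", "B"), dive_id = "d", depth_m = c(65, 65),
                     species = "sp two", family = "F", count = c(1, 1))
  props2 <- zone_proportions(obs2, asg2)
  # 65 m is rariphotic at A but mesophotic at B
  expect_equal(unname(props2["sp two", ]), c(0.5, 0.5),
               ignore_attr = TRUE)

  expect_error(zone_proportions(
    data.frame(site = "A", dive_id = "d", depth_m = 95, species = "s",
               family = "F", count = 1), mk_assignment()), "A:90")
})

test_that("specialist classification uses a strict 75% rule", {
  p <- rbind(spec = c(0.8, 0.2), gen = c(0.5, 0.5), edge = c(0.75, 0.25))
  colnames(p) <- c("upper_mesophotic", "upper_rariphotic")
  got <- suppressMessages(classify_specialist(p))
  expect_equal(unname(got["spec"]), "upper_mesophotic")
  expect_true(is.na(got["gen"]))
  expect_true(is.na(got["edge"])) # exactly at the threshold: not a specialist
  got_inclusive <- classify_specialist(p, strict = FALSE)
  expect_equal(unname(got_inclusive["edge"]), "upper_mesophotic")
})

test_that("affinity categories follow the stated precedence", {
  zones <- c("upper_mesophotic", "lower_mesophotic",
             "upper_rariphotic", "lower_rariphotic")
  p <- rbind(shallowmeso = c(0.6, 0.3, 0.1, 0),
             deepmeso    = c(0.5, 0.4, 0.1, 0),
             rari        = c(0, 0.1, 0.5, 0.4),
             straddle    = c(0, 0.5, 0.5, 0),
             abyssal     = c(0, 0, 0.2, 0.8))
  colnames(p) <- zones
  got <- classify_affinity(
    p,
    shallow_occurrence = c(shallowmeso = TRUE, deepmeso = FALSE),
    deep_sea_species = "abyssal")
  expect_equal(unname(got["shallowmeso"]), "altiphotic_mesophotic")
  expect_equal(unname(got["deepmeso"]), "mesophotic")
  expect_equal(unname(got["rari"]), "rariphotic")
  expect_equal(unname(got["straddle"]), "mesophotic_rariphotic")
  expect_equal(unname(got["abyssal"]), "deep_sea")
  # total: every species is classified
  expect_false(any(is.na(got)))
})

test_that("family categories derive from depth-range midpoints", {
  fr <- data.frame(family = c("Shallowfam", "Midfam", "Abyssfam", "Widefam"),
                   min_depth = c(0, 100, 450, 10),
                   max_depth = c(120, 400, 900, 800))
  fc <- family_categories(fr)
  expect_equal(fc$category,
               c("altiphotic_mesophotic", "rariphotic", "deep_sea",
                 "depth_generalist"))
  # a precomputed table passes through
  pre <- data.frame(family = "X", category = "rariphotic")
  expect_equal(family_categories(pre), pre)
  expect_error(family_categories(data.frame(family = "X", category = "no")),
               "unknown")
})

test_that("zone composition fractions sum to one per zone", {
  obs <- data.frame(site = "A", dive_id = "d",
                    depth_m = c(45, 47, 55, 65, 72),
                    species = c("s1", "s2", "s1", "s3", "s3"),
                    family = c("F1", "F2", "F1", "F2", "F2"),
                    count = c(2, 1, 3, 4, 5))
  cats <- c(s1 = "altiphotic_mesophotic", s2 = "mesophotic",
            s3 = "rariphotic")
  prof <- zone_composition_profile(obs, mk_assignment(), cats)
  for (z in unique(prof$zone)) {
    expect_equal(sum(prof$richness_frac[prof$zone == z]), 1)
    expect_equal(sum(prof$abundance_frac[prof$zone == z]), 1)
  }
  # one category only: every zone is 100% that category
  prof1 <- zone_composition_profile(obs, mk_assignment(),
                                    c(s1 = "x", s2 = "x", s3 = "x"))
  expect_true(all(prof1$richness_frac == 1))
  expect_true(all(prof1$abundance_frac == 1))
})

test_that("specialists plus non-specialists partition the species set", {
  sv <- simulate_community(sim_config(n_sites = 2, seed = 5))
  asg <- data.frame(site = rep(c("site1", "site2"),
                               each = length(sv$truth$bin_zone)),
                    bin_start = rep(as.numeric(names(sv$truth$bin_zone)), 2),
                    zone = paste0("zone_",
                                  rep(sv$truth$bin_zone, 2)))
  props <- zone_proportions(sv$observations, asg)
  expect_equal(unname(rowSums(props)), rep(1, nrow(props)))
  spec <- classify_specialist(props)
  expect_equal(sum(!is.na(spec)) + sum(is.na(spec)), nrow(props))
})
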