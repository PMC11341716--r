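#' Read a pipeline configuration file
#'
#' YAML (or JSON) file whose keys mirror the arguments of
#' [run_site_analysis()] and [run_crosssite_analysis()]; every analysis
#' parameter (pooling threshold, SIMPROF alpha, specialist and SIMPER
#' thresholds, permutation counts, seed) is a named key with the
#' conventional default.
#'
#' @param path path to a YAML configuration file.
#' @return named list of parameters.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read configuration files")
  }
  yaml::read_yaml(path)
}

write_stage <- function(manifest, out_dir, name, writer) {
  if (is.null(out_dir)) return(manifest)
  path <- file.path(out_dir, name)
  writer(path)
  manifest[[name]] <- unname(tools::md5sum(path))
  manifest
}

#' Run the full single-site depth-zonation analysis
#'
#' Orchestrates, in order: depth binning and matrix construction, sparse
#' bin pooling, square-root transform, Bray-Curtis dissimilarity, recursive
#' SIMPROF clustering, zone pooling and break extraction, one-way PERMANOVA
#' of the zones, SIMPER with the indicator-species rule for each adjacent
#' zone pair, the beta-diversity table, effort-normalized abundance and
#' richness profiles, rarefaction, species depth-affinity classification,
#' and congener depth-segregation tests. Identical inputs and seed give
#' identical outputs.
#'
#' @param obs observation data frame.
#' @param effort effort table (`site, depth_bin, hours`).
#' @param site site to analyse.
#' @param window,bin_width,min_total,linkage,alpha,n_expected,n_null,n_zones,zone_names
#'   passed to [depth_zonation()].
#' @param n_perm permutations for PERMANOVA and SIMPER (default 999).
#' @param simper_contrib,simper_p indicator-species thresholds (default 5
#'   percent and 0.05).
#' @param specialist_threshold depth-specialist threshold (default 0.75).
#' @param shallow_occurrence,deep_sea_species optional external knowledge
#'   for [classify_affinity()].
#' @param seed master seed.
#' @param out_dir optional directory: all result tables are written as CSV
#'   and listed (with checksums) in the report manifest.
#' @param force allow non-contiguous zones with a warning.
#' @return list of class `"site_analysis"` with all stage outputs, the
#'   parameter echo, and the file `manifest`.
#' @export
run_site_analysis <- function(obs, effort, site,
                              window = c(40, 300), bin_width = 10,
                              min_total = 5, linkage = "complete",
                              alpha = 1e-7, n_expected = 999, n_null = 9999,
                              n_zones = 4, zone_names = NULL, n_perm = 999,
                              simper_contrib = 5, simper_p = 0.05,
                              specialist_threshold = 0.75,
                              shallow_occurrence = NULL,
                              deep_sea_species = character(0),
                              seed = 1, out_dir = NULL, force = FALSE) {
  t0 <- Sys.time()
  obs <- validate_observations(obs)
  effort <- validate_effort(effort)
  if (!site %in% obs$site) stop("site not present in observations: ", site)
  obs_site <- obs[obs$site == site, , drop = FALSE]
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  manifest <- list()

  zonation <- depth_zonation(obs_site, site = site, window = window,
                             bin_width = bin_width, min_total = min_total,
                             linkage = linkage, alpha = alpha,
                             n_expected = n_expected, n_null = n_null,
                             n_zones = n_zones, zone_names = zone_names,
                             seed = seed, force = force)

  zones_per_sample <- zonation$assignment$zone[
    match(sample_meta(zonation$matrix_raw)$sample,
          zonation$assignment$sample)]
  perm <- permanova(zonation$dist, zones_per_sample, n_perm = n_perm,
                    seed = seed)

  zorder <- zone_order(unique(zonation$assignment$zone))
  meta <- sample_meta(zonation$matrix)
  sample_zone <- setNames(zones_per_sample, meta$sample)
  simper_list <- list()
  indicators <- list()
  if (length(zorder) > 1) {
    for (i in seq_len(length(zorder) - 1)) {
      z1 <- zorder[i]; z2 <- zorder[i + 1]
      keep <- sample_zone %in% c(z1, z2)
      grp <- factor(sample_zone[keep], levels = c(z1, z2))
      st <- simper_analysis(unclass(zonation$matrix)[keep, , drop = FALSE],
                            grp, n_perm = n_perm, seed = seed + i)
      simper_list[[paste(z1, "vs", z2)]] <- st
      ind <- indicator_species(st, contrib_threshold = simper_contrib,
                               p_threshold = simper_p)
      if (nrow(ind) > 0) {
        ind$zone_pair <- paste(z1, "vs", z2)
        indicators[[length(indicators) + 1]] <- ind
      }
    }
  }
  indicators <- if (length(indicators) > 0) do.call(rbind, indicators) else
    data.frame()

  beta <- zone_beta_table(zonation$matrix_raw, zonation$assignment)

  coefs <- sampling_coefficients(effort, site = site)
  m_bins <- build_abundance_matrix(obs_site, site = site, window = window,
                                   bin_width = bin_width)
  surveyed <- sample_meta(m_bins)$bin_start %in%
    coefs$depth_bin[coefs$site == site]
  m_surveyed <- new_abundance_matrix(unclass(m_bins)[surveyed, , drop = FALSE],
                                     attr(m_bins, "site")[surveyed],
                                     attr(m_bins, "bins")[surveyed])
  m_norm <- normalize_abundance(m_surveyed, coefs)
  profiles <- list(relative_abundance = relative_abundance(m_norm, window),
                   richness = richness_profile(m_surveyed),
                   rarefaction = rarefaction_curve(obs_site, site = site))

  props <- zone_proportions(obs_site, zonation$assignment,
                            bin_width = bin_width)
  specialists <- classify_specialist(props,
                                     threshold = specialist_threshold)
  affinity <- classify_affinity(props, shallow_occurrence = shallow_occurrence,
                                deep_sea_species = deep_sea_species)

  elig <- eligible_genera(obs_site)
  segregation <- lapply(unique(elig$genus), function(g) {
    genus_depth_test(obs_site[obs_site$genus == g &
                                obs_site$species %in% elig$species, ,
                              drop = FALSE],
                     coefficients = coefs, bin_width = bin_width)
  })
  names(segregation) <- unique(elig$genus)

  manifest <- write_stage(manifest, out_dir, "abundance_matrix.csv",
                          function(p) write_abundance_matrix(
                            zonation$matrix_raw, p))
  manifest <- write_stage(manifest, out_dir, "zone_assignment.csv",
                          function(p) write.csv(zonation$assignment, p,
                                                row.names = FALSE))
  manifest <- write_stage(manifest, out_dir, "depth_breaks.csv",
                          function(p) write.csv(zonation$breaks, p,
                                                row.names = FALSE))
  manifest <- write_stage(manifest, out_dir, "simprof_tests.csv",
                          function(p) write.csv(zonation$simprof$tests, p,
                                                row.names = FALSE))
  manifest <- write_stage(manifest, out_dir, "permanova.csv",
                          function(p) write.csv(as.data.frame(perm), p,
                                                row.names = FALSE))
  manifest <- write_stage(manifest, out_dir, "indicator_species.csv",
                          function(p) write.csv(indicators, p,
                                                row.names = FALSE))
  manifest <- write_stage(manifest, out_dir, "beta_diversity.csv",
                          function(p) write.csv(as.data.frame(beta), p,
                                                row.names = FALSE))
  manifest <- write_stage(manifest, out_dir, "relative_abundance.csv",
                          function(p) write.csv(
                            profiles$relative_abundance, p,
                            row.names = FALSE))
  manifest <- write_stage(manifest, out_dir, "richness_profile.csv",
                          function(p) write.csv(profiles$richness, p,
                                                row.names = FALSE))
  manifest <- write_stage(manifest, out_dir, "rarefaction.csv",
                          function(p) write.csv(profiles$rarefaction, p,
                                                row.names = FALSE))
  manifest <- write_stage(manifest, out_dir, "species_affinity.csv",
                          function(p) write.csv(
                            data.frame(species = rownames(props), props,
                                       specialist_zone = unname(specialists),
                                       affinity = unname(affinity),
                                       check.names = FALSE),
                            p, row.names = FALSE))
  manifest <- write_stage(manifest, out_dir, "dendrogram.nwk",
                          function(p) dendrogram_newick(zonation, p))

  structure(list(site = site, zonation = zonation, permanova = perm,
                 simper = simper_list, indicators = indicators,
                 beta = beta, profiles = profiles,
                 zone_proportions = props, specialists = specialists,
                 affinity = affinity, segregation = segregation,
                 manifest = manifest,
                 params = list(window = window, bin_width = bin_width,
                               min_total = min_total, linkage = linkage,
                               alpha = alpha, n_expected = n_expected,
                               n_null = n_null, n_zones = n_zones,
                               n_perm = n_perm,
                               simper_contrib = simper_contrib,
                               simper_p = simper_p,
                               specialist_threshold = specialist_threshold,
                               seed = seed),
                 wall_time_s = as.numeric(difftime(Sys.time(), t0,
                                                   units = "secs"))),
            class = "site_analysis")
}

#' @export
print.site_analysis <- function(x, ...) {
  cat("Site analysis:", x$site, "\n")
  print(x$zonation)
  cat("  PERMANOVA R2 (zones):",
      round(100 * x$permanova$r_squared[1], 1), "%, p =",
      format.pval(x$permanova$p_value[1], digits = 3), "\n")
  cat("  ", nrow(x$indicators), " indicator species; ",
      sum(!is.na(x$specialists)), "/", length(x$specialists),
      " depth specialists; ", length(x$segregation),
      " genera tested for segregation\n", sep = "")
  invisible(x)
}

#' Run the cross-site depth-zonation analysis
#'
#' Combines all sites, clusters with Ward linkage and recursive SIMPROF,
#' pools clusters into depth zones, runs the two-way crossed PERMANOVA
#' (depth zone, site, and their interaction, sequential sums of squares in
#' that order) and the between-site beta-diversity table per zone.
#'
#' @inheritParams run_site_analysis
#' @param linkage agglomeration method (default `"ward.D2"`).
#' @param alpha SIMPROF level (default `1e-6`, the cross-site convention).
#' @return list of class `"crosssite_analysis"`.
#' @export
run_crosssite_analysis <- function(obs, effort = NULL,
                                   window = c(40, 300), bin_width = 10,
                                   min_total = 5, linkage = "ward.D2",
                                   alpha = 1e-6, n_expected = 999,
                                   n_null = 9999, n_zones = 4,
                                   zone_names = NULL, n_perm = 999,
                                   seed = 1, out_dir = NULL, force = FALSE) {
  t0 <- Sys.time()
  obs <- validate_observations(obs)
  sites <- unique(obs$site)
  if (length(sites) < 2) {
    stop("cross-site analysis requires at least 2 sites; found ",
         length(sites), " — use run_site_analysis()")
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  zonation <- crosssite_zonation(obs, window = window, bin_width = bin_width,
                                 min_total = min_total, linkage = linkage,
                                 alpha = alpha, n_expected = n_expected,
                                 n_null = n_null, n_zones = n_zones,
                                 zone_names = zone_names, seed = seed,
                                 force = force)
  meta <- sample_meta(zonation$matrix)
  zone_f <- zonation$assignment$zone[match(meta$sample,
                                           zonation$assignment$sample)]
  perm <- permanova(zonation$dist, zone_f, groups2 = meta$site,
                    interaction = TRUE, n_perm = n_perm, seed = seed)
  beta_sites <- crosssite_beta(zonation$matrix_raw, zonation$assignment)

  manifest <- list()
  manifest <- write_stage(manifest, out_dir, "crosssite_assignment.csv",
                          function(p) write.csv(zonation$assignment, p,
                                                row.names = FALSE))
  manifest <- write_stage(manifest, out_dir, "crosssite_permanova.csv",
                          function(p) write.csv(as.data.frame(perm), p,
                                                row.names = FALSE))
  manifest <- write_stage(manifest, out_dir, "crosssite_beta.csv",
                          function(p) write.csv(beta_sites, p,
                                                row.names = FALSE))
  manifest <- write_stage(manifest, out_dir, "crosssite_dendrogram.nwk",
                          function(p) dendrogram_newick(zonation, p))

  structure(list(sites = sites, zonation = zonation, permanova = perm,
                 beta_between_sites = beta_sites, manifest = manifest,
                 params = list(window = window, bin_width = bin_width,
                               min_total = min_total, linkage = linkage,
                               alpha = alpha, n_expected = n_expected,
                               n_null = n_null, n_zones = n_zones,
                               n_perm = n_perm, seed = seed),
                 wall_time_s = as.numeric(difftime(Sys.time(), t0,
                                                   units = "secs"))),
            class = "crosssite_analysis")
}

#' @export
print.crosssite_analysis <- function(x, ...) {
  cat("Cross-site analysis of", length(x$sites), "sites:",
      paste(x$sites, collapse = ", "), "\n")
  print(x$zonation)
  r2 <- round(100 * x$permanova$r_squared[1:3], 1)
  cat("  PERMANOVA R2: zone", r2[1], "%, site", r2[2],
      "%, interaction", r2[3], "%\n")
  invisible(x)
}
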