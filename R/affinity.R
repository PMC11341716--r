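#' Per-species abundance proportions across depth zones
#'
#' Maps every observation to a depth zone through the site-specific zone
#' assignment (sites can have different break depths), pools counts across
#' sites, and returns each species' fraction of total abundance per zone.
#'
#' @param obs observation data frame.
#' @param assignment zone assignment (`site, bin_start, zone`), typically
#'   from [depth_zonation()] fits of each site.
#' @param bin_width depth bin width used in the assignment (default 10).
#' @return matrix species x zones of proportions (rows sum to 1).
#' @export
zone_proportions <- function(obs, assignment, bin_width = 10) {
  obs <- validate_observations(obs)
  obs$bin <- bin_depth(obs$depth_m, bin_width)
  key <- paste(assignment$site, assignment$bin_start)
  idx <- match(paste(obs$site, obs$bin), key)
  if (anyNA(idx)) {
    miss <- unique(paste0(obs$site[is.na(idx)], ":", obs$bin[is.na(idx)]))
    stop("observation bin(s) not covered by the zone assignment: ",
         paste(miss, collapse = ", "))
  }
  obs$zone <- assignment$zone[idx]
  zones <- zone_order(unique(assignment$zone))
  species <- sort(unique(obs$species))
  tab <- matrix(0, length(species), length(zones),
                dimnames = list(species, zones))
  agg <- aggregate(count ~ species + zone, data = obs, FUN = sum)
  tab[cbind(match(agg$species, species), match(agg$zone, zones))] <- agg$count
  tab / rowSums(tab)
}

#' Classify depth specialists
#'
#' A species is a depth specialist of a zone when more than `threshold`
#' (default 0.75) of its observed abundance falls in that single zone. The
#' comparison is strict by default; exact-threshold species are reported
#' via a message so borderline cases are visible.
#'
#' @param proportions matrix from [zone_proportions()] (or a single named
#'   proportion vector).
#' @param threshold specialist threshold (default 0.75).
#' @param strict use strict `>` (default) rather than `>=`.
#' @return named character vector: specialist zone per species, `NA` for
#'   non-specialists.
#' @export
classify_specialist <- function(proportions, threshold = 0.75,
                                strict = TRUE) {
  if (is.vector(proportions)) proportions <- t(as.matrix(proportions))
  best <- max.col(proportions, ties.method = "first")
  best_p <- proportions[cbind(seq_len(nrow(proportions)), best)]
  at_threshold <- abs(best_p - threshold) < 1e-12
  if (strict && any(at_threshold)) {
    message(sum(at_threshold), " species exactly at the ", threshold,
            " threshold classified as non-specialists (strict rule)")
  }
  pass <- if (strict) best_p > threshold else best_p >= threshold
  out <- ifelse(pass, colnames(proportions)[best], NA_character_)
  names(out) <- rownames(proportions)
  out
}

MESO_ZONES <- c("upper_mesophotic", "lower_mesophotic")
RARI_ZONES <- c("upper_rariphotic", "lower_rariphotic")

#' Classify species depth affinity
#'
#' Assigns each species one of five depth-affinity categories by precedence:
#' `deep_sea` for species on the user-supplied deep-sea list;
#' `altiphotic_mesophotic` when at least 75% of abundance is mesophotic and
#' the species is flagged as commonly occurring above 40 m;
#' `mesophotic` when mesophotic abundance reaches 75% without the shallow
#' flag; `rariphotic` when rariphotic abundance reaches 75%; and
#' `mesophotic_rariphotic` otherwise.
#'
#' @param proportions matrix from [zone_proportions()].
#' @param shallow_occurrence named logical: is the species known to occur
#'   commonly above 40 m? Unlisted species default to `FALSE`.
#' @param deep_sea_species character vector of species associated with
#'   deep-sea ecosystems.
#' @param threshold affinity threshold (default 0.75, inclusive `>=`).
#' @return named character vector of affinity categories.
#' @export
classify_affinity <- function(proportions, shallow_occurrence = NULL,
                              deep_sea_species = character(0),
                              threshold = 0.75) {
  zones <- colnames(proportions)
  meso <- rowSums(proportions[, intersect(MESO_ZONES, zones), drop = FALSE])
  rari <- rowSums(proportions[, intersect(RARI_ZONES, zones), drop = FALSE])
  sp <- rownames(proportions)
  flag <- setNames(rep(FALSE, length(sp)), sp)
  if (!is.null(shallow_occurrence)) {
    flag[intersect(names(shallow_occurrence), sp)] <-
      shallow_occurrence[intersect(names(shallow_occurrence), sp)]
  }
  out <- rep("mesophotic_rariphotic", length(sp))
  out[rari >= threshold] <- "rariphotic"
  out[meso >= threshold] <- "mesophotic"
  out[meso >= threshold & flag] <- "altiphotic_mesophotic"
  out[sp %in% deep_sea_species] <- "deep_sea"
  names(out) <- sp
  out
}

#' Family depth categories from depth ranges
#'
#' Classifies fish families by the depth range of their members: midpoint
#' shallower than `meso_cutoff` (130 m) gives `altiphotic_mesophotic`,
#' between the cutoffs gives `rariphotic`, deeper than `deep_cutoff`
#' (500 m) gives `deep_sea`; families whose range crosses both cutoffs are
#' `depth_generalist`.
#'
#' @param family_ranges data frame `family, min_depth, max_depth`, or a
#'   precomputed `family, category` table which is validated and returned.
#' @param meso_cutoff,deep_cutoff depth cutoffs in metres.
#' @return data frame `family, category`.
#' @export
family_categories <- function(family_ranges, meso_cutoff = 130,
                              deep_cutoff = 500) {
  if ("category" %in% names(family_ranges)) {
    ok <- c("altiphotic_mesophotic", "rariphotic", "deep_sea",
            "depth_generalist")
    bad <- setdiff(unique(family_ranges$category), ok)
    if (length(bad) > 0) stop("unknown categories: ",
                              paste(bad, collapse = ", "))
    return(family_ranges[, c("family", "category")])
  }
  need <- c("family", "min_depth", "max_depth")
  if (!all(need %in% names(family_ranges))) {
    stop("family_ranges needs columns family, min_depth, max_depth ",
         "(or family, category)")
  }
  mid <- (family_ranges$min_depth + family_ranges$max_depth) / 2
  cat <- ifelse(mid < meso_cutoff, "altiphotic_mesophotic",
                ifelse(mid <= deep_cutoff, "rariphotic", "deep_sea"))
  spans_both <- family_ranges$min_depth < meso_cutoff &
    family_ranges$max_depth > deep_cutoff
  cat[spans_both] <- "depth_generalist"
  data.frame(family = family_ranges$family, category = cat,
             stringsAsFactors = FALSE)
}

#' Depth-zone composition by affinity or family category
#'
#' For each depth zone, the fraction of species richness and of total
#' abundance contributed by each category (species depth affinity or
#' family depth category).
#'
#' @param obs observation data frame.
#' @param assignment zone assignment (`site, bin_start, zone`).
#' @param categories named character vector: category per species, e.g.
#'   from [classify_affinity()]; or per family if `by = "family"`.
#' @param by `"species"` (default) or `"family"`.
#' @param bin_width depth bin width (default 10).
#' @return data frame `zone, category, richness_frac, abundance_frac`;
#'   fractions sum to 1 within each zone.
#' @export
zone_composition_profile <- function(obs, assignment, categories,
                                     by = c("species", "family"),
                                     bin_width = 10) {
  by <- match.arg(by)
  obs <- validate_observations(obs)
  obs$bin <- bin_depth(obs$depth_m, bin_width)
  key <- paste(assignment$site, assignment$bin_start)
  idx <- match(paste(obs$site, obs$bin), key)
  if (anyNA(idx)) {
    stop("observation bin(s) not covered by the zone assignment")
  }
  obs$zone <- assignment$zone[idx]
  unit <- if (by == "species") obs$species else obs$family
  obs$category <- unname(categories[unit])
  if (anyNA(obs$category)) {
    stop("no category for: ",
         paste(unique(unit[is.na(obs$category)]), collapse = ", "))
  }
  rows <- list()
  for (z in zone_order(unique(obs$zone))) {
    sub <- obs[obs$zone == z, ]
    rich <- tapply(sub$species, sub$category,
                   function(s) length(unique(s)))
    abun <- tapply(sub$count, sub$category, sum)
    cats <- names(rich)
    rows[[length(rows) + 1]] <- data.frame(
      zone = z, category = cats,
      richness_frac = as.numeric(rich / sum(rich)),
      abundance_frac = as.numeric(abun[cats] / sum(abun)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
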