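ZONE_NAMES_6 <- c("altiphotic", "upper_mesophotic", "lower_mesophotic",
                  "upper_rariphotic", "lower_rariphotic", "below_rariphotic")
ZONE_NAMES_4 <- ZONE_NAMES_6[2:5]

# canonical shallow-to-deep ordering of zone labels
zone_order <- function(zones) {
  known <- ZONE_NAMES_6[ZONE_NAMES_6 %in% zones]
  c(known, sort(setdiff(zones, known)))
}

default_zone_names <- function(n) {
  if (n == 4) ZONE_NAMES_4
  else if (n == 6) ZONE_NAMES_6
  else if (n == 5) ZONE_NAMES_6[2:6]
  else paste0("zone_", seq_len(n))
}

#' Pool significant clusters into named depth zones
#'
#' Cuts the dendrogram at its `n_zones - 1` highest merge heights (the main
#' branching events), grouping SIMPROF clusters into `n_zones` depth zones.
#' When `n_zones` exceeds the number of significant clusters a cluster is
#' split at its own main internal branch, which the cut realizes naturally.
#' Zones must occupy contiguous depth spans within each site; otherwise an
#' error lists the offending bins unless `force = TRUE` downgrades it to a
#' warning.
#'
#' @param sc a `"simprof_clusters"` object.
#' @param meta sample metadata from [sample_meta()] of the clustered
#'   matrix.
#' @param n_zones number of depth zones to form.
#' @param zone_names names shallow to deep; defaults to the standard reef
#'   nomenclature for 4-6 zones.
#' @param force allow non-contiguous zones with a warning.
#' @return data frame of class `"zone_assignment"`: `site, bin_start, bins,
#'   sample, cluster, zone`.
#' @export
pool_clusters_to_zones <- function(sc, meta, n_zones,
                                   zone_names = NULL, force = FALSE) {
  if (is.null(zone_names)) zone_names <- default_zone_names(n_zones)
  if (length(zone_names) != n_zones) {
    stop("need exactly n_zones zone names")
  }
  groups <- cutree(sc$tree, k = n_zones)
  # order groups shallow to deep by mean constituent depth
  depth_of <- tapply(meta$bin_start, groups[meta$sample], mean)
  ord <- rank(depth_of, ties.method = "first")
  zone <- zone_names[ord[as.character(groups[meta$sample])]]
  out <- data.frame(site = meta$site,
                    bin_start = meta$bin_start,
                    sample = meta$sample,
                    cluster = unname(sc$clusters[meta$sample]),
                    zone = zone,
                    stringsAsFactors = FALSE)
  # contiguity: within each site, sorting by depth must not interleave zones
  offenders <- character(0)
  for (s in unique(out$site)) {
    sub <- out[out$site == s, ]
    sub <- sub[order(sub$bin_start), ]
    runs <- rle(sub$zone)$values
    if (anyDuplicated(runs)) {
      dup <- runs[duplicated(runs)]
      offenders <- c(offenders, paste0(
        s, ": ", paste(sub$sample[sub$zone %in% dup], collapse = ", ")))
    }
  }
  if (length(offenders) > 0) {
    msg <- paste("non-contiguous depth zone(s) at",
                 paste(offenders, collapse = "; "))
    if (force) warning(msg) else stop(msg)
  }
  class(out) <- c("zone_assignment", class(out))
  out
}

#' Depth breaks between consecutive zones
#'
#' The break between two zones is reported as the minimum depth of the
#' shallowest bin of the deeper zone (i.e., the deeper bin's label).
#'
#' @param assignment a zone assignment data frame
#'   (`site, bin_start, zone`).
#' @return data frame `site, shallower_zone, deeper_zone, break_depth`.
#' @export
depth_breaks <- function(assignment) {
  rows <- list()
  for (s in unique(assignment$site)) {
    sub <- assignment[assignment$site == s, ]
    sub <- sub[order(sub$bin_start), ]
    change <- which(sub$zone[-1] != sub$zone[-nrow(sub)])
    for (i in change) {
      rows[[length(rows) + 1]] <- data.frame(
        site = s, shallower_zone = sub$zone[i], deeper_zone = sub$zone[i + 1],
        break_depth = sub$bin_start[i + 1], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(site = character(0), shallower_zone = character(0),
                      deeper_zone = character(0), break_depth = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Delimit depth zones of a reef-fish community
#'
#' The package's central fit: from long-format observation records it
#' builds the per-bin abundance matrix inside a depth window, pools sparse
#' bins, square-root transforms, computes Bray-Curtis dissimilarities,
#' clusters the bins agglomeratively, delimits significant clusters by
#' recursive SIMPROF, pools the clusters into named depth zones at the main
#' branching events, and extracts the community break depths.
#'
#' @param obs observation data frame (see [validate_observations()]).
#' @param site site label to analyse (must be a single site; see
#'   [crosssite_zonation()] for the multi-site analysis).
#' @param window half-open depth window in metres (default `c(40, 300)`).
#' @param bin_width depth bin width in metres (default 10).
#' @param min_total pooling threshold: minimum individuals per sample
#'   (default 5).
#' @param linkage agglomeration method (default `"complete"`).
#' @param alpha SIMPROF significance level (default `1e-7`; effectively
#'   `max(alpha, 1/(n_null + 1))`).
#' @param n_expected,n_null SIMPROF permutation counts.
#' @param n_zones number of depth zones to pool clusters into (default 4:
#'   upper/lower mesophotic and upper/lower rariphotic). `NULL` uses the
#'   number of significant clusters.
#' @param zone_names optional zone names, shallow to deep.
#' @param seed master RNG seed.
#' @param force allow non-contiguous zone assignments with a warning.
#' @return an object of class `"depth_zonation"`: list with the pooled raw
#'   and transformed matrices, the distance matrix, `hclust` tree, SIMPROF
#'   tests and clusters, zone `assignment`, and `breaks`.
#' @export
depth_zonation <- function(obs, site = NULL, window = c(40, 300),
                           bin_width = 10, min_total = 5,
                           linkage = "complete", alpha = 1e-7,
                           n_expected = 999, n_null = 9999,
                           n_zones = 4, zone_names = NULL, seed = 1,
                           force = FALSE) {
  obs <- validate_observations(obs)
  if (is.null(site)) {
    site <- unique(obs$site)
    if (length(site) > 1) {
      stop("multiple sites present; pass a single `site` or use ",
           "crosssite_zonation()")
    }
  }
  m_raw <- build_abundance_matrix(obs, site = site, window = window,
                                  bin_width = bin_width)
  m_pool <- pool_sparse_bins(m_raw, min_total = min_total)
  m_tr <- sqrt_transform(m_pool)
  sc <- simprof_clusters(m_tr, linkage = linkage, alpha = alpha,
                         n_expected = n_expected, n_null = n_null,
                         seed = seed)
  meta <- sample_meta(m_pool)
  if (is.null(n_zones)) n_zones <- length(sc$members)
  n_zones <- min(n_zones, nrow(m_pool))
  assignment <- pool_clusters_to_zones(sc, meta, n_zones,
                                       zone_names = zone_names, force = force)
  # expand pooled samples back to their constituent bins
  bins <- attr(m_pool, "bins")
  expand <- do.call(rbind, lapply(seq_len(nrow(meta)), function(i) {
    data.frame(site = meta$site[i], bin_start = bins[[i]],
               sample = meta$sample[i], stringsAsFactors = FALSE)
  }))
  expanded <- merge(expand,
                    assignment[, c("sample", "cluster", "zone")],
                    by = "sample", sort = FALSE)
  expanded <- expanded[order(expanded$site, expanded$bin_start),
                       c("site", "bin_start", "sample", "cluster", "zone")]
  rownames(expanded) <- NULL
  structure(list(matrix_raw = m_pool, matrix = m_tr,
                 dist = distance_matrix(m_tr, "bray_curtis"),
                 tree = sc$tree, simprof = sc,
                 clusters = sc$members,
                 assignment = expanded,
                 breaks = depth_breaks(expanded),
                 window = window, site = site, n_zones = n_zones,
                 params = list(bin_width = bin_width, min_total = min_total,
                               linkage = linkage, alpha = alpha,
                               n_expected = n_expected, n_null = n_null,
                               seed = seed),
                 call = match.call()),
            class = "depth_zonation")
}

#' Cross-site depth zonation
#'
#' Combines all sites into one matrix (samples are site x depth bin,
#' species columns are the cross-site union) and runs the same recursive
#' SIMPROF clustering with Ward linkage, the convention for the regional
#' analysis.
#'
#' @inheritParams depth_zonation
#' @param linkage agglomeration method (default `"ward.D2"`).
#' @param alpha SIMPROF level for the cross-site test (default `1e-6`).
#' @return a `"depth_zonation"` object spanning all sites.
#' @export
crosssite_zonation <- function(obs, window = c(40, 300), bin_width = 10,
                               min_total = 5, linkage = "ward.D2",
                               alpha = 1e-6, n_expected = 999, n_null = 9999,
                               n_zones = 4, zone_names = NULL, seed = 1,
                               force = FALSE) {
  obs <- validate_observations(obs)
  sites <- unique(obs$site)
  if (length(sites) < 2) {
    stop("cross-site analysis needs at least 2 sites; found ",
         length(sites))
  }
  m_raw <- build_abundance_matrix(obs, site = NULL, window = window,
                                  bin_width = bin_width)
  m_pool <- pool_sparse_bins(m_raw, min_total = min_total)
  m_tr <- sqrt_transform(m_pool)
  sc <- simprof_clusters(m_tr, linkage = linkage, alpha = alpha,
                         n_expected = n_expected, n_null = n_null,
                         seed = seed)
  meta <- sample_meta(m_pool)
  if (is.null(n_zones)) n_zones <- length(sc$members)
  assignment <- pool_clusters_to_zones(sc, meta, n_zones,
                                       zone_names = zone_names, force = force)
  bins <- attr(m_pool, "bins")
  expand <- do.call(rbind, lapply(seq_len(nrow(meta)), function(i) {
    data.frame(site = meta$site[i], bin_start = bins[[i]],
               sample = meta$sample[i], stringsAsFactors = FALSE)
  }))
  expanded <- merge(expand, assignment[, c("sample", "cluster", "zone")],
                    by = "sample", sort = FALSE)
  expanded <- expanded[order(expanded$site, expanded$bin_start),
                       c("site", "bin_start", "sample", "cluster", "zone")]
  rownames(expanded) <- NULL
  structure(list(matrix_raw = m_pool, matrix = m_tr,
                 dist = distance_matrix(m_tr, "bray_curtis"),
                 tree = sc$tree, simprof = sc,
                 clusters = sc$members,
                 assignment = expanded,
                 breaks = depth_breaks(expanded),
                 window = window, site = sites, n_zones = n_zones,
                 params = list(bin_width = bin_width, min_total = min_total,
                               linkage = linkage, alpha = alpha,
                               n_expected = n_expected, n_null = n_null,
                               seed = seed),
                 call = match.call()),
            class = "depth_zonation")
}

#' @export
print.depth_zonation <- function(x, ...) {
  cat("Depth zonation of", paste(x$site, collapse = ", "),
      sprintf("(%d-%d m, %s linkage)\n", x$window[1], x$window[2],
              x$params$linkage))
  cat("  ", length(x$clusters), " significant SIMPROF cluster(s) pooled into ",
      x$n_zones, " depth zone(s)\n", sep = "")
  if (nrow(x$breaks) > 0) {
    cat("  community breaks:\n")
    for (i in seq_len(nrow(x$breaks))) {
      cat(sprintf("    %s: %s | %s at %g m\n", x$breaks$site[i],
                  x$breaks$shallower_zone[i], x$breaks$deeper_zone[i],
                  x$breaks$break_depth[i]))
    }
  } else {
    cat("  single zone, no community breaks\n")
  }
  invisible(x)
}

#' @export
summary.depth_zonation <- function(object, ...) {
  zones <- split(object$assignment$bin_start, object$assignment$zone)
  zone_tab <- do.call(rbind, lapply(zone_order(names(zones)), function(z) {
    data.frame(zone = z, shallowest_bin = min(zones[[z]]),
               deepest_bin = max(zones[[z]]), n_bins = length(zones[[z]]),
               stringsAsFactors = FALSE)
  }))
  out <- list(site = object$site, zones = zone_tab, breaks = object$breaks,
              simprof_tests = object$simprof$tests,
              n_clusters = length(object$clusters),
              params = object$params)
  class(out) <- "summary.depth_zonation"
  out
}

#' @export
print.summary.depth_zonation <- function(x, ...) {
  cat("Depth zonation summary —", paste(x$site, collapse = ", "), "\n\n")
  cat("Zones (shallow to deep):\n")
  print(x$zones, row.names = FALSE)
  cat("\nBreaks:\n")
  print(x$breaks, row.names = FALSE)
  cat("\nSIMPROF tests (", x$n_clusters, " significant clusters):\n",
      sep = "")
  print(x$simprof_tests, row.names = FALSE)
  invisible(x)
}

#' @export
plot.depth_zonation <- function(x, ...) {
  plot(x$tree, hang = -1,
       main = paste("Depth zonation:", paste(x$site, collapse = ", ")),
       xlab = "depth bin (m)", sub = "", ...)
  k <- length(x$clusters)
  if (k > 1 && k < length(x$simprof$clusters)) {
    stats::rect.hclust(x$tree, k = k, border = "grey40")
  }
  invisible(x)
}

#' @export
as.hclust.depth_zonation <- function(x, ...) x$tree

#' Export a dendrogram in Newick format
#'
#' @param tree an `hclust` object (or `depth_zonation`, whose tree is
#'   used); merge heights become node heights, so branch lengths reflect
#'   dissimilarity.
#' @param path optional file to write to.
#' @return the Newick string, invisibly if written to a file.
#' @export
dendrogram_newick <- function(tree, path = NULL) {
  if (inherits(tree, "depth_zonation")) tree <- tree$tree
  build <- function(node, parent_height) {
    if (node < 0) {
      lab <- gsub("[ ,():;]", "_", tree$labels[-node])
      return(paste0(lab, ":", format(parent_height, digits = 10)))
    }
    h <- tree$height[node]
    left <- build(tree$merge[node, 1], h)
    right <- build(tree$merge[node, 2], h)
    paste0("(", left, ",", right, "):",
           format(max(parent_height - h, 0), digits = 10))
  }
  root <- nrow(tree$merge)
  h <- tree$height[root]
  left <- build(tree$merge[root, 1], h)
  right <- build(tree$merge[root, 2], h)
  nwk <- paste0("(", left, ",", right, ");")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
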