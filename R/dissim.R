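#' Square-root transform of an abundance matrix
#'
#' Applied before clustering to damp the influence of very abundant
#' (schooling) species while keeping rare species from dominating. The
#' transform is recorded in the matrix history; applying it twice is almost
#' always a mistake and triggers a warning.
#'
#' @param m `abundance_matrix` with nonnegative cells.
#' @return transformed `abundance_matrix`.
#' @export
sqrt_transform <- function(m) {
  if (any(unclass(m) < 0)) stop("negative cells cannot be sqrt-transformed")
  if ("sqrt" %in% attr(m, "transform")) {
    warning("matrix already sqrt-transformed; applying again yields a ",
            "fourth-root transform")
  }
  out <- sqrt(unclass(m))
  new_abundance_matrix(out, attr(m, "site"), attr(m, "bins"),
                       transform = c(attr(m, "transform"), "sqrt"))
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `1 - 2 * sum(pmin(u, v)) / sum(u + v)`; 0 for identical vectors, 1 for
#' disjoint species support.
#'
#' @param u,v nonnegative numeric vectors of equal length, not both all
#'   zero.
#' @return dissimilarity in `[0, 1]`.
#' @export
#' @examples
#' bray_curtis(c(1, 0, 3), c(1, 2, 0)) # 5/7
bray_curtis <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  if (any(u < 0) || any(v < 0)) stop("abundances must be nonnegative")
  tot <- sum(u) + sum(v)
  if (tot == 0) stop("Bray-Curtis undefined for two all-zero vectors")
  1 - 2 * sum(pmin(u, v)) / tot
}

#' Pairwise distance matrix between samples
#'
#' @param m `abundance_matrix` with at least two rows.
#' @param metric `"bray_curtis"` (default) or `"euclidean"`.
#' @return a `dist` object with sample labels and a `metric` attribute.
#' @export
distance_matrix <- function(m, metric = c("bray_curtis", "euclidean")) {
  metric <- match.arg(metric)
  if (nrow(m) < 2) stop("need at least 2 samples")
  if (metric == "bray_curtis") {
    zero_rows <- rowSums(unclass(m)) == 0
    if (any(zero_rows)) {
      stop("all-zero sample(s) for Bray-Curtis: ",
           paste(rownames(m)[zero_rows], collapse = ", "))
    }
    d <- vegan::vegdist(unclass(m), method = "bray")
  } else {
    d <- dist(unclass(m), method = "euclidean")
  }
  attr(d, "Labels") <- rownames(m)
  attr(d, "metric") <- metric
  d
}

#' Partition pairwise beta diversity into turnover and nestedness
#'
#' From the presence sets of two assemblages with `a` shared species, `b`
#' unique to the first and `c` unique to the second:
#' total dissimilarity `beta_sor = (b + c) / (2a + b + c)` (Sorensen),
#' turnover `beta_sim = min(b, c) / (a + min(b, c))` (Simpson), and
#' nestedness `beta_nes = beta_sor - beta_sim`.
#'
#' @param group1,group2 character vectors of species present in each
#'   assemblage (presence derived from raw counts upstream).
#' @return data frame with `a, b, c, beta_sor, beta_sim, beta_nes`.
#' @export
beta_partition <- function(group1, group2) {
  group1 <- unique(as.character(group1))
  group2 <- unique(as.character(group2))
  if (length(group1) == 0 && length(group2) == 0) {
    stop("both assemblages are empty")
  }
  a <- length(intersect(group1, group2))
  b <- length(setdiff(group1, group2))
  c_ <- length(setdiff(group2, group1))
  beta_sor <- if (2 * a + b + c_ == 0) 0 else (b + c_) / (2 * a + b + c_)
  beta_sim <- if (a + min(b, c_) == 0) 0 else min(b, c_) / (a + min(b, c_))
  data.frame(a = a, b = b, c = c_,
             beta_sor = beta_sor, beta_sim = beta_sim,
             beta_nes = beta_sor - beta_sim)
}

#' Beta-diversity table across depth zones
#'
#' Pools species presence per (site, zone) from raw counts and partitions
#' beta diversity for every zone pair within each site, with cross-site
#' mean and standard error per pair attached as the `"summary"` attribute.
#' Zone pairs absent from a site are skipped; a pair present at a single
#' site gets no standard error.
#'
#' @param m raw-count `abundance_matrix` (one or several sites).
#' @param assignment depth-zone assignment data frame
#'   (`site, bin_start, zone`), e.g. from [depth_zonation()].
#' @return data frame `site, zone1, zone2, adjacent, a, b, c, beta_sor,
#'   beta_sim, beta_nes`; `attr(, "summary")` holds per-pair mean and SE.
#' @export
zone_beta_table <- function(m, assignment) {
  if (length(attr(m, "transform")) > 0) {
    warning("beta partitioning uses presence from raw counts; matrix has a ",
            "transform history")
  }
  meta <- sample_meta(m)
  zones_ord <- zone_order(unique(assignment$zone))
  rows <- list()
  for (s in unique(meta$site)) {
    asg <- assignment[assignment$site == s, , drop = FALSE]
    pres <- list()
    for (z in zones_ord) {
      bins_z <- asg$bin_start[asg$zone == z]
      if (length(bins_z) == 0) next
      # pooled rows count towards a zone when any constituent bin falls in it
      all_bins <- attr(m, "bins")
      ridx <- which(meta$site == s &
                      vapply(all_bins, function(b) any(b %in% bins_z),
                             logical(1)))
      sub <- unclass(m)[ridx, , drop = FALSE]
      sp <- colnames(m)[colSums(sub) > 0]
      pres[[z]] <- sp
    }
    zs <- names(pres)
    if (length(zs) < 2) next
    for (i in seq_len(length(zs) - 1)) {
      for (j in seq(i + 1, length(zs))) {
        bp <- beta_partition(pres[[zs[i]]], pres[[zs[j]]])
        rows[[length(rows) + 1]] <- cbind(
          data.frame(site = s, zone1 = zs[i], zone2 = zs[j],
                     adjacent = (j == i + 1), stringsAsFactors = FALSE),
          bp)
      }
    }
  }
  if (length(rows) == 0) stop("no site has two or more assigned zones")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  pair <- paste(out$zone1, out$zone2, sep = " vs ")
  se <- function(x) if (length(x) < 2) NA_real_ else sd(x) / sqrt(length(x))
  summ <- do.call(rbind, lapply(split(out, pair), function(d) {
    data.frame(zone1 = d$zone1[1], zone2 = d$zone2[1],
               adjacent = d$adjacent[1], n_sites = nrow(d),
               beta_sor_mean = mean(d$beta_sor), beta_sor_se = se(d$beta_sor),
               beta_sim_mean = mean(d$beta_sim), beta_sim_se = se(d$beta_sim),
               beta_nes_mean = mean(d$beta_nes), beta_nes_se = se(d$beta_nes),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  attr(out, "summary") <- summ
  out
}

#' Cross-site beta diversity within each depth zone
#'
#' Presence/absence dissimilarity between sites at each depth zone,
#' quantifying how community composition at a fixed zone varies regionally.
#'
#' @param m raw-count cross-site `abundance_matrix`.
#' @param assignment depth-zone assignment (`site, bin_start, zone`).
#' @param index which index to report; Sorensen `beta_sor` by default
#'   (the turnover and nestedness components are always included).
#' @return data frame `zone, site1, site2, a, b, c, beta_sor, beta_sim,
#'   beta_nes`.
#' @export
crosssite_beta <- function(m, assignment, index = "beta_sor") {
  meta <- sample_meta(m)
  all_bins <- attr(m, "bins")
  rows <- list()
  for (z in zone_order(unique(assignment$zone))) {
    pres <- list()
    for (s in unique(meta$site)) {
      bins_z <- assignment$bin_start[assignment$site == s &
                                       assignment$zone == z]
      if (length(bins_z) == 0) next
      ridx <- which(meta$site == s &
                      vapply(all_bins, function(b) any(b %in% bins_z),
                             logical(1)))
      sub <- unclass(m)[ridx, , drop = FALSE]
      pres[[s]] <- colnames(m)[colSums(sub) > 0]
    }
    ss <- names(pres)
    if (length(ss) < 2) next
    for (i in seq_len(length(ss) - 1)) {
      for (j in seq(i + 1, length(ss))) {
        bp <- beta_partition(pres[[ss[i]]], pres[[ss[j]]])
        rows[[length(rows) + 1]] <- cbind(
          data.frame(zone = z, site1 = ss[i], site2 = ss[j],
                     stringsAsFactors = FALSE), bp)
      }
    }
  }
  if (length(rows) == 0) stop("no zone is shared by two or more sites")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
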