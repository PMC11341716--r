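#' Sampling coefficients from dive effort
#'
#' For each site, the coefficient of a depth bin is the site's maximal
#' per-bin effort divided by the bin's effort, so the best-surveyed bin has
#' coefficient 1 and sparsely surveyed bins are scaled up.
#'
#' @param effort effort data frame (`site, depth_bin, hours`).
#' @param site optional site restriction.
#' @return data frame `site, depth_bin, hours, coefficient`.
#' @export
#' @examples
#' eff <- data.frame(site = "A", depth_bin = c(40, 50, 60), hours = c(2, 4, 1))
#' sampling_coefficients(eff)$coefficient # 2 1 4
sampling_coefficients <- function(effort, site = NULL) {
  effort <- validate_effort(effort)
  if (!is.null(site)) effort <- effort[effort$site %in% site, , drop = FALSE]
  if (nrow(effort) == 0) stop("no effort rows for the requested site")
  split_eff <- split(effort, effort$site)
  out <- do.call(rbind, lapply(split_eff, function(e) {
    e$coefficient <- max(e$hours) / e$hours
    e
  }))
  rownames(out) <- NULL
  out
}

#' Normalize abundances by sampling effort
#'
#' Multiplies each sample (row) of the matrix by its sampling coefficient,
#' correcting raw counts for unequal dive time across depth bins.
#' Normalization operates on unpooled single-bin samples; normalize before
#' pooling if both are needed.
#'
#' @param m raw-count `abundance_matrix` with single-bin rows.
#' @param coefficients output of [sampling_coefficients()].
#' @return effort-normalized `abundance_matrix` (cells become reals).
#' @export
normalize_abundance <- function(m, coefficients) {
  meta <- sample_meta(m)
  if (any(meta$n_bins > 1)) {
    stop("normalize_abundance requires unpooled (single-bin) samples; ",
         "apply it before pool_sparse_bins")
  }
  key <- paste(coefficients$site, coefficients$depth_bin)
  idx <- match(paste(meta$site, meta$bin_start), key)
  if (anyNA(idx)) {
    miss <- meta[is.na(idx), ]
    stop("no sampling coefficient for sample(s): ",
         paste(paste0(miss$site, ":", miss$bin_start), collapse = ", "))
  }
  co <- coefficients$coefficient[idx]
  out <- unclass(m) * co
  new_abundance_matrix(out, attr(m, "site"), attr(m, "bins"),
                       transform = c(attr(m, "transform"),
                                     "effort_normalized"))
}

#' Relative abundance depth profile
#'
#' Expresses normalized per-bin total abundance as a percentage of the
#' maximal per-bin abundance inside a reference depth window, so the
#' best-populated bin in the window reads 100.
#'
#' @param m effort-normalized `abundance_matrix` for a single site.
#' @param window depth window over which the maximum is taken (default
#'   `c(40, 300)`, half-open).
#' @return data frame `depth_bin, value` with `value` in `[0, 100]` inside
#'   the window (values outside the window may exceed 100).
#' @export
relative_abundance <- function(m, window = c(40, 300)) {
  meta <- sample_meta(m)
  if (length(unique(meta$site)) > 1) {
    stop("relative_abundance operates on one site at a time")
  }
  totals <- rowSums(m)
  in_win <- meta$bin_start >= window[1] & meta$bin_start < window[2]
  if (!any(in_win)) stop("no samples inside the reference window")
  ref <- max(totals[in_win])
  if (ref <= 0) stop("all-zero abundance inside the reference window")
  data.frame(depth_bin = meta$bin_start,
             value = 100 * totals / ref)
}

#' Species richness depth profile
#'
#' Per-sample count of species with nonzero abundance, computed on raw
#' (untransformed) counts.
#'
#' @param m raw-count `abundance_matrix`.
#' @return data frame `site, depth_bin, value`.
#' @export
richness_profile <- function(m) {
  if (length(attr(m, "transform")) > 0) {
    warning("richness is normally computed on raw counts; matrix has ",
            "transform history ", paste(attr(m, "transform"), collapse = ","))
  }
  meta <- sample_meta(m)
  data.frame(site = meta$site, depth_bin = meta$bin_start,
             value = as.integer(rowSums(unclass(m) > 0)))
}

#' Sample-based rarefaction curve over dives
#'
#' Expected species richness for n = 1..N dives, computed exactly from
#' hypergeometric inclusion probabilities of per-dive species incidences
#' (no resampling): `S(n) = sum_i 1 - choose(N - N_i, n) / choose(N, n)`.
#' A seeded resampling mode is available for parity with common practice.
#'
#' @param obs observation data frame.
#' @param site optional site restriction.
#' @param method `"exact"` (default) or `"random"`.
#' @param n_resample permutations for `method = "random"`.
#' @param seed RNG seed for `method = "random"`.
#' @return data frame `n_dives, richness`.
#' @export
rarefaction_curve <- function(obs, site = NULL, method = c("exact", "random"),
                              n_resample = 200, seed = 1) {
  method <- match.arg(method)
  obs <- validate_observations(obs)
  if (!is.null(site)) obs <- obs[obs$site %in% site, , drop = FALSE]
  if (nrow(obs) == 0) stop("no observations for the requested site")
  inc <- table(obs$dive_id, obs$species) > 0
  comm <- matrix(as.numeric(inc), nrow = nrow(inc), dimnames = dimnames(inc))
  if (method == "exact") {
    sac <- vegan::specaccum(comm, method = "exact")
  } else {
    set.seed(seed)
    sac <- vegan::specaccum(comm, method = "random",
                            permutations = n_resample)
  }
  data.frame(n_dives = sac$sites, richness = as.numeric(sac$richness))
}
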