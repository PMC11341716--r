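#' Genera eligible for congener depth-segregation testing
#'
#' A genus is testable when at least `min_species` of its species each have
#' at least `min_individuals` observed individuals pooled across sites
#' (both bounds inclusive). Species below the individual threshold are
#' dropped from the genus rather than disqualifying it.
#'
#' @param obs observation data frame.
#' @param min_species minimum number of qualifying species (default 2).
#' @param min_individuals minimum individuals per species (default 10).
#' @return data frame `genus, species, n_individuals` restricted to
#'   qualifying species of eligible genera.
#' @export
eligible_genera <- function(obs, min_species = 2, min_individuals = 10) {
  obs <- validate_observations(obs)
  tot <- aggregate(count ~ genus + species, data = obs, FUN = sum)
  names(tot)[3] <- "n_individuals"
  tot <- tot[tot$n_individuals >= min_individuals, , drop = FALSE]
  n_sp <- table(tot$genus)
  keep <- names(n_sp)[n_sp >= min_species]
  out <- tot[tot$genus %in% keep, , drop = FALSE]
  out <- out[order(out$genus, out$species), ]
  rownames(out) <- NULL
  out
}

# expand records to one depth value per individual
expand_depths <- function(obs) {
  data.frame(species = rep(obs$species, obs$count),
             depth = rep(obs$depth_m, obs$count),
             stringsAsFactors = FALSE)
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Insert-and-absorb algorithm: groups sharing a letter are not
#' significantly different at `alpha`.
#'
#' @param pmat symmetric matrix of pairwise p-values (diagonal ignored).
#' @param alpha significance level (default 0.05).
#' @return named character vector of letter codes.
#' @export
compact_letters <- function(pmat, alpha = 0.05) {
  k <- nrow(pmat)
  labels <- rownames(pmat)
  sig <- !is.na(pmat) & pmat < alpha
  diag(sig) <- FALSE
  # each letter group is a set of indices with no significant pair inside
  groups <- list(1L)
  for (i in seq_len(k)[-1]) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      if (!any(sig[i, groups[[g]]])) {
        groups[[g]] <- c(groups[[g]], i)
        placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1]] <- i
  }
  # absorb redundant groups
  redundant <- rep(FALSE, length(groups))
  for (g in seq_along(groups)) {
    for (h in seq_along(groups)) {
      if (g != h && !redundant[h] &&
          all(groups[[g]] %in% groups[[h]])) {
        redundant[g] <- TRUE
        break
      }
    }
  }
  groups <- groups[!redundant]
  out <- vapply(seq_len(k), function(i) {
    paste0(letters[which(vapply(groups, function(g) i %in% g, logical(1)))],
           collapse = "")
  }, character(1))
  names(out) <- labels
  out
}

#' Depth-segregation tests among congeneric species
#'
#' Expands counts to per-individual depth observations and tests whether
#' species of one genus occupy different depths: Shapiro-Wilk normality per
#' species (the gate motivating rank-based tests), a Kruskal-Wallis omnibus
#' test of depth ~ species, two-sided pairwise Wilcoxon rank-sum tests
#' without multiplicity adjustment (a Holm option exists), and a compact
#' letter display. Tests use raw depths; the reported mean depths are
#' corrected for sampling effort when coefficients are supplied.
#'
#' @param obs observations of a single genus (or use `genus` to subset).
#' @param genus optional genus label to subset `obs`.
#' @param alpha significance level for the letter display (default 0.05).
#' @param p_adjust p-value adjustment for pairwise tests (default
#'   `"none"`).
#' @param coefficients optional [sampling_coefficients()] table for
#'   effort-corrected mean depths.
#' @param bin_width depth bin width for coefficient lookup (default 10).
#' @return list of class `"genus_depth_test"`: `genus`, `species` summary
#'   (n, normality p, mean depth), `kruskal_p`, `pairwise` p matrix,
#'   `letters`.
#' @export
genus_depth_test <- function(obs, genus = NULL, alpha = 0.05,
                             p_adjust = "none", coefficients = NULL,
                             bin_width = 10) {
  obs <- validate_observations(obs)
  if (!is.null(genus)) obs <- obs[obs$genus == genus, , drop = FALSE]
  g <- unique(obs$genus)
  if (length(g) != 1) stop("observations must cover exactly one genus")
  drop_sp <- names(which(tapply(obs$count, obs$species, sum) == 0))
  if (length(drop_sp) > 0) {
    warning("dropping species with zero individuals: ",
            paste(drop_sp, collapse = ", "))
    obs <- obs[!obs$species %in% drop_sp, , drop = FALSE]
  }
  long <- expand_depths(obs)
  long$species <- factor(long$species)
  if (nlevels(long$species) < 2) stop("need at least two species")
  shapiro_p <- vapply(split(long$depth, long$species), function(x) {
    if (length(unique(x)) < 3 || length(x) < 3 || length(x) > 5000) {
      return(NA_real_)
    }
    shapiro.test(x)$p.value
  }, numeric(1))
  kw <- suppressWarnings(kruskal.test(depth ~ species, data = long))
  pw <- suppressWarnings(
    pairwise.wilcox.test(long$depth, long$species,
                         p.adjust.method = p_adjust))
  # lower-triangular result to full symmetric matrix
  sp <- levels(long$species)
  pmat <- matrix(NA_real_, length(sp), length(sp),
                 dimnames = list(sp, sp))
  pm <- pw$p.value
  pmat[rownames(pm), colnames(pm)] <- pm
  pmat[is.na(pmat)] <- t(pmat)[is.na(pmat)]
  diag(pmat) <- NA_real_
  letters_ <- compact_letters(pmat, alpha = alpha)
  mean_depths <- vapply(sp, function(s) {
    mean_depth_of_occurrence(obs[obs$species == s, , drop = FALSE],
                             coefficients = coefficients,
                             bin_width = bin_width)
  }, numeric(1))
  species_tab <- data.frame(
    species = sp,
    n = as.integer(table(long$species)[sp]),
    shapiro_p = unname(shapiro_p[sp]),
    mean_depth = unname(mean_depths),
    letter = unname(letters_[sp]),
    stringsAsFactors = FALSE)
  structure(list(genus = g, species = species_tab,
                 kruskal_p = kw$p.value, pairwise = pmat,
                 letters = letters_, alpha = alpha),
            class = "genus_depth_test")
}

#' @export
print.genus_depth_test <- function(x, ...) {
  cat("Congener depth segregation —", x$genus, "\n")
  cat("  Kruskal-Wallis p =", format.pval(x$kruskal_p, digits = 3), "\n")
  print(x$species, row.names = FALSE)
  invisible(x)
}

#' Effort-corrected mean depth of occurrence
#'
#' Weighted mean of observation depths with weights count x sampling
#' coefficient of each observation's (site, depth bin); uniform effort when
#' no coefficients are given.
#'
#' @param obs observation data frame (one species, typically).
#' @param coefficients optional [sampling_coefficients()] table.
#' @param bin_width depth bin width for coefficient lookup (default 10).
#' @return mean depth in metres.
#' @export
mean_depth_of_occurrence <- function(obs, coefficients = NULL,
                                     bin_width = 10) {
  obs <- validate_observations(obs)
  if (nrow(obs) == 0) stop("no observations")
  w <- obs$count
  if (!is.null(coefficients)) {
    bins <- bin_depth(obs$depth_m, bin_width)
    idx <- match(paste(obs$site, bins),
                 paste(coefficients$site, coefficients$depth_bin))
    if (anyNA(idx)) {
      miss <- unique(paste0(obs$site[is.na(idx)], ":", bins[is.na(idx)]))
      stop("no sampling coefficient for: ", paste(miss, collapse = ", "))
    }
    w <- w * coefficients$coefficient[idx]
  }
  sum(obs$depth_m * w) / sum(w)
}
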