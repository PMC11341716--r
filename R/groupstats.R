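#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the total sum of squares of a distance matrix by one or two
#' grouping factors, with sequential (Type I) sums of squares for the
#' two-factor crossed design (first factor, second factor, interaction) and
#' p-values by permutation of raw sample identities. With Euclidean
#' distances and one factor the pseudo-F equals the classical one-way
#' ANOVA F.
#'
#' @param d `dist` object over samples.
#' @param groups grouping vector (first factor), length = number of
#'   samples, at least 2 levels.
#' @param groups2 optional second factor for the crossed design.
#' @param interaction include the interaction term (two-factor designs).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return data frame of class `"permanova"`: `term, df, sum_sq, pseudo_f,
#'   r_squared, p_value` including Residual and Total rows.
#' @export
permanova <- function(d, groups, groups2 = NULL, interaction = TRUE,
                      n_perm = 999, seed = 1) {
  n <- attr(d, "Size")
  if (length(groups) != n) stop("groups length must match samples")
  groups <- factor(groups)
  if (nlevels(groups) < 2) {
    stop("need at least 2 levels in the grouping factor")
  }
  lone <- names(which(table(groups) < 2))
  if (length(lone) > 0) {
    warning("factor level(s) with a single sample: ",
            paste(lone, collapse = ", "))
  }
  dat <- data.frame(g1 = groups)
  if (is.null(groups2)) {
    fml <- d ~ g1
  } else {
    if (length(groups2) != n) stop("groups2 length must match samples")
    dat$g2 <- factor(groups2)
    if (nlevels(dat$g2) < 2) stop("need at least 2 levels in groups2")
    fml <- if (interaction) d ~ g1 * g2 else d ~ g1 + g2
  }
  set.seed(seed)
  fit <- vegan::adonis2(fml, data = dat, permutations = n_perm,
                        by = "terms")
  term_names <- rownames(fit)
  pretty <- c(g1 = "factor1", g2 = "factor2", `g1:g2` = "interaction")
  term_names <- ifelse(term_names %in% names(pretty),
                       pretty[term_names], term_names)
  out <- data.frame(term = term_names,
                    df = fit$Df,
                    sum_sq = fit$SumOfSqs,
                    pseudo_f = fit$F,
                    r_squared = fit$R2,
                    p_value = fit$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  class(out) <- c("permanova", class(out))
  out
}

# per-pair species contributions to Bray-Curtis between two groups:
# average over all between-group sample pairs of |x_ik - x_jk| / sum_k(x_ik + x_jk)
simper_contributions <- function(mat, idx1, idx2) {
  p <- ncol(mat)
  contrib <- numeric(p)
  for (i in idx1) {
    for (j in idx2) {
      denom <- sum(mat[i, ] + mat[j, ])
      if (denom > 0) {
        contrib <- contrib + abs(mat[i, ] - mat[j, ]) / denom
      }
    }
  }
  contrib / (length(idx1) * length(idx2))
}

#' Similarity percentage analysis (SIMPER)
#'
#' Decomposes the average between-group Bray-Curtis dissimilarity into
#' per-species contributions. For every between-group pair of samples,
#' species k contributes `|x_ik - x_jk| / sum_k(x_ik + x_jk)`; contributions
#' are averaged over pairs and sum to the average between-group
#' dissimilarity. Species p-values come from permutations of group labels:
#' `p = (1 + #{perm contribution >= observed}) / (1 + n_perm)`.
#'
#' @param m `abundance_matrix`, conventionally square-root transformed (the
#'   same transform as the clustering it supports).
#' @param grouping factor with exactly two levels over the samples.
#' @param n_perm label permutations (default 999).
#' @param seed RNG seed.
#' @return data frame of class `"simper_table"`: `species, average,
#'   contribution_pct, higher_in, p_value`, sorted by contribution; the
#'   average between-group dissimilarity is in `attr(, "overall")`.
#' @export
simper_analysis <- function(m, grouping, n_perm = 999, seed = 1) {
  mat <- unclass(m)
  grouping <- factor(grouping)
  if (nlevels(grouping) != 2) stop("SIMPER compares exactly two groups")
  if (length(grouping) != nrow(mat)) {
    stop("grouping length must match samples")
  }
  idx1 <- which(grouping == levels(grouping)[1])
  idx2 <- which(grouping == levels(grouping)[2])
  if (length(idx1) == 0 || length(idx2) == 0) stop("both groups must be nonempty")
  if (sum(mat[idx1, ]) == 0 || sum(mat[idx2, ]) == 0) {
    stop("a group has zero total abundance")
  }
  obs <- simper_contributions(mat, idx1, idx2)
  overall <- sum(obs)
  set.seed(seed)
  n_all <- nrow(mat)
  n1 <- length(idx1)
  exceed <- numeric(ncol(mat))
  for (r in seq_len(n_perm)) {
    perm1 <- sample(n_all, n1)
    perm2 <- setdiff(seq_len(n_all), perm1)
    pc <- simper_contributions(mat, perm1, perm2)
    exceed <- exceed + (pc >= obs)
  }
  p <- (1 + exceed) / (1 + n_perm)
  mean1 <- colMeans(mat[idx1, , drop = FALSE])
  mean2 <- colMeans(mat[idx2, , drop = FALSE])
  out <- data.frame(species = colnames(mat),
                    average = obs,
                    contribution_pct = if (overall > 0) 100 * obs / overall
                                       else rep(0, length(obs)),
                    higher_in = ifelse(mean1 >= mean2, levels(grouping)[1],
                                       levels(grouping)[2]),
                    p_value = p,
                    stringsAsFactors = FALSE)
  out <- out[out$average > 0 | colSums(mat) > 0, , drop = FALSE]
  out <- out[order(-out$average), ]
  rownames(out) <- NULL
  attr(out, "overall") <- overall
  attr(out, "groups") <- levels(grouping)
  class(out) <- c("simper_table", class(out))
  out
}

#' Indicator species from a SIMPER table
#'
#' Species whose SIMPER contribution exceeds `contrib_threshold` percent
#' and whose permutation p-value is below `p_threshold`, annotated with the
#' group (depth zone) in which they are more abundant.
#'
#' @param r a `"simper_table"` from [simper_analysis()].
#' @param contrib_threshold minimum percent contribution (default 5,
#'   strict `>`).
#' @param p_threshold maximum p-value (default 0.05, strict `<`).
#' @param direction optional group label: keep only species more abundant
#'   in that group.
#' @return subset of the SIMPER table.
#' @export
indicator_species <- function(r, contrib_threshold = 5, p_threshold = 0.05,
                              direction = NULL) {
  keep <- r$contribution_pct > contrib_threshold & r$p_value < p_threshold
  out <- r[keep, , drop = FALSE]
  if (!is.null(direction)) out <- out[out$higher_in == direction, , drop = FALSE]
  rownames(out) <- NULL
  out
}
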