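#' Similarity-profile (SIMPROF) test for multivariate structure
#'
#' Tests whether a set of samples contains significant internal structure.
#' The observed profile is the sorted vector of pairwise Bray-Curtis
#' dissimilarities. Under the null of exchangeability, each species' values
#' are permuted independently across samples: the expected profile is the
#' rank-wise mean over `n_expected` permuted profiles, the statistic
#' `pi` is the summed absolute rank-wise deviation of the observed profile
#' from the expected one, and the p-value compares `pi` with `n_null`
#' further permuted profiles scored against the same expected profile,
#' with the add-one correction `p = (1 + #{pi_null >= pi_obs}) /
#' (1 + n_null)`.
#'
#' @param m numeric matrix or `abundance_matrix`, samples x species,
#'   already transformed as desired. Fewer than 3 samples have at most one
#'   pairwise distance and are declared homogeneous without testing.
#' @param n_expected permutations for the expected profile (default 999).
#' @param n_null permutations for the null distribution (default 9999).
#' @param alpha significance level used for the reported decision; the
#'   effective level is `max(alpha, 1 / (n_null + 1))`, the smallest
#'   attainable p at the given permutation count.
#' @param seed RNG seed.
#' @return list with `pi`, `p_value`, `n_permutations`, `alpha_effective`,
#'   `decision` (`"heterogeneous"` or `"homogeneous"`), and the observed
#'   and expected profiles.
#' @export
simprof_test <- function(m, n_expected = 999, n_null = 9999, alpha = 1e-7,
                         seed = 1) {
  if (n_expected < 1 || n_null < 1) stop("permutation counts must be >= 1")
  mat <- unclass(m)
  if (!is.matrix(mat)) stop("m must be a matrix")
  alpha_eff <- max(alpha, 1 / (n_null + 1))
  if (nrow(mat) < 3) {
    return(list(pi = 0, p_value = 1, n_permutations = n_null,
                alpha_effective = alpha_eff, decision = "homogeneous",
                observed = numeric(0), expected = numeric(0)))
  }
  set.seed(seed)
  eng <- .simprof_engine(mat, as.integer(n_expected), as.integer(n_null))
  p <- (1 + sum(eng$pi_null >= eng$pi_obs)) / (1 + n_null)
  # alpha = 0 is the degenerate "never reject" limit; otherwise the rule is
  # p <= max(alpha, minimal attainable p at this permutation count)
  reject <- alpha > 0 && p <= alpha_eff
  list(pi = eng$pi_obs, p_value = p, n_permutations = n_null,
       alpha_effective = alpha_eff,
       decision = if (reject) "heterogeneous" else "homogeneous",
       observed = eng$observed, expected = eng$expected)
}

# Leaves (sample indices) under a node of an hclust merge matrix.
# node > 0 refers to merge row, node < 0 to leaf -node.
merge_leaves <- function(merge, node) {
  if (node < 0) return(-node)
  c(merge_leaves(merge, merge[node, 1]), merge_leaves(merge, merge[node, 2]))
}

#' Significant clusters by recursive SIMPROF along a dendrogram
#'
#' Agglomeratively clusters the samples, then walks the tree from the root:
#' each node's members are tested with [simprof_test()]; if significant
#' structure is found the walk recurses into both children, otherwise the
#' node's members form one final (internally homogeneous) cluster. Each
#' node's permutations are seeded from `seed + node id`, so p-values are
#' stable under changes elsewhere in the tree.
#'
#' @param m transformed `abundance_matrix` (pooling and square-root
#'   transform are applied upstream).
#' @param linkage `"complete"` (site-level default), `"ward.D2"` or
#'   `"ward.D"`.
#' @param alpha significance level (default 1e-7); the effective level is
#'   `max(alpha, 1/(n_null + 1))`.
#' @param n_expected,n_null permutation counts per node.
#' @param seed master RNG seed.
#' @return list of class `"simprof_clusters"` with `tree` (hclust),
#'   `clusters` (integer cluster id per sample, named), `members` (list of
#'   sample labels per cluster), `tests` (data frame of per-node results),
#'   and the parameters used.
#' @export
simprof_clusters <- function(m, linkage = c("complete", "ward.D2", "ward.D"),
                             alpha = 1e-7, n_expected = 999, n_null = 9999,
                             seed = 1) {
  linkage <- match.arg(linkage)
  d <- distance_matrix(m, "bray_curtis")
  if (any(is.na(d))) stop("distance matrix contains NA")
  tree <- hclust(d, method = linkage)
  n <- nrow(m)
  merge <- tree$merge
  alpha_eff <- max(alpha, 1 / (n_null + 1))
  tests <- list()
  cluster_of <- integer(n)
  next_cluster <- 0L

  assign_cluster <- function(leaves) {
    next_cluster <<- next_cluster + 1L
    cluster_of[leaves] <<- next_cluster
  }

  walk <- function(node) {
    leaves <- merge_leaves(merge, node)
    if (length(leaves) < 3) {
      if (node > 0) {
        tests[[length(tests) + 1]] <<- data.frame(
          node = node, n = length(leaves), pi = NA_real_, p_value = NA_real_,
          decision = "homogeneous", stringsAsFactors = FALSE)
      }
      assign_cluster(leaves)
      return(invisible())
    }
    node_seed <- (seed + node) %% 2147483647L
    res <- simprof_test(unclass(m)[leaves, , drop = FALSE],
                        n_expected = n_expected, n_null = n_null,
                        alpha = alpha, seed = node_seed)
    tests[[length(tests) + 1]] <<- data.frame(
      node = node, n = length(leaves), pi = res$pi, p_value = res$p_value,
      decision = res$decision, stringsAsFactors = FALSE)
    if (res$decision == "heterogeneous") {
      walk(merge[node, 1])
      walk(merge[node, 2])
    } else {
      assign_cluster(leaves)
    }
    invisible()
  }

  if (n == 1) {
    cluster_of[1] <- 1L
  } else {
    walk(nrow(merge))
  }
  names(cluster_of) <- rownames(m)
  # renumber clusters in dendrogram (and thus depth) order
  ord <- unique(cluster_of[tree$order])
  cluster_of <- match(cluster_of, ord)
  names(cluster_of) <- rownames(m)
  members <- split(names(cluster_of), cluster_of)
  structure(list(tree = tree,
                 clusters = cluster_of,
                 members = members,
                 tests = if (length(tests) > 0) do.call(rbind, tests)
                         else data.frame(),
                 alpha = alpha, alpha_effective = alpha_eff,
                 n_expected = n_expected, n_null = n_null,
                 linkage = linkage, seed = seed),
            class = "simprof_clusters")
}

#' @export
print.simprof_clusters <- function(x, ...) {
  cat("SIMPROF clustering (", x$linkage, " linkage): ",
      length(x$members), " significant cluster(s) among ",
      length(x$clusters), " samples\n", sep = "")
  cat("  alpha =", format(x$alpha),
      "(effective", format(x$alpha_effective), "with",
      x$n_null, "null permutations)\n")
  for (k in seq_along(x$members)) {
    cat("  cluster ", k, ": ", paste(x$members[[k]], collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
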