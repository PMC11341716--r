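#' @useDynLib depthzone, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats aggregate as.dist cutree dist hclust kruskal.test
#'   pairwise.wilcox.test rlnorm rnbinom rnorm rpois runif sd setNames
#'   shapiro.test
#' @importFrom utils read.csv write.csv
NULL

OBS_COLUMNS <- c("site", "dive_id", "depth_m", "species", "family", "count")

#' Validate a table of fish observation records
#'
#' Checks the long-format observation schema used throughout the package:
#' one row per sighting event with columns `site`, `dive_id`, `depth_m`,
#' `species`, `family` and `count` (a `genus` column is derived from the
#' first word of `species` when absent). Counts are sightings, so must be
#' positive integers; depths are metres below the surface.
#'
#' @param obs data frame of observation records.
#' @return the validated data frame (invisibly augmented with `genus`).
#' @export
validate_observations <- function(obs) {
  if (!is.data.frame(obs)) stop("observations must be a data frame")
  missing_cols <- setdiff(OBS_COLUMNS, names(obs))
  if (length(missing_cols) > 0) {
    stop("observation table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  obs$count <- as.numeric(obs$count)
  obs$depth_m <- as.numeric(obs$depth_m)
  bad_count <- which(is.na(obs$count) | obs$count < 1 |
                       obs$count != round(obs$count))
  if (length(bad_count) > 0) {
    stop("count must be a positive integer; first offending row: ",
         bad_count[1])
  }
  bad_depth <- which(is.na(obs$depth_m) | obs$depth_m < 0)
  if (length(bad_depth) > 0) {
    stop("depth_m must be >= 0; first offending row: ", bad_depth[1])
  }
  if (!"genus" %in% names(obs)) {
    obs$genus <- vapply(strsplit(as.character(obs$species), "[ _]"),
                        `[`, character(1), 1L)
  }
  obs
}

#' Read fish observation records from CSV
#'
#' @param path path to a UTF-8 comma-separated file with header
#'   `site,dive_id,depth_m,species,genus,family,count` (`genus` optional).
#' @return validated observation data frame.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obs <- read.csv(path, stringsAsFactors = FALSE)
  obs <- validate_observations(obs)
  message(nrow(obs), " observation records read from ", path)
  obs
}

#' Write observation records to CSV
#' @param obs observation data frame.
#' @param path output path.
#' @export
write_observations <- function(obs, path) {
  write.csv(obs, path, row.names = FALSE)
  invisible(path)
}

#' Read a sampling-effort table from CSV
#'
#' @param path CSV with columns `site,depth_bin,hours`; one row per
#'   surveyed (site, 10-m depth bin), hours strictly positive.
#' @return validated effort data frame.
#' @export
read_effort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  eff <- read.csv(path, stringsAsFactors = FALSE)
  validate_effort(eff)
}

#' @rdname read_effort
#' @param effort effort data frame to validate.
#' @export
validate_effort <- function(effort) {
  need <- c("site", "depth_bin", "hours")
  missing_cols <- setdiff(need, names(effort))
  if (length(missing_cols) > 0) {
    stop("effort table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  effort$hours <- as.numeric(effort$hours)
  effort$depth_bin <- as.numeric(effort$depth_bin)
  if (any(is.na(effort$hours) | effort$hours <= 0)) {
    stop("effort hours must be strictly positive")
  }
  if (anyDuplicated(effort[, c("site", "depth_bin")])) {
    stop("effort table must have one row per (site, depth_bin)")
  }
  effort
}

#' Write an effort table to CSV
#' @param effort effort data frame.
#' @param path output path.
#' @export
write_effort <- function(effort, path) {
  write.csv(effort, path, row.names = FALSE)
  invisible(path)
}

#' Assign a depth to its 10-m bin label
#'
#' Bins are half-open `[label, label + bin_width)` and labelled by their
#' minimum depth, so a 49 m sighting belongs to the 40 m bin.
#'
#' @param depth numeric depth(s) in metres, `>= 0`.
#' @param bin_width bin width in metres (default 10).
#' @return numeric bin label(s).
#' @export
#' @examples
#' bin_depth(49) # 40
bin_depth <- function(depth, bin_width = 10) {
  if (any(is.na(depth)) || any(depth < 0)) stop("depth must be >= 0")
  if (bin_width <= 0) stop("bin_width must be positive")
  floor(depth / bin_width) * bin_width
}

new_abundance_matrix <- function(mat, site, bins, transform = character(0)) {
  stopifnot(is.matrix(mat), length(site) == nrow(mat),
            length(bins) == nrow(mat))
  structure(mat,
            site = as.character(site),
            bins = bins,
            transform = transform,
            class = c("abundance_matrix", class(mat)))
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("Abundance matrix:", nrow(x), "samples x", ncol(x), "species\n")
  tr <- attr(x, "transform")
  cat("  sites:", paste(unique(attr(x, "site")), collapse = ", "), "\n")
  cat("  transform history:",
      if (length(tr) == 0) "(raw counts)" else paste(tr, collapse = " -> "),
      "\n")
  invisible(x)
}

#' Row metadata of an abundance matrix
#'
#' @param m abundance matrix.
#' @return data frame with one row per sample: `sample`, `site`,
#'   `bin_start` (minimum depth of the shallowest constituent bin) and
#'   `n_bins` (number of pooled constituent bins).
#' @export
sample_meta <- function(m) {
  bins <- attr(m, "bins")
  data.frame(sample = rownames(m),
             site = attr(m, "site"),
             bin_start = vapply(bins, min, numeric(1)),
             n_bins = lengths(bins),
             stringsAsFactors = FALSE)
}

row_label <- function(site, bins, single_site) {
  span <- if (length(bins) == 1) as.character(bins[1]) else
    paste0(min(bins), "-", max(bins))
  if (single_site) span else paste0(site, ":", span)
}

#' Build a samples-by-species abundance matrix
#'
#' Aggregates observation counts into (site, depth bin) samples within a
#' depth window. Every bin inside the window appears as a row (all-zero
#' where nothing was observed); columns are the union of species observed
#' in-window.
#'
#' @param obs observation data frame (see [validate_observations()]).
#' @param site optional site label(s) to restrict to; `NULL` keeps all
#'   sites and produces one row per (site, bin).
#' @param window half-open depth window `c(lo, hi)` in metres, both
#'   multiples of `bin_width`. Default `c(40, 300)`.
#' @param bin_width depth bin width in metres.
#' @return an `abundance_matrix` of raw counts.
#' @export
build_abundance_matrix <- function(obs, site = NULL, window = c(40, 300),
                                   bin_width = 10) {
  obs <- validate_observations(obs)
  if (length(window) != 2 || window[2] <= window[1]) {
    stop("window must be c(lo, hi) with lo < hi")
  }
  if (any(window %% bin_width != 0)) {
    stop("window bounds must be multiples of bin_width")
  }
  if (!is.null(site)) obs <- obs[obs$site %in% site, , drop = FALSE]
  obs$bin <- bin_depth(obs$depth_m, bin_width)
  obs <- obs[obs$bin >= window[1] & obs$bin < window[2], , drop = FALSE]
  sites <- if (is.null(site)) sort(unique(obs$site)) else site
  if (nrow(obs) == 0 || length(sites) == 0) {
    warning("no observations in the selected site/window; empty matrix")
    m <- matrix(0, 0, 0)
    return(new_abundance_matrix(m, character(0), list()))
  }
  bin_starts <- seq(window[1], window[2] - bin_width, by = bin_width)
  species <- sort(unique(obs$species))
  single_site <- length(sites) == 1
  grid <- expand.grid(bin = bin_starts, site = sites,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mat <- matrix(0, nrow = nrow(grid), ncol = length(species),
                dimnames = list(NULL, species))
  key <- paste(grid$site, grid$bin)
  idx_row <- match(paste(obs$site, obs$bin), key)
  idx_col <- match(obs$species, species)
  for (r in seq_len(nrow(obs))) {
    mat[idx_row[r], idx_col[r]] <- mat[idx_row[r], idx_col[r]] + obs$count[r]
  }
  rownames(mat) <- mapply(row_label, grid$site, grid$bin,
                          MoreArgs = list(single_site = single_site),
                          USE.NAMES = FALSE)
  new_abundance_matrix(mat, grid$site, as.list(grid$bin))
}

#' Pool sparse depth bins downward
#'
#' Scanning shallow to deep within each site, any sample whose total count
#' is below `min_total` is merged (cell-wise sum) into the next deeper
#' sample, repeatedly, until every surviving sample reaches the threshold.
#' If the deepest sample ends below the threshold it is retained with a
#' warning (pooling is strictly downward). Column sums are conserved.
#'
#' @param m raw-count `abundance_matrix`, rows ordered shallow to deep
#'   within site.
#' @param min_total minimum total individuals per sample (default 5).
#' @return pooled `abundance_matrix`; pooled rows are labelled with their
#'   bin span and remember their constituent bins.
#' @export
pool_sparse_bins <- function(m, min_total = 5) {
  if (length(attr(m, "transform")) > 0) {
    stop("pool_sparse_bins expects raw counts (no transform applied)")
  }
  meta <- sample_meta(m)
  sites <- unique(meta$site)
  single_site <- length(sites) == 1
  out_rows <- list()
  out_site <- character(0)
  out_bins <- list()
  for (s in sites) {
    idx <- which(meta$site == s)
    idx <- idx[order(meta$bin_start[idx])]
    sub <- m[idx, , drop = FALSE]
    bins <- attr(m, "bins")[idx]
    acc_row <- NULL
    acc_bins <- numeric(0)
    rows <- list(); rbins <- list()
    for (i in seq_along(idx)) {
      acc_row <- if (is.null(acc_row)) sub[i, ] else acc_row + sub[i, ]
      acc_bins <- c(acc_bins, bins[[i]])
      if (sum(acc_row) >= min_total) {
        rows[[length(rows) + 1]] <- acc_row
        rbins[[length(rbins) + 1]] <- acc_bins
        acc_row <- NULL
        acc_bins <- numeric(0)
      }
    }
    if (!is.null(acc_row)) {
      if (length(rows) > 0) {
        # leftover deep tail below threshold: fold into the deepest kept row
        # only if combining is still required by the rule? The rule pools
        # downward only, so a trailing sparse tail is kept as its own sample.
        rows[[length(rows) + 1]] <- acc_row
        rbins[[length(rbins) + 1]] <- acc_bins
        warning("deepest sample at site ", s, " has total ", sum(acc_row),
                " < ", min_total, "; retained (pooling is downward only)")
      } else {
        rows[[1]] <- acc_row
        rbins[[1]] <- acc_bins
        warning("site ", s, " pooled into a single sample with total ",
                sum(acc_row), " < ", min_total)
      }
    }
    for (k in seq_along(rows)) {
      out_rows[[length(out_rows) + 1]] <- rows[[k]]
      out_site <- c(out_site, s)
      out_bins[[length(out_bins) + 1]] <- rbins[[k]]
    }
  }
  mat <- do.call(rbind, out_rows)
  colnames(mat) <- colnames(m)
  rownames(mat) <- mapply(row_label, out_site, out_bins,
                          MoreArgs = list(single_site = single_site),
                          USE.NAMES = FALSE)
  new_abundance_matrix(mat, out_site, out_bins,
                       transform = attr(m, "transform"))
}

#' Write an abundance matrix as wide CSV
#' @param m abundance matrix.
#' @param path output path; first column is the sample label.
#' @export
write_abundance_matrix <- function(m, path) {
  df <- data.frame(sample = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
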