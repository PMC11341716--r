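# Small in-code fixtures shared across test files.

# a well-formed observation table with two sites, two dives each
toy_obs <- function() {
  data.frame(
    site = rep(c("A", "B"), each = 6),
    dive_id = rep(c("A_d1", "A_d2", "B_d1", "B_d2"), each = 3),
    depth_m = c(41, 48, 55, 44, 62, 71, 42, 49, 58, 45, 66, 75),
    species = rep(c("Genus1 sp1", "Genus1 sp2", "Genus2 sp1"), 4),
    family = "Fam1",
    count = c(2, 3, 1, 4, 2, 5, 1, 1, 2, 3, 2, 2),
    stringsAsFactors = FALSE
  )
}

# abundance matrix straight from cell values (single site)
toy_matrix <- function(cells, bins = NULL, site = "A") {
  m <- as.matrix(cells)
  if (is.null(bins)) bins <- seq(40, by = 10, length.out = nrow(m))
  if (is.null(colnames(m))) colnames(m) <- paste0("sp", seq_len(ncol(m)))
  rownames(m) <- as.character(bins)
  depthzone:::new_abundance_matrix(m, rep(site, nrow(m)),
                                   as.list(bins))
}

# two-block matrix: disjoint species between shallow and deep halves
block_matrix <- function(n_per_block = 4, n_species = 6, value = 50) {
  m <- matrix(0, 2 * n_per_block, 2 * n_species)
  m[seq_len(n_per_block), seq_len(n_species)] <- value
  m[n_per_block + seq_len(n_per_block),
    n_species + seq_len(n_species)] <- value
  colnames(m) <- paste0("sp", seq_len(ncol(m)))
  toy_matrix(m)
}

# brute-force Bray-Curtis for the oracle route
bc_oracle <- function(u, v) {
  1 - 2 * sum(pmin(u, v)) / sum(u + v)
}
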