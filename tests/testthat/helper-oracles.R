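# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Ordinary least squares via the normal equations.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  list(intercept = beta[1], slope = beta[2])
}

# Brute-force agglomerative clustering on a distance matrix. Cluster
# distances are recomputed from the original pairwise distances at every
# step (exact for average/complete/single linkage). Ties break on the
# lexicographically smallest merged label set. Returns one row per merge:
# height plus the sorted member labels of the new cluster.
agglomerate_oracle <- function(d, labels, linkage = "average") {
  d <- as.matrix(d)
  clusters <- as.list(seq_along(labels))
  merges <- list()
  cluster_dist <- function(a, b) {
    block <- d[a, b, drop = FALSE]
    switch(linkage,
           average = mean(block),
           complete = max(block),
           single = min(block))
  }
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- cluster_dist(clusters[[i]], clusters[[j]])
        key <- paste(sort(labels[c(clusters[[i]], clusters[[j]])]), collapse = "|")
        if (is.null(best) || h < best$h - 1e-12 ||
            (abs(h - best$h) <= 1e-12 && key < best$key)) {
          best <- list(i = i, j = j, h = h, key = key)
        }
      }
    }
    merged <- c(clusters[[best$i]], clusters[[best$j]])
    merges[[length(merges) + 1]] <- list(
      height = best$h,
      members = sort(labels[merged])
    )
    clusters[[best$i]] <- merged
    clusters[[best$j]] <- NULL
  }
  merges
}

# Extract the same (height, member set) view from an hclust fit.
hclust_merges <- function(h) {
  members <- vector("list", nrow(h$merge))
  out <- vector("list", nrow(h$merge))
  for (k in seq_len(nrow(h$merge))) {
    grab <- function(idx) {
      if (idx < 0) h$labels[-idx] else members[[idx]]
    }
    members[[k]] <- sort(c(grab(h$merge[k, 1]), grab(h$merge[k, 2])))
    out[[k]] <- list(height = h$height[k], members = members[[k]])
  }
  out
}

# A minimal valid sample tibble where one congener carries the signal and
# the others are benign fillers; used by the group-test simulations.
make_test_samples <- function(values, groups, signal = "PCB28") {
  stopifnot(length(values) == length(groups))
  out <- tibble::tibble(
    sample_id = sprintf("s%03d", seq_along(values)),
    product = groups,
    brand = NA_character_
  )
  for (cg in pcbrisk::ndl_congeners) {
    out[[cg]] <- if (cg == signal) values else seq_along(values) * 0.01 + 1
  }
  out
}

table5_specs <- function() {
  dplyr::filter(pcb_reference_concentrations("product"), congener != "total")
}
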