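#' Build a congener-profile matrix
#'
#' Arranges concentrations as a congeners x columns matrix for profile
#' clustering: columns are individual samples or group (product/brand)
#' means, in input order. Optional row scaling removes the large
#' between-congener scale differences (PCB 180 concentrations are two
#' orders of magnitude above PCB 28's and would otherwise dominate every
#' distance): `"unit_variance"` divides each row by its SD,
#' `"z_score"` additionally centres it, `"none"` leaves raw values.
#' Constant rows cannot be scaled; they are left raw and recorded in the
#' `flagged_rows` attribute.
#'
#' @inheritParams total_ndl
#' @param group_by `"sample"`, `"product"` or `"brand"`.
#' @param scaling `"unit_variance"` (default), `"z_score"` or `"none"`.
#' @return A numeric matrix of class `profile_matrix` (rows = congeners)
#'   with attributes `scaling` and `flagged_rows`.
#' @export
#' @examples
#' samples <- generate_samples(pcb_reference_concentrations("product"),
#'                             n_samples = 10, seed = 1)
#' build_profile_matrix(samples, group_by = "product")
build_profile_matrix <- function(data,
                                 group_by = c("sample", "product", "brand"),
                                 scaling = c("unit_variance", "z_score", "none")) {
  group_by <- match.arg(group_by)
  scaling <- match.arg(scaling)
  check_congener_columns(data)
  key <- switch(group_by, sample = "sample_id", product = "product", brand = "brand")
  if (!key %in% names(data)) abort(paste0("Column `", key, "` not found."))
  cols <- unique(data[[key]])
  cols <- cols[!is.na(cols)]
  if (length(cols) < 2) {
    abort("Profile matrix needs at least 2 columns after grouping.")
  }
  mat <- vapply(cols, function(cl) {
    rows <- data[[key]] == cl & !is.na(data[[key]])
    colMeans(as.matrix(data[rows, ndl_congeners, drop = FALSE]))
  }, numeric(length(ndl_congeners)))
  dimnames(mat) <- list(ndl_congeners, as.character(cols))
  flagged <- character(0)
  if (scaling != "none") {
    for (i in seq_len(nrow(mat))) {
      s <- sd(mat[i, ])
      if (s == 0) {
        flagged <- c(flagged, rownames(mat)[i])
        next
      }
      mat[i, ] <- if (scaling == "z_score") (mat[i, ] - mean(mat[i, ])) / s
                  else mat[i, ] / s
    }
    if (length(flagged)) {
      warn(paste0("Constant row(s) left unscaled: ", paste(flagged, collapse = ", ")))
    }
  }
  structure(mat, scaling = scaling, flagged_rows = flagged,
            class = c("profile_matrix", class(mat)))
}

#' Hierarchical clustering of congener profiles
#'
#' Agglomerative clustering of the profile-matrix rows (congeners) under a
#' Euclidean metric, wrapping [stats::hclust()]. For row-scaled profiles
#' the squared Euclidean distance between two rows is an affine function
#' of their Pearson correlation, so tight clusters are congeners whose
#' concentrations co-vary across samples.
#'
#' @param matrix A [build_profile_matrix()] result (or any numeric matrix
#'   with rows to cluster).
#' @param metric Distance metric; `"euclidean"`.
#' @param linkage `"average"` (default), `"complete"`, `"single"` or
#'   `"ward"` (ward.D2).
#' @return An object of class `congener_tree` wrapping the `hclust` fit,
#'   with elements `hclust`, `metric`, `linkage`, `labels`.
#' @export
#' @examples
#' pm <- build_profile_matrix(
#'   generate_samples(pcb_reference_concentrations("product"),
#'                    n_samples = 10, seed = 1),
#'   group_by = "product")
#' hierarchical_cluster(pm)
hierarchical_cluster <- function(matrix, metric = "euclidean",
                                 linkage = c("average", "complete", "single", "ward")) {
  linkage <- match.arg(linkage)
  metric <- match.arg(metric, "euclidean")
  if (nrow(matrix) < 2) abort("Need at least 2 rows to cluster.")
  if (any(!is.finite(matrix))) abort("Profile matrix contains non-finite values.")
  method <- if (linkage == "ward") "ward.D2" else linkage
  h <- hclust(dist(matrix, method = metric), method = method)
  structure(list(hclust = h, metric = metric, linkage = linkage,
                 labels = rownames(matrix)),
            class = "congener_tree")
}

#' @export
print.congener_tree <- function(x, ...) {
  cat("<congener_tree>", x$linkage, "linkage,", x$metric, "metric,",
      length(x$hclust$labels), "leaves\n")
  cat("  merge heights:", paste(format(x$hclust$height, digits = 3), collapse = ", "), "\n")
  invisible(x)
}

#' First-merged cluster of a tree
#'
#' Labels joined at the lowest merge height — the tightest congener pair,
#' the quantity profile studies report first.
#'
#' @param tree A `congener_tree`.
#' @return Character vector of the labels in the lowest merge.
#' @export
first_cluster <- function(tree) {
  stopifnot(inherits(tree, "congener_tree"))
  h <- tree$hclust
  pair <- h$merge[1, ]
  h$labels[-pair]
}

#' Export a cluster tree as Newick text
#'
#' Serialises the dendrogram as a Newick string with branch lengths
#' derived from merge heights (leaves sit at height/2 under the standard
#' ultrametric conversion), suitable for any phylogenetics toolkit.
#'
#' @param tree A `congener_tree`.
#' @return A single Newick string (semicolon-terminated).
#' @export
export_tree <- function(tree) {
  stopifnot(inherits(tree, "congener_tree"))
  phy <- ape::as.phylo(tree$hclust)
  ape::write.tree(phy)
}

#' Render a clustered heat map of congener profiles
#'
#' Writes a dendrogram-ordered heat map of the profile matrix to a PNG or
#' PDF file via pheatmap. Deterministic for fixed inputs.
#'
#' @param matrix A [build_profile_matrix()] result.
#' @param path Output file; extension selects the device (.png/.pdf).
#' @param row_tree Optional `congener_tree` for the rows (computed with
#'   default settings when `TRUE`).
#' @param cluster_cols Cluster columns too (only with >= 2 columns).
#' @param ... Passed to [pheatmap::pheatmap()].
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(matrix, path, row_tree = TRUE,
                           cluster_cols = FALSE, ...) {
  if (any(!is.finite(matrix))) abort("Profile matrix contains non-finite values.")
  cluster_rows <- if (inherits(row_tree, "congener_tree")) row_tree$hclust else isTRUE(row_tree)
  pheatmap::pheatmap(unclass(matrix), cluster_rows = cluster_rows,
                     cluster_cols = cluster_cols, filename = path,
                     silent = TRUE, ...)
  if (!file.exists(path)) abort(paste0("Failed to write heat map to ", path))
  invisible(path)
}

#' @describeIn build_profile_matrix Tile plot of the profile matrix.
#' @param object A `profile_matrix`.
#' @param ... Unused.
#' @method autoplot profile_matrix
#' @export
autoplot.profile_matrix <- function(object, ...) {
  df <- tibble::as_tibble(unclass(object), rownames = "congener") |>
    tidyr::pivot_longer(-"congener", names_to = "column", values_to = "value")
  df$congener <- factor(df$congener, levels = rev(ndl_congeners))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$congener,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = attr(object, "scaling")) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "NDL-PCB congener profile") +
    ggplot2::theme_minimal()
}
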