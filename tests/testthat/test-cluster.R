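product_mean_records <- function() {
  specs <- table5_specs()
  purrr::map_dfr(dairy_products, function(p) {
    row <- tibble::tibble(sample_id = p, product = p, brand = NA_character_)
    for (cg in ndl_congeners) {
      row[[cg]] <- specs$mean[specs$group == p & specs$congener == cg]
    }
    row
  })
}

test_that("profile matrix holds group means in congener-by-group layout", {
  pm <- build_profile_matrix(product_mean_records(), group_by = "product",
                             scaling = "none")
  expect_equal(dim(pm), c(6, 3))
  expect_equal(unname(pm["PCB180", ]), c(9.58, 8.14, 12.21))
  expect_equal(colnames(pm), dairy_products)

  z <- build_profile_matrix(product_mean_records(), group_by = "product",
                            scaling = "z_score")
  expect_equal(unname(rowMeans(z)), rep(0, 6), tolerance = 1e-9)
  expect_equal(unname(apply(z, 1, sd)), rep(1, 6), tolerance = 1e-9)

  one <- dplyr::filter(product_mean_records(), product == "yogurt")
  expect_error(build_profile_matrix(one, group_by = "product"), "2 columns")
})

test_that("constant rows are left unscaled and flagged", {
  recs <- product_mean_records()
  for (p in dairy_products) recs$PCB28[recs$product == p] <- 0.1
  expect_warning(
    pm <- build_profile_matrix(recs, group_by = "product", scaling = "z_score"),
    "PCB28")
  expect_equal(attr(pm, "flagged_rows"), "PCB28")
  expect_equal(unname(pm["PCB28", ]), rep(0.1, 3))
})

test_that("identical rows merge at height zero; 3-leaf case matches a hand trace", {
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(5, 5, 5))
  tree <- hierarchical_cluster(m, linkage = "single")
  expect_equal(tree$hclust$height[1], 0)
  expect_equal(first_cluster(tree), c("a", "b"))

  # mutual distances 1, 2, 3 -> single linkage merges at heights 1 then 2
  pts <- rbind(A = c(0, 0), B = c(1, 0), C = c(3, 0))
  tr <- hierarchical_cluster(pts, linkage = "single")
  expect_equal(tr$hclust$height, c(1, 2))
  expect_equal(first_cluster(tr), c("A", "B"))
})

test_that("clustering equals the brute-force agglomeration oracle on small instances", {
  set.seed(77)
  for (linkage in c("average", "complete", "single")) {
    for (n_leaves in 3:5) {
      for (rep in 1:3) {
        m <- matrix(rnorm(n_leaves * 4), nrow = n_leaves,
                    dimnames = list(letters[seq_len(n_leaves)], NULL))
        tree <- hierarchical_cluster(m, linkage = linkage)
        got <- hclust_merges(tree$hclust)
        want <- agglomerate_oracle(dist(m), rownames(m), linkage = linkage)
        expect_equal(length(got), length(want))
        for (k in seq_along(got)) {
          expect_equal(got[[k]]$members, want[[k]]$members)
          expect_equal(got[[k]]$height, want[[k]]$height, tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("clustering is invariant to column permutation", {
  set.seed(3)
  m <- matrix(rnorm(24), nrow = 6, dimnames = list(ndl_congeners, NULL))
  t1 <- hierarchical_cluster(m)
  t2 <- hierarchical_cluster(m[, c(3, 1, 4, 2)])
  expect_equal(t1$hclust$height, t2$hclust$height, tolerance = 1e-12)
  expect_equal(hclust_merges(t1$hclust), hclust_merges(t2$hclust),
               tolerance = 1e-12)
})

test_that("for z-scored rows squared distance is an affine map of correlation", {
  set.seed(14)
  raw <- matrix(rexp(6 * 8), nrow = 6,
                dimnames = list(ndl_congeners, paste0("s", 1:8)))
  n <- ncol(raw)
  z <- t(apply(raw, 1, function(r) (r - mean(r)) / sd(r)))
  for (i in 1:5) {
    for (j in (i + 1):6) {
      d2 <- sum((z[i, ] - z[j, ])^2)
      r <- cor(raw[i, ], raw[j, ])
      expect_equal(d2, 2 * (n - 1) * (1 - r), tolerance = 1e-9)
    }
  }
})

test_that("Newick export round-trips topology, heights and labels", {
  pm <- build_profile_matrix(product_mean_records(), group_by = "product")
  tree <- hierarchical_cluster(pm)
  nwk <- export_tree(tree)
  expect_match(nwk, ";$")
  phy <- ape::read.tree(text = nwk)
  expect_equal(sort(phy$tip.label), sort(ndl_congeners))
  expect_equal(length(phy$tip.label), 6)
  # leaves of an ultrametric dendrogram sit at max(height)/2
  depths <- ape::node.depth.edgelength(phy)[seq_along(phy$tip.label)]
  expect_equal(depths, rep(max(tree$hclust$height) / 2, 6), tolerance = 1e-9)

  # two leaves merged at height h serialize as (A:h/2, B:h/2);
  duo <- hierarchical_cluster(rbind(A = c(0, 0), B = c(2, 0)))
  phy2 <- ape::read.tree(text = export_tree(duo))
  expect_equal(unname(phy2$edge.length), c(1, 1))
})

test_that("heat maps render deterministically to file", {
  pm <- build_profile_matrix(product_mean_records(), group_by = "product")
  tree <- hierarchical_cluster(pm)
  f1 <- tempfile(fileext = ".png")
  f2 <- tempfile(fileext = ".png")
  render_heatmap(pm, f1, row_tree = tree)
  render_heatmap(pm, f2, row_tree = tree)
  expect_true(file.exists(f1) && file.size(f1) > 0)
  expect_equal(file.size(f1), file.size(f2))
  unlink(c(f1, f2))
})
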