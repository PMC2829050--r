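test_that("spearman dissimilarity uses 1 - |rho| with hand-checked values", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4), c = c(4, 3, 2, 1),
             d = c(1, 2, 3, 4))
  d <- spearman_dissimilarity(m)
  expect_equal(diag(d), rep(0, 4), ignore_attr = TRUE)
  expect_equal(d["a", "b"], 1 - 0.8)  # hand-computed rank correlation
  expect_equal(d["a", "c"], 0)        # perfectly anti-monotone: |rho| = 1
  expect_equal(d["a", "d"], 0)        # identical rows
  expect_true(all(d >= 0 & d <= 1 + 1e-12))
  # invariant to monotone transforms of rows
  m2 <- m
  m2["a", ] <- exp(m["a", ])
  m2["b", ] <- m["b", ]^3
  expect_equal(spearman_dissimilarity(m2), d)
})

test_that("constant rows yield distance one with a warning", {
  m <- rbind(a = c(1, 2, 3, 4), k = c(5, 5, 5, 5))
  expect_warning(d <- spearman_dissimilarity(m), "undefined")
  expect_equal(d["a", "k"], 1)
})

test_that("clustering recovers planted correlation blocks", {
  set.seed(55)
  recovered <- sapply(1:20, function(i) {
    z1 <- rnorm(25); z2 <- rnorm(25)
    block <- function(z) t(sapply(1:4, function(j) z * 0.95 + rnorm(25, 0, 0.3)))
    m <- rbind(block(z1), block(z2))
    rownames(m) <- sprintf("m%02d", 1:8)
    cl <- hierarchical_cluster(spearman_dissimilarity(m), "complete", k = 2)
    groups <- split(names(cl$clusters), cl$clusters)
    setequal(groups[[1]], sprintf("m%02d", 1:4)) ||
      setequal(groups[[1]], sprintf("m%02d", 5:8))
  })
  expect_gte(sum(recovered), 18)
})

test_that("clustering is deterministic and validates symmetry", {
  m <- matrix(rnorm(40), 8, 5, dimnames = list(sprintf("x%d", 1:8), NULL))
  d <- spearman_dissimilarity(m)
  c1 <- hierarchical_cluster(d, k = 3)$clusters
  perm <- sample(8)
  c2 <- hierarchical_cluster(d[perm, perm], k = 3)$clusters
  # same partition up to label renumbering
  expect_equal(length(unique(paste(c1[names(c2)], c2))), 3)
  bad <- d; bad[1, 2] <- bad[1, 2] + 0.5
  expect_error(hierarchical_cluster(bad), class = "metamodule_data_error")
  single <- matrix(0, 1, 1, dimnames = list("only", "only"))
  expect_s3_class(hierarchical_cluster(single)$dendrogram, "hclust")
})

test_that("PCA variance fractions behave on structured inputs", {
  # rank-1 data: all points on a line through the centroid
  v <- c(1, 2, 3)
  m <- outer(v, seq(-2, 2, length.out = 10))  # 3 metabolites x 10 individuals
  rownames(m) <- c("a", "b", "c")
  res <- pca_changes(m)
  expect_equal(res$variance_fraction[1], 1, tolerance = 1e-9)
  expect_equal(sum(res$variance_fraction), 1, tolerance = 1e-9)

  # isotropic noise: near-equal fractions
  set.seed(66)
  iso <- matrix(rnorm(4 * 1000), nrow = 4,
                dimnames = list(paste0("m", 1:4), NULL))
  fr <- pca_changes(iso)$variance_fraction
  expect_lt(max(fr) - min(fr), 0.1)
})

test_that("PCA recovers planted orthogonal loading blocks", {
  set.seed(67)
  n <- 200
  # unequal factor strengths keep the top-2 eigenvalues separated so the
  # rotation is identifiable
  f1 <- rnorm(n); f2 <- rnorm(n)
  m <- rbind(t(sapply(1:3, function(i) 2 * f1 + rnorm(n, 0, 0.2))),
             t(sapply(1:3, function(i) 1.2 * f2 + rnorm(n, 0, 0.2))))
  rownames(m) <- sprintf("m%d", 1:6)
  res <- pca_changes(m)
  rot <- res$fit$rotation[, 1:2]
  block1 <- c(1, 1, 1, 0, 0, 0) / sqrt(3)
  block2 <- c(0, 0, 0, 1, 1, 1) / sqrt(3)
  cosines <- abs(crossprod(cbind(block1, block2), rot))
  expect_true(all(apply(cosines, 1, max) >= 0.9))
})

test_that("missing changes are median-imputed and logged", {
  m <- rbind(a = c(1, 2, NA, 4), b = c(2, 1, 3, 2), c = c(0, 1, 0, 1))
  expect_message(res <- pca_changes(m), "imputed 1")
  expect_equal(res$n_imputed, 1L)
})

test_that("change matrices restrict to significant metabolites plus keepers", {
  ab <- tidyr::expand_grid(metabolite = c("sig", "ns", "keep"),
                           individual = sprintf("S%d", 1:4)) |>
    dplyr::mutate(pre = 10, post = c(15, 14, 16, 15, 10.1, 9.9, 10, 10.2,
                                     11, 12, 9, 10))
  change <- tibble::tibble(metabolite = c("sig", "ns", "keep"),
                           q_value = c(0.01, 0.8, 0.9))
  m <- fractional_change_matrix(ab, change, 0.05, always_include = "keep")
  expect_setequal(rownames(m), c("sig", "keep"))
  expect_equal(m["sig", "S1"], 0.5)
  # zero/missing pre yields NA change
  ab0 <- dplyr::mutate(ab, pre = dplyr::if_else(metabolite == "sig" &
                                                  individual == "S1", 0, pre))
  m0 <- fractional_change_matrix(ab0, change, 0.05, always_include = "keep")
  expect_true(is.na(m0["sig", "S1"]))
})
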