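test_that("Bray-Curtis handles the canonical cases", {
  m <- rbind(s1 = c(1, 2), s2 = c(2, 1), s3 = c(1, 2), s4 = c(0, 3))
  D <- bray_curtis(m)
  expect_equal(D["s1", "s3"], 0)
  expect_equal(D["s1", "s2"], 1 / 3)
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(D, t(D))
  disj <- rbind(a = c(1, 0), b = c(0, 1))
  expect_equal(bray_curtis(disj)["a", "b"], 1)
  # invariant to joint rescaling of all samples
  expect_equal(bray_curtis(m * 7), D)
  expect_error(bray_curtis(rbind(a = c(0, 0), b = c(1, 1))),
               "all-zero sample")
})

test_that("PCoA recovers Euclidean configurations without correction", {
  set.seed(1)
  pts <- matrix(rnorm(8), 4, 2, dimnames = list(paste0("s", 1:4), NULL))
  D <- as.matrix(dist(pts))
  ord <- pcoa_ord(D)
  expect_equal(ord$correction_constant, 0)
  rec <- as.matrix(dist(ord$coordinates))
  expect_lt(max(abs(rec - D)), 1e-10)
  # two samples at dissimilarity d: one axis, points at +/- d/2
  D2 <- matrix(c(0, 0.8, 0.8, 0), 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  ord2 <- pcoa_ord(D2)
  expect_equal(ncol(ord2$coordinates), 1L)
  expect_equal(unname(sort(ord2$coordinates[, 1])), c(-0.4, 0.4))
})

test_that("Cailliez correction removes negative eigenvalues and embeds D + c", {
  # a fixed non-Euclidean dissimilarity (strong triangle violation)
  D <- matrix(0, 4, 4)
  D[upper.tri(D)] <- c(1, 1, 1, 1, 1, 2.9)
  D <- D + t(D)
  dimnames(D) <- list(paste0("s", 1:4), paste0("s", 1:4))
  raw <- eigen(epslps:::.gower(D), symmetric = TRUE)$values
  expect_lt(min(raw), 0)  # fixture really is non-Euclidean
  ord <- pcoa_ord(D)
  expect_gt(ord$correction_constant, 0)
  expect_gte(min(ord$eigenvalues), -1e-8 * max(ord$eigenvalues))
  rec <- as.matrix(dist(ord$coordinates))
  target <- D + ord$correction_constant
  diag(target) <- 0
  expect_lt(max(abs(rec - target)), 1e-8)
  expect_true(sum(ord$proportions) <= 1 + 1e-12)
})

test_that("PCoA eigenvalues agree with the ape reference", {
  skip_if_not_installed("ape")
  set.seed(2)
  m <- matrix(rexp(7 * 5), 7, 5, dimnames = list(paste0("s", 1:7), NULL))
  D <- bray_curtis(m)
  ours <- pcoa_ord(D)
  ref <- ape::pcoa(as.dist(D), correction = "cailliez")
  vals <- if (!is.null(ref$values$Corr_eig)) ref$values$Corr_eig else
    ref$values$Eigenvalues
  k <- min(length(vals), sum(ours$eigenvalues > 1e-8))
  expect_equal(ours$eigenvalues[seq_len(k)], vals[seq_len(k)],
               tolerance = 1e-6)
})

test_that("soil PCA standardises and matches a direct eigendecomposition", {
  md <- data.frame(sample_id = paste0("s", 1:6),
                   v1 = c(1, 2, 3, 4, 5, 6) + 0.1 * c(1, -1, 0, 1, -1, 0),
                   v2 = c(6, 4, 5, 1, 3, 2),
                   v3 = c(2, 2, 4, 4, 7, 1))
  ord <- pca_soil(md, cols = c("v1", "v2", "v3"))
  x <- scale(as.matrix(md[, c("v1", "v2", "v3")]))
  e <- eigen(stats::cov(x), symmetric = TRUE)
  expect_equal(ord$eigenvalues, e$values, tolerance = 1e-10)
  # scores match up to axis sign
  sc <- x %*% e$vectors
  for (j in 1:3) {
    expect_true(isTRUE(all.equal(ord$coordinates[, j], sc[, j],
                                 tolerance = 1e-8,
                                 check.attributes = FALSE)) ||
                isTRUE(all.equal(ord$coordinates[, j], -sc[, j],
                                 tolerance = 1e-8,
                                 check.attributes = FALSE)))
  }
  # two perfectly correlated variables: one axis carries everything
  md2 <- data.frame(a = 1:5, b = 2 * (1:5))
  ord2 <- pca_soil(md2, cols = c("a", "b"))
  expect_equal(ord2$proportions[1], 1)
  md3 <- data.frame(a = 1:5, b = 2 * (1:5), cst = 1)
  expect_warning(pca_soil(md3, cols = c("a", "b", "cst")), "zero-variance")
})

test_that("confidence ellipses follow the covariance eigenstructure", {
  # points on a circle: centred, equal semi-axes
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  circ <- cbind(cos(th), sin(th))
  e <- confidence_ellipse(circ)
  expect_equal(unname(e$center), c(0, 0), tolerance = 1e-12)
  expect_equal(e$semi_axes[1], e$semi_axes[2], tolerance = 1e-10)
  expect_false(e$degenerate)
  # hand-computed 3-point fixture
  pts <- rbind(c(0, 0), c(2, 1), c(4, 0))
  S <- stats::cov(pts)
  lam <- eigen(S, symmetric = TRUE)$values
  e3 <- confidence_ellipse(pts, level = 0.95)
  expect_equal(unname(e3$semi_axes),
               sqrt(lam * stats::qchisq(0.95, 2)), tolerance = 1e-10)
  # F-based small-sample quantile is wider at n = 3
  ef <- confidence_ellipse(pts, quantile = "f")
  expect_true(all(ef$semi_axes > e3$semi_axes))
  # collinear points and tiny groups are flagged degenerate
  expect_true(confidence_ellipse(cbind(1:4, 2 * (1:4)))$degenerate)
  expect_true(confidence_ellipse(cbind(1:2, 1:2))$degenerate)
})
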