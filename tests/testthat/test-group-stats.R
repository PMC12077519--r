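const_std_map <- function(value, id, label = "g", mask_cells = NULL) {
  m <- structure(list(values = matrix(value, 97L, 50L),
                      mask = matrix(FALSE, 97L, 50L),
                      levels = seq(0.02, 0.98, by = 0.01),
                      angles = theta_grid(50L), bone_length = 40,
                      standardized = TRUE,
                      meta = list(id = id, label = label)),
                 class = "thickness_map")
  if (!is.null(mask_cells)) m$mask[mask_cells] <- TRUE
  m
}

test_that("assemble_matrix flattens row-major and aligns ids with rows", {
  a <- const_std_map(1, "a"); b <- const_std_map(3, "b")
  sm <- assemble_matrix(list(a, b), c("g1", "g2"))
  expect_identical(dim(sm$X), c(2L, 4850L))
  expect_true(all(sm$X[1L, ] == 1) && all(sm$X[2L, ] == 3))
  # row-major: cell (level 2, angle 1) is column 51
  c2 <- const_std_map(0, "c")
  c2$values[2L, 1L] <- 9
  smc <- assemble_matrix(list(c2), "g")
  expect_equal(smc$X[1L, 51L], 9)

  sm2 <- assemble_matrix(list(b, a), c("g2", "g1"))
  expect_identical(sm2$ids, c("b", "a"))
  expect_equal(sm2$X, sm$X[2:1, ])
  expect_error(assemble_matrix(list(a, a), c("g", "g")), "duplicate")
  un <- a; un$standardized <- FALSE
  expect_error(assemble_matrix(list(un, un), c("g", "g")), "standardized|mixed")
})

test_that("flagged cells are imputed from the group column mean and counted", {
  maps <- c(lapply(1:9, function(i) const_std_map(2, paste0("g", i))),
            list(const_std_map(2, "g10", mask_cells = cbind(1:5, 1L))))
  maps[[10L]]$values[cbind(1:5, 1L)] <- 99  # masked garbage must be replaced
  sm <- assemble_matrix(maps, rep("grp", 10L))
  expect_identical(sm$n_imputed, 5L)
  expect_true(all(sm$X == 2))
})

test_that("PCA: rank detection, reconstruction, eigenvalue/score consistency", {
  withr::with_seed(21, {
    base <- stats::rnorm(40)
    X <- t(vapply(seq(0, 3, length.out = 8L), function(a) base * a + 1, base))
  })
  p <- fit_pca(X)
  expect_lt(p$eigenvalues[2L] / p$eigenvalues[1L], 1e-10)

  withr::with_seed(22, Xf <- matrix(stats::rnorm(8 * 6), 8L, 6L))
  pf <- fit_pca(Xf)
  recon <- sweep(pf$scores %*% t(pf$components), 2L, pf$mean, "+")
  expect_lt(max(abs(recon - Xf)), 1e-8)
  expect_lt(max(abs(crossprod(pf$components) - diag(ncol(pf$components)))), 1e-8)
  expect_lt(max(abs(colMeans(pf$scores))), 1e-8)
  expect_equal(apply(pf$scores, 2L, stats::var), pf$eigenvalues,
               tolerance = 1e-6, ignore_attr = TRUE)
  # sign convention: largest-|loading| entry positive
  for (j in seq_len(ncol(pf$components)))
    expect_gt(pf$components[which.max(abs(pf$components[, j])), j], 0)
  expect_error(fit_pca(matrix(1, 5L, 4L)), "rank")
})

test_that("PCA scores ignore a constant shift of every specimen", {
  withr::with_seed(23, X <- matrix(stats::rnorm(60), 10L, 6L))
  p1 <- fit_pca(X, r = 3L)
  p2 <- fit_pca(sweep(X, 2L, rep(7, 6L), "+"), r = 3L)
  expect_equal(p1$scores, p2$scores, tolerance = 1e-8)
})

test_that("Hotelling T2: zero at the mean, t^2 in one dimension, calibrated size", {
  withr::with_seed(31, X <- matrix(stats::rnorm(60), 20L, 3L))
  ht <- hotelling_one_sample(X, colMeans(X))
  expect_equal(ht$T2, 0)
  expect_equal(ht$p_value, 1)

  withr::with_seed(32, x1 <- matrix(stats::rnorm(15, 0.4), ncol = 1L))
  ht1 <- hotelling_one_sample(x1, 0)
  tt <- stats::t.test(x1, mu = 0)
  expect_equal(ht1$T2, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(ht1$p_value, tt$p.value, tolerance = 1e-10)

  expect_error(hotelling_one_sample(X[1:3, ], c(0, 0, 0)), "m > p")
})

test_that("Hotelling T2 is invariant to joint affine transforms", {
  withr::with_seed(33, {
    X <- matrix(stats::rnorm(60), 20L, 3L)
    A <- matrix(stats::rnorm(9), 3L) + diag(3)
    b <- stats::rnorm(3)
  })
  target <- c(0.2, -0.1, 0.5)
  h1 <- hotelling_one_sample(X, target)
  h2 <- hotelling_one_sample(sweep(X %*% A, 2L, b, "+"),
                             as.numeric(target %*% A) + b)
  expect_equal(h1$T2, h2$T2, tolerance = 1e-8)
})

test_that("CVA: axis count, whitened within-covariance, forced separation", {
  withr::with_seed(41, {
    X <- do.call(rbind, lapply(1:4, function(g)
      sweep(matrix(stats::rnorm(30), 10L, 3L), 2L, c(g * 2, 0, 0), "+")))
  })
  lab <- rep(paste0("g", 1:4), each = 10L)
  cv <- fit_cva(X, lab)
  expect_identical(ncol(cv$canonical_axes), 3L)
  # pooled within-group covariance is whitened in canonical space
  Wc <- t(cv$canonical_axes) %*% cv$pooled_within_covariance %*% cv$canonical_axes
  expect_lt(max(abs(Wc - diag(3))), 1e-6)

  withr::with_seed(42, {
    Y <- rbind(matrix(stats::rnorm(300), 100L, 3L),
               sweep(matrix(stats::rnorm(300), 100L, 3L), 2L, c(10, 0, 0), "+"))
  })
  cv2 <- fit_cva(Y, rep(c("a", "b"), each = 100L))
  ax <- cv2$canonical_axes[, 1L] / sqrt(sum(cv2$canonical_axes[, 1L]^2))
  expect_gt(abs(ax[1L]), 0.99)
  expect_error(fit_cva(Y, rep("a", 200L)), "2 groups")
  expect_error(fit_cva(Y, c("a", rep("b", 199L))), "at least 2 members")
})

test_that("CVA group separation vanishes under label permutation", {
  withr::with_seed(43, {
    Y <- rbind(matrix(stats::rnorm(60), 20L, 3L),
               sweep(matrix(stats::rnorm(60), 20L, 3L), 2L, c(4, 0, 0), "+"))
    lab <- rep(c("a", "b"), each = 20L)
    real_eig <- fit_cva(Y, lab)$eigenvalues[1L]
    perm_eig <- replicate(100L, fit_cva(Y, sample(lab))$eigenvalues[1L])
  })
  expect_gt(real_eig, stats::quantile(perm_eig, 0.95))
})

test_that("CVA discriminant subspace matches MASS::lda", {
  skip_if_not_installed("MASS")
  withr::with_seed(44, {
    Y <- rbind(matrix(stats::rnorm(60), 20L, 3L),
               sweep(matrix(stats::rnorm(60), 20L, 3L), 2L, c(2, 1, 0), "+"),
               sweep(matrix(stats::rnorm(60), 20L, 3L), 2L, c(0, 3, 1), "+"))
  })
  lab <- rep(c("a", "b", "c"), each = 20L)
  cv <- fit_cva(Y, lab)
  ld <- MASS::lda(Y, grouping = lab)
  # first canonical axis parallel to LD1 (up to sign and scale)
  a1 <- cv$canonical_axes[, 1L]; l1 <- ld$scaling[, 1L]
  cosang <- abs(sum(a1 * l1)) / sqrt(sum(a1^2) * sum(l1^2))
  expect_gt(cosang, 0.999)
})

test_that("typicality: centroid gives 1, chi-square tail identity, monotone decay", {
  withr::with_seed(45, {
    Y <- rbind(matrix(stats::rnorm(45), 15L, 3L),
               sweep(matrix(stats::rnorm(45), 15L, 3L), 2L, c(6, 0, 0), "+"),
               sweep(matrix(stats::rnorm(45), 15L, 3L), 2L, c(0, 6, 0), "+"),
               sweep(matrix(stats::rnorm(45), 15L, 3L), 2L, c(0, 0, 6), "+"))
  })
  lab <- rep(c("a", "b", "c", "d"), each = 15L)
  cv <- fit_cva(Y, lab)
  t0 <- typicality(cv, cv$group_means["a", ], "a")
  expect_equal(t0$D2, 0)
  expect_equal(t0$p, 1)
  # D2 = 7.815 is the 95th chi-square percentile on 3 df
  z <- cv$group_means["a", ] + c(sqrt(7.815), 0, 0)
  expect_equal(typicality(cv, z, "a")$p, 0.05, tolerance = 1e-3)
  d <- seq(0, 4, by = 0.5)
  probs <- vapply(d, function(x)
    typicality(cv, cv$group_means["a", ] + c(x, 0, 0), "a")$p, 0)
  expect_true(all(diff(probs[-1L]) < 0))
  expect_error(typicality(cv, z, "nope"), "unknown group")
  # F-based small-sample variant is more conservative far from the centroid
  tF <- typicality(cv, z, "a", method = "F")
  expect_true(tF$p > 0 && tF$p < 1)
})

test_that("leave-one-out: chance for identical groups, perfect for separated ones", {
  withr::with_seed(46, {
    Y <- matrix(stats::rnorm(40 * 3), 40L, 3L)
    lab <- rep(c("a", "b"), each = 20L)
    lo <- loo_classification(Y, lab)
  })
  # indistinguishable groups: accuracy within the binomial 95% band around 0.5
  expect_gt(lo$overall, 0.5 - 1.96 * sqrt(0.25 / 40))
  expect_lt(lo$overall, 0.5 + 1.96 * sqrt(0.25 / 40))

  withr::with_seed(47, {
    Ys <- rbind(matrix(stats::rnorm(60), 20L, 3L),
                sweep(matrix(stats::rnorm(60), 20L, 3L), 2L, c(10, 0, 0), "+"))
  })
  lo2 <- loo_classification(Ys, rep(c("a", "b"), each = 20L))
  expect_equal(lo2$overall, 1.0)
  expect_identical(sum(lo2$confusion), 40L)
  expect_error(loo_classification(Ys, rep(c("a", "b"), each = 20L),
                                  ids = c("x", rep("y", 39L))), "duplicate")
  expect_error(loo_classification(Ys[1:5, ], c("a", "a", "b", "b", "b")),
               "at least 3")
})
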