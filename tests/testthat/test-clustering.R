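two_clouds <- function(sep = 20, n = 20, d = 2) {
  x <- rbind(
    matrix(rnorm(n * d, 0, 1), ncol = d),
    matrix(rnorm(n * d, sep, 1), ncol = d)
  )
  rownames(x) <- sprintf("p%02d", seq_len(2 * n))
  x
}

test_that("complete linkage merges the worked three-point example", {
  m <- matrix(c(0, 1, 10), ncol = 1, dimnames = list(c("a", "b", "c"), "f"))
  d <- hierarchical_complete(m, "euclidean")
  expect_identical(d$merges$height, c(1, 10))
  expect_equal(unlist(d$merges[1, c("a", "b")]), c(a = -2, b = -1))
  ## identical rows merge at height 0
  m2 <- matrix(c(1, 1, 5, 1, 1, 9), ncol = 2, dimnames = list(c("x", "y", "z"), NULL))
  d2 <- hierarchical_complete(m2, "euclidean")
  expect_identical(d2$merges$height[1], 0)
  ## heights are non-decreasing (complete-link monotonicity)
  expect_true(!is.unsorted(d2$merges$height))
  expect_error(hierarchical_complete(m[1, , drop = FALSE]), "at least 2")
  ## asymmetric "metric" is rejected
  expect_error(
    hierarchical_complete(m, metric = function(a, b) a[1] - b[1]),
    "symmetric"
  )
})

test_that("complete linkage agrees with stats::hclust on generic data", {
  withr::with_seed(17, {
    for (rep in 1:8) {
      n <- sample(4:9, 1)
      m <- matrix(rnorm(n * 3), ncol = 3)
      rownames(m) <- sprintf("r%02d", seq_len(n))
      mine <- hierarchical_complete(m, "euclidean")
      ref <- stats::hclust(dist(m), method = "complete")
      expect_equal(mine$merges$height, ref$height, tolerance = 1e-10)
      ## identical partitions at every cut height
      hc <- as.hclust(mine)
      for (k in 2:(n - 1)) {
        a <- cutree(hc, k)
        b <- cutree(ref, k)
        ## same partition up to label permutation
        expect_identical(length(unique(paste(a, b))), k)
      }
    }
  })
})

test_that("cosine distance ignores row magnitudes", {
  m <- rbind(a = c(1, 0), b = c(10, 0), c = c(0, 3))
  d <- cosine_distance(m)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 1)
  expect_true(all(abs(d - t(d)) < 1e-12))
})

test_that("fcm separates well-separated clouds and matches the direct formulas", {
  withr::with_seed(5, x <- two_clouds(sep = 40))
  f <- fcm(x, c = 2, seed = 9)
  top <- apply(f$membership, 1, max)
  expect_true(all(top > 0.95))
  ## the two fuzzy centers sit near the two cloud means
  centers <- f$centers[order(f$centers[, 1]), ]
  expect_lt(max(abs(centers[1, ] - colMeans(x[1:20, ]))), 1)
  expect_lt(max(abs(centers[2, ] - colMeans(x[21:40, ]))), 1)
  ## agreement with a loop-based implementation of the update formulas,
  ## run from the same initial centers
  init <- x[withr::with_seed(9, sample.int(nrow(x), 2)), ]
  ref <- fcm_reference(x, init, m = 2, iters = f$iterations + 1L)
  expect_equal(f$centers, ref$centers, tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(f$membership, ref$membership, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("fcm agrees with an independent library implementation", {
  withr::with_seed(23, x <- two_clouds(sep = 12, n = 15))
  f <- fcm(x, c = 2, seed = 31, tol = 1e-8)
  ref <- e1071::cmeans(x, centers = f$centers, m = 2, iter.max = 200)
  ## same fixed point: centers and memberships match after alignment
  perm <- if (sum(abs(ref$centers[1, ] - f$centers[1, ])) <
    sum(abs(ref$centers[2, ] - f$centers[1, ]))) 1:2 else 2:1
  expect_equal(unname(ref$centers[perm, ]), unname(f$centers), tolerance = 1e-3)
  expect_equal(unname(ref$membership[, perm]), unname(f$membership), tolerance = 1e-3)
})

test_that("fcm degenerate inputs and determinism behave as specified", {
  ## identical points: identical centers, memberships 1/c
  x <- matrix(1, 6, 2, dimnames = list(paste0("p", 1:6), NULL))
  f <- fcm(x, 2, seed = 3)
  expect_true(all(abs(f$membership - 0.5) < 1e-9))
  expect_equal(f$centers[1, ], f$centers[2, ], ignore_attr = TRUE)
  ## a point coincident with a converged center gets full membership there
  y2 <- rbind(c(0, 0), c(10, 0))
  fy <- fcm(y2, 2, seed = 2)
  expect_true(all(apply(fy$membership, 1, max) > 1 - 1e-9))
  ## determinism under the seed
  y <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1), c(5, 3))
  expect_identical(fcm(y, 2, seed = 4)$membership, fcm(y, 2, seed = 4)$membership)
  ## objective trace is non-increasing
  withr::with_seed(8, z <- two_clouds(sep = 6))
  fz <- fcm(z, 3, seed = 11)
  expect_true(all(diff(fz$objective_trace) < 1e-8))
  expect_error(fcm(z, c = 1, seed = 1))
  expect_error(fcm(z, c = 2, m = 1, seed = 1))
})

test_that("validity indices hit their analytic values on hard and uniform partitions", {
  x <- matrix(c(0, 0, 10, 10, 0, 1, 0, 1), ncol = 2)
  hard <- structure(
    list(
      centers = rbind(c(0, 0.5), c(10, 0.5)),
      membership = rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1)),
      m = 2
    ),
    class = "fcm_fit"
  )
  vi <- validity_indices(x, list(hard))
  expect_identical(vi$PC, 1)
  expect_identical(vi$CE, 0)
  uniform <- hard
  uniform$membership <- matrix(0.5, 4, 2)
  vu <- validity_indices(x, list(uniform))
  expect_equal(vu$PC, 0.5)
  expect_equal(vu$CE, log(2))
  ## PC bounds: 1/c <= PC <= 1 on a real fit
  withr::with_seed(2, y <- two_clouds(sep = 15))
  f3 <- fcm(y, 3, seed = 6)
  v3 <- validity_indices(y, list(f3))
  expect_gte(v3$PC, 1 / 3)
  expect_lte(v3$PC, 1)
  expect_gte(v3$CE, 0)
  ## duplicate centers leave XBI undefined
  dup <- hard
  dup$centers <- rbind(c(0, 0.5), c(0, 0.5))
  expect_true(is.na(validity_indices(x, list(dup))$XBI))
})

test_that("XBI prefers the true cluster count on separated clouds", {
  withr::with_seed(41, x <- two_clouds(sep = 25))
  f2 <- fcm(x, 2, seed = 21)
  f5 <- fcm(x, 5, seed = 21)
  v <- validity_indices(x, list(f2, f5))
  expect_lt(v$XBI[v$c == 2], v$XBI[v$c == 5])
})

test_that("three planted gene clusters are recovered and flagged by PI", {
  withr::with_seed(33, {
    x <- rbind(
      matrix(rnorm(15 * 4, 0, 1), ncol = 4),
      matrix(rnorm(15 * 4, 12, 1), ncol = 4),
      matrix(rnorm(15 * 4, 24, 1), ncol = 4)
    )
    rownames(x) <- sprintf("g%02d", 1:45)
  })
  fits <- lapply(2:6, function(ci) fcm(x, ci, seed = 50 + ci))
  vi <- validity_indices(x, fits)
  ## centers at c = 3 land on the planted means within the cloud spread
  f3 <- fits[[2]]
  truth <- rbind(rep(0, 4), rep(12, 4), rep(24, 4))
  ord <- order(f3$centers[, 1])
  expect_lt(max(abs(f3$centers[ord, ] - truth)), 1.5)
  ## PI elbow at 3 clusters: the largest relative drop lands there,
  ## and XBI reaches its minimum at the true count
  drops <- vi$PI[-nrow(vi)] / vi$PI[-1]
  expect_identical(vi$c[-1][which.max(drops)], 3L)
  expect_identical(vi$c[which.min(vi$XBI)], 3L)
})

test_that("pca_2d projects onto the top axes with fixed signs", {
  withr::with_seed(3, {
    x <- cbind(rnorm(30, sd = 5), rnorm(30, sd = 1))
    rot <- matrix(c(cos(0.7), sin(0.7), -sin(0.7), cos(0.7)), 2)
    y <- x %*% rot
  })
  coords <- pca_2d(y)
  ## 2-D centered data: rotation only, pairwise distances preserved
  expect_equal(as.matrix(dist(coords)), as.matrix(dist(y)), tolerance = 1e-8)
  expect_gte(var(coords[, 1]), var(coords[, 2]))
  ## collinear points: second coordinate collapses with a warning
  line <- cbind(1:10, (1:10) * 2)
  expect_warning(c2 <- pca_2d(line), "rank")
  expect_true(all(abs(c2[, 2]) < 1e-8))
})

test_that("fuzzy area and itemset cross-match follow the membership threshold", {
  u <- rbind(
    a = c(0.5, 0.5),
    b = c(0.9, 0.1),
    c = c(0.59, 0.41),
    d = c(1.0, 0.0)
  )
  expect_setequal(fuzzy_area_genes(u, tau = 0.6), c("a", "c"))
  expect_identical(fuzzy_area_genes(u, tau = 1.0), c("a", "b", "c"))
  it <- transaction_db(list(t1 = c("a", "b"), t2 = c("a", "b"), t3 = c("x", "y", "a")))
  mined <- mine_frequent(it, 30)
  cross <- crossmatch_itemsets(mined, fuzzy_area = c("a", "c"), universe = rownames(u))
  expect_identical(cross$fuzzy_fraction[cross$items == "a,b"], 0.5)
  expect_identical(cross$fuzzy_fraction[cross$items == "a"], 1)
  expect_identical(cross$fuzzy_fraction[cross$items == "b"], 0)
  ## genes outside the clustered universe are counted separately
  expect_identical(cross$n_unknown[cross$items == "a,x"], 1L)
  expect_identical(cross$fuzzy_fraction[cross$items == "x,y"], NA_real_)
  expect_identical(cross$n_unknown[cross$items == "x,y"], 2L)
})
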