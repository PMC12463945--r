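test_that("corrected item-total correlation matches hand computations", {
  # three identical columns: each item correlates perfectly with its rest score
  d <- data.frame(i1 = c(1, 2, 3, 4), i2 = c(1, 2, 3, 4), i3 = c(1, 2, 3, 4))
  expect_equal(unname(corrected_item_total(d, names(d))), rep(1, 3))

  # C runs against the (A + B) rest score
  d <- data.frame(A = 1:4, B = 1:4, C = 4:1)
  expect_equal(unname(corrected_item_total(d, c("A", "B", "C"))[3]), -1)

  d$Z <- 2
  expect_error(corrected_item_total(d, c("A", "B", "Z")), "zero-variance.*Z")
})

test_that("item-total screen at 0.5 eliminates a 0.199 item", {
  L <- matrix(c(0.8, 0.8, 0.8, 0.7, 0.1, 0.05, 0.1, 0.6), 4, 2,
              dimnames = list(c("a1", "a2", "a3", "ks3"), NULL))
  it <- c(a1 = 0.7, a2 = 0.7, a3 = 0.7, ks3 = 0.199)
  scr <- apply_item_retention_rules(list(loadings = L), it)
  expect_false(scr$retained[scr$item == "ks3"])
  expect_equal(scr$reason[scr$item == "ks3"], "low_item_total")
})

test_that("cronbach alpha matches direct formula and closed forms", {
  # perfectly parallel items
  d <- data.frame(i1 = c(1, 3, 2, 5), i2 = c(1, 3, 2, 5), i3 = c(1, 3, 2, 5))
  expect_equal(cronbach_alpha(d, names(d)), 1)

  # hand evaluation of alpha = k/(k-1) (1 - sum var_i / var_tot)
  d <- data.frame(a = c(1, 2, 3, 4), b = c(2, 3, 4, 5), c = c(1, 2, 4, 5))
  k <- 3
  vt <- var(rowSums(d))
  expect_equal(cronbach_alpha(d, names(d)),
               k / (k - 1) * (1 - sum(apply(d, 2, var)) / vt))

  # two empirically uncorrelated equal-variance items: alpha = 0
  x <- exact_parallel_items(100, 2, r = 0, seed = 4)
  d <- data.frame(x1 = x[, 1], x2 = x[, 2])
  expect_equal(cronbach_alpha(d, names(d)), 0, tolerance = 1e-12)
})

test_that("alpha equals the Spearman-Brown form kr/(1+(k-1)r) on parallel items", {
  for (r in c(0.2, 0.5, 0.8)) {
    for (k in c(3, 5)) {
      x <- as.data.frame(exact_parallel_items(60, k, r, seed = k))
      expect_equal(cronbach_alpha(x, names(x)), k * r / (1 + (k - 1) * r),
                   tolerance = 1e-12)
    }
  }
})

test_that("alpha is invariant under adding a constant to an item", {
  d <- generate_responses(ground_truth(tiny_instrument()), 300, seed = 2)
  items <- paste0("A", 1:3)
  a0 <- cronbach_alpha(d, items)
  d$A1 <- d$A1 + 7
  expect_equal(cronbach_alpha(d, items), a0)
})

test_that("KMO agrees with regression-residual partial correlations", {
  set.seed(10)
  n <- 400
  f <- rnorm(n)
  x <- sapply(1:6, function(i) 0.7 * f + rnorm(n))
  colnames(x) <- paste0("v", 1:6)
  d <- as.data.frame(x)
  expect_equal(kmo(d)$kmo, kmo_oracle(x), tolerance = 1e-10)
})

test_that("KMO is high for a strong single common factor", {
  set.seed(12)
  n <- 5000
  f <- rnorm(n)
  d <- as.data.frame(sapply(1:3, function(i)
    0.9 * f + sqrt(1 - 0.81) * rnorm(n)))
  names(d) <- paste0("v", 1:3)
  expect_gt(kmo(d)$kmo, 0.7)
})

test_that("KMO errors on an identity correlation structure", {
  d <- as.data.frame(exact_parallel_items(40, 4, r = 0, seed = 7))
  names(d) <- paste0("v", 1:4)
  expect_error(kmo(d), "no common variance")
})

test_that("Bartlett sphericity matches its closed form", {
  # exactly orthonormal columns: R = I, chi2 = 0, p-value 1
  x <- as.data.frame(exact_parallel_items(50, 4, r = 0, seed = 3))
  b <- bartlett_sphericity(x)
  expect_equal(b$chisq, 0, tolerance = 1e-8)
  expect_equal(b$p.value, 1)
  expect_equal(b$df, 6)

  # direct formula on random data
  set.seed(9)
  y <- as.data.frame(matrix(rnorm(200 * 9), 200))
  names(y) <- paste0("v", 1:9)
  b <- bartlett_sphericity(y)
  expect_equal(b$df, 36)
  R <- cor(as.matrix(y))
  expect_equal(b$chisq, -(200 - 1 - (2 * 9 + 5) / 6) * log(det(R)),
               tolerance = 1e-8)
})

test_that("EFA retains one component for single-factor data", {
  set.seed(14)
  n <- 3000
  f <- rnorm(n)
  d <- as.data.frame(sapply(1:9, function(i)
    0.8 * f + sqrt(1 - 0.64) * rnorm(n)))
  names(d) <- paste0("v", 1:9)
  sol <- efa_pca_varimax(d)
  expect_equal(ncol(sol$loadings), 1)
  expect_true(all(sol$loadings > 0))
})

test_that("EFA satisfies eigenvalue-sum and communality invariants", {
  d <- generate_responses(ground_truth(tiny_instrument()), 400, seed = 6)
  items <- setdiff(names(d), c("respondent", "BEH-1", "BEH-2"))
  sol <- efa_pca_varimax(d, items)
  expect_equal(sum(sol$eigenvalues), length(items), tolerance = 1e-10)
  # communalities invariant under rotation: recompute from unrotated loadings
  R <- cor(as.matrix(d[, items]))
  e <- eigen(R, symmetric = TRUE)
  keep <- e$values > 1
  L0 <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]), sum(keep))
  expect_equal(unname(sol$communalities), rowSums(L0^2), tolerance = 1e-8)
})

test_that("varimax rotation matches the stats reference implementation", {
  # three moderately correlated factors, three items each
  set.seed(17)
  n <- 1000
  F3 <- matrix(rnorm(n * 3), n) %*% chol(0.3 + diag(0.7, 3))
  x <- sapply(1:9, function(i)
    0.8 * F3[, (i - 1) %/% 3 + 1] + 0.6 * rnorm(n))
  colnames(x) <- paste0("v", 1:9)
  sol <- efa_pca_varimax(as.data.frame(x))
  expect_equal(ncol(sol$loadings), 3)

  R <- cor(x)
  e <- eigen(R, symmetric = TRUE)
  L0 <- e$vectors[, 1:3] %*% diag(sqrt(e$values[1:3]))
  ref <- unclass(stats::varimax(L0, normalize = TRUE, eps = 1e-15)$loadings)
  aligned <- align_loadings(unname(sol$loadings), ref)
  expect_lt(max(abs(aligned - ref)), 1e-6)
})

test_that("retention rules flag cross-loadings and dissolve small factors", {
  # the (0.607, 0.61) pattern: primary passes but the cross-loading kills it
  L <- matrix(c(0.61,  0.8, 0.8, 0.8,
                0.607, 0.1, 0.1, 0.1), 4, 2,
              dimnames = list(c("ks3", "a1", "a2", "a3"), NULL))
  it <- setNames(rep(0.7, 4), rownames(L))
  scr <- apply_item_retention_rules(list(loadings = L), it)
  expect_equal(scr$reason[scr$item == "ks3"], "cross_loading")
  expect_true(all(scr$retained[scr$item != "ks3"]))

  # a factor left with two items is dissolved
  L <- rbind(matrix(c(rep(0.8, 3), rep(0.05, 3)), 3, 2),
             matrix(c(rep(0.05, 2), rep(0.8, 2)), 2, 2))
  rownames(L) <- c("a1", "a2", "a3", "b1", "b2")
  it <- setNames(rep(0.7, 5), rownames(L))
  scr <- apply_item_retention_rules(list(loadings = L), it)
  expect_equal(scr$reason[scr$item %in% c("b1", "b2")],
               rep("orphan_factor", 2))

  # clean simple structure: nothing eliminated
  L <- rbind(matrix(c(rep(0.9, 3), rep(0, 3)), 3, 2),
             matrix(c(rep(0, 3), rep(0.9, 3)), 3, 2))
  rownames(L) <- paste0("i", 1:6)
  it <- setNames(rep(0.8, 6), rownames(L))
  scr <- apply_item_retention_rules(list(loadings = L), it)
  expect_true(all(scr$retained))
})

test_that("AVE and CR recover printed reliability values from loadings", {
  expect_equal(round(ave(c(0.821, 0.802, 0.738)), 3), 0.621)
  expect_equal(round(composite_reliability(c(0.821, 0.802, 0.738)), 3), 0.830)
  expect_equal(round(ave(c(0.849, 0.888, 0.886)), 3), 0.765)
  expect_equal(round(composite_reliability(c(0.859, 0.817, 0.816)), 3), 0.870)
  expect_equal(ave(c(1, 1)), 1)
  expect_equal(composite_reliability(c(1, 1, 1)), 1)
  expect_error(ave(numeric(0)), "empty")
  expect_error(composite_reliability(numeric(0)), "empty")
})

test_that("Fornell-Larcker comparison is strict at the boundary", {
  expect_equal(round(sqrt(ave(c(0.821, 0.802, 0.738))), 3), 0.788)
  fc <- matrix(c(1, 0.8, 0.8, 1), 2, dimnames = list(c("A", "B"), c("A", "B")))
  # sqrt(0.64) = 0.8 equals the correlation: strict comparison fails
  res <- fornell_larcker(c(A = 0.64, B = 1), fc)
  expect_false(res$discriminant[["A"]])
  expect_true(res$discriminant[["B"]])   # sqrt(1) = 1 > 0.8
  expect_error(fornell_larcker(c(A = 0.5), fc), "missing")
})

test_that("split_half partitions the sample by order and reproducibly at random", {
  d <- generate_responses(ground_truth(tiny_instrument()), 101, seed = 1)
  h1 <- split_half(d, "first"); h2 <- split_half(d, "second")
  expect_equal(nrow(h1), 50)
  expect_equal(nrow(h2), 51)
  expect_equal(sort(c(h1$respondent, h2$respondent)), d$respondent)
  r1 <- split_half(d, "first", random = TRUE, seed = 3)
  r1b <- split_half(d, "first", random = TRUE, seed = 3)
  expect_identical(r1, r1b)
})
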