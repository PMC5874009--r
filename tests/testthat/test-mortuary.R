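test_that("Jaccard distances follow the set definition with the empty convention", {
  m <- rbind(a = c(1, 1, 0, 0), b = c(0, 1, 1, 0), c = c(1, 1, 0, 0),
             d = c(0, 0, 0, 1), e = c(0, 0, 0, 0), f = c(0, 0, 0, 0))
  d <- jaccard_matrix(m)
  expect_equal(d["a", "c"], 0)        # identical profiles
  expect_equal(d["a", "d"], 1)        # disjoint non-empty profiles
  expect_equal(d["a", "b"], 2 / 3)    # {1,2} vs {2,3}
  expect_equal(d["e", "f"], 0)        # both empty: identity by convention
  expect_equal(d["a", "e"], 1)
  expect_true(isSymmetric(d))
  expect_equal(diag(d), setNames(rep(0, 6), rownames(m)))
})

test_that("Jaccard distances satisfy the triangle inequality and match vegan", {
  skip_if_not_installed("vegan")
  set.seed(31)
  for (rep in 1:5) {
    m <- toy_binary(12, 20, prob = 0.35, seed = 31 + rep)
    m <- m[rowSums(m) > 0, ]  # vegan's jaccard is undefined on empty rows
    d <- jaccard_matrix(m)
    ref <- as.matrix(vegan::vegdist(m, method = "jaccard", binary = TRUE))
    expect_equal(d, ref, tolerance = 1e-12, ignore_attr = TRUE)
    n <- nrow(d)
    for (i in 1:n) for (j in 1:n) for (k in 1:n) {
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
    }
  }
})

test_that("complete linkage agglomerates farthest-neighbour with monotone heights", {
  # two tight clusters at distance 1 merge last, at exactly 1
  m <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  m["A", "B"] <- m["B", "A"] <- 0
  m["C", "D"] <- m["D", "C"] <- 0
  diag(m) <- 0
  hc <- complete_linkage(m)
  expect_equal(max(hc$height), 1)
  expect_equal(sort(cutree(hc, 2)), sort(c(A = 1, B = 1, C = 2, D = 2)))

  # hand agglomeration: AB at 2, then C joins at max(5, 6) = 6, D at max(9,10,3)=10
  mm <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  mm["A", "B"] <- 2; mm["A", "C"] <- 5; mm["B", "C"] <- 6
  mm["A", "D"] <- 9; mm["B", "D"] <- 10; mm["C", "D"] <- 3
  mm <- mm + t(mm)
  hc2 <- complete_linkage(mm)
  expect_equal(hc2$height, c(2, 3, 10))
  expect_true(all(diff(hc2$height) >= 0))
  expect_error(complete_linkage(matrix(0, 1, 1)), "at least two")
})

test_that("goods-by-group chi-square reproduces hand-computed tables", {
  # perfectly sex-segregated goods: chi2 = N = 20, df = 1
  m <- rbind(matrix(c(1, 0), 10, 2, byrow = TRUE),
             matrix(c(0, 1), 10, 2, byrow = TRUE))
  colnames(m) <- c("sword", "mirror")
  rownames(m) <- paste0("i", 1:20)
  res <- goods_by_group_chisq(m, rep(c("m", "f"), each = 10))
  expect_equal(res$statistic, 20)
  expect_equal(res$df, 1)
  expect_lt(res$p_value, 0.001)

  # identical group profiles: no association
  m2 <- rbind(a = c(1, 1, 0), b = c(1, 1, 0), c = c(1, 1, 0), d = c(1, 1, 0))
  colnames(m2) <- c("x", "y", "z")
  res2 <- suppressWarnings(goods_by_group_chisq(m2, c("g1", "g1", "g2", "g2")))
  expect_equal(res2$statistic, 0)
  expect_equal(res2$dropped, "z")
  # df reflects the dropped all-zero good: (2-1)*(2-1)
  expect_equal(res2$df, 1)
})

test_that("AMOVA attains 1 on perfectly separated groups", {
  d <- matrix(1, 4, 4); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0
  d[3, 4] <- d[4, 3] <- 0
  rownames(d) <- colnames(d) <- letters[1:4]
  res <- amova(d, c("g1", "g1", "g2", "g2"), n_permutations = 99, seed = 1)
  expect_equal(res$phi_st, 1)
  expect_equal(res$ss_within, 0)
  # the p-value floor is 1/(B+1); 4 individuals admit few distinct partitions
  expect_lte(res$permutation_p, 0.5)
})

test_that("AMOVA equals the brute-force decomposition on random instances", {
  set.seed(202)
  for (rep in 1:100) {
    n <- sample(4:12, 1)
    pts <- matrix(rnorm(n * 3), n)
    d <- as.matrix(dist(pts))
    g <- sample(paste0("g", 1:sample(2:3, 1)), n, replace = TRUE)
    while (length(unique(g)) < 2) g <- sample(paste0("g", 1:2), n, replace = TRUE)
    res <- amova(d, g, n_permutations = 0)
    expect_lt(abs(res$phi_st - brute_amova_phi(d, g)), 1e-12)
  }
})

test_that("AMOVA is calibrated under the null", {
  set.seed(303)
  phis <- numeric(40)
  ps <- numeric(40)
  for (i in seq_len(40)) {
    m <- toy_binary(16, 25, prob = 0.3, seed = 500 + i)
    d <- jaccard_matrix(m)
    g <- sample(rep(c("x", "y"), 8))
    res <- amova(d, g, n_permutations = 99)
    phis[i] <- res$phi_st
    ps[i] <- res$permutation_p
  }
  expect_lt(abs(mean(phis)), 0.05)       # centred on zero
  expect_gt(mean(ps > 0.05), 0.6)        # mostly non-significant
  expect_warning(
    amova(jaccard_matrix(toy_binary(5, 10)), c("a", "a", "a", "a", "b"),
          n_permutations = 9),
    "size 1"
  )
})

test_that("correspondence analysis decomposes inertia as chi-square / N", {
  # independence: a rank-1 table has zero inertia
  indep <- outer(c(2, 3, 5), c(1, 4, 2))
  ca0 <- correspondence_analysis(indep)
  expect_equal(ca0$total_inertia, 0, tolerance = 1e-12)

  # diagonal 2x2: one axis carrying inertia chi2/N = 1
  ca1 <- correspondence_analysis(rbind(c(10, 0), c(0, 10)))
  expect_equal(length(ca1$inertia), 1)
  expect_equal(ca1$total_inertia, 1, tolerance = 1e-12)
  expect_equal(ca1$share, 1)

  # block-diagonal: row blocks separate by sign on axis 1
  block <- rbind(c(8, 9, 0, 0), c(9, 7, 0, 0), c(0, 0, 8, 9), c(0, 0, 7, 9))
  ca2 <- correspondence_analysis(block)
  s <- sign(ca2$row_coords[, 1])
  expect_equal(s[1], s[2])
  expect_equal(s[3], s[4])
  expect_true(s[1] != s[3])
  expect_warning(correspondence_analysis(rbind(c(1, 0), c(0, 0))), "all-zero")
})

test_that("correspondence analysis matches an established implementation", {
  skip_if_not_installed("MASS")
  set.seed(8)
  tab <- matrix(rpois(20, 6) + 1, 4, 5)
  ours <- correspondence_analysis(tab, dims = 2)
  ref <- MASS::corresp(tab, nf = 2)
  # principal coordinates = standard scores scaled by the singular values
  ref_rows <- ref$rscore %*% diag(ref$cor)
  for (ax in 1:2) {
    ratio <- ours$row_coords[, ax] / ref_rows[, ax]
    expect_equal(abs(ratio), rep(1, 4), tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("Random Forest recognises a perfect predictor and honours the seed", {
  set.seed(61)
  n <- 40
  y <- rep(c("m", "f"), each = n / 2)
  m <- cbind(signal = as.integer(y == "m"),
             toy_binary(n, 15, prob = 0.5, seed = 62))
  rf <- random_forest_importance(m, y, n_trees = 200, seed = 7)
  expect_equal(names(which.max(rf$importance)), "signal")
  expect_lte(rf$oob_error, 0.05)
  expect_equal(sum(rf$confusion), n)

  # same seed, same forest
  rf2 <- random_forest_importance(m, y, n_trees = 200, seed = 7)
  expect_identical(rf$importance, rf2$importance)
  expect_identical(rf$oob_error, rf2$oob_error)

  # permuting the feature columns keeps the perfect predictor on top
  perm <- sample(ncol(m))
  rf3 <- random_forest_importance(m[, perm], y, n_trees = 200, seed = 7)
  expect_equal(names(which.max(rf3$importance)), "signal")

  expect_error(random_forest_importance(m, c("solo", y[-1]), seed = 1),
               "single member")
})

test_that("Random Forest is uninformative on label-independent features", {
  set.seed(63)
  n <- 40
  m <- toy_binary(n, 12, prob = 0.5, seed = 64)
  y <- rep(c("m", "f"), each = n / 2)  # unrelated to m by construction
  rf <- random_forest_importance(m, y, n_trees = 300, seed = 9)
  # OOB error near the majority-class error of 0.5
  expect_gt(rf$oob_error, 0.25)
})

test_that("stepwise VIF removes collinear variables in the documented order", {
  set.seed(21)
  m <- toy_binary(40, 4, prob = 0.5, seed = 22)
  dup <- cbind(m, dup = m[, 1])
  res <- vif_stepwise(dup)
  expect_true(any(c("g01", "dup") %in% res$removed$variable))
  expect_equal(length(res$retained), 4)
  expect_true(is.infinite(res$removed$vif[1]))

  # mutually uncorrelated columns all survive with VIF 1
  ortho <- cbind(a = rep(c(1, 0, 1, 0), 10), b = rep(c(1, 1, 0, 0), 10),
                 c = rep(c(1, 0, 0, 1), 10))
  res2 <- vif_stepwise(ortho)
  expect_setequal(res2$retained, c("a", "b", "c"))
  expect_true(all(res2$vif < 1.01))

  # x3 = x1 OR x2 with a rare x2: x3 is nearly linear in x1, x2 and is
  # removed at the default threshold
  set.seed(23)
  x1 <- rbinom(200, 1, 0.5); x2 <- rbinom(200, 1, 0.05)
  x3 <- as.integer(x1 | x2)
  r2 <- summary(lm(x3 ~ x1 + x2))$r.squared
  expect_gt(1 / (1 - r2), 5)  # direct least-squares check of the construction
  res3 <- vif_stepwise(cbind(x1 = x1, x2 = x2, x3 = x3,
                             noise = rbinom(200, 1, 0.5)))
  expect_true("x3" %in% res3$removed$variable)
  expect_true(all(c("x1", "x2") %in% res3$retained) ||
                length(res3$retained) >= 2)

  # constant columns are removed up front
  res4 <- vif_stepwise(cbind(m, const = 1))
  expect_true("const" %in% res4$removed$variable)
})
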