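test_that("angular transform matches direct evaluation and is monotone", {
  # frozen oracle value (direct arcsine evaluation); at k = 0 both the
  # double-arcsine and the mean-arcsine variant reduce to pi/2 - asin(sqrt(1/11))
  expect_equal(ft_theta(0, 10), 1.2645190, tolerance = 1e-6)
  expect_equal(ft_theta(0, 10, variant = "asin-mean"), 1.2645190, tolerance = 1e-6)
  for (variant in c("freeman-tukey", "asin-mean", "anscombe")) {
    for (n in c(1, 7, 31)) {
      th <- ft_theta(0:n, n, variant = variant)
      expect_true(all(diff(th) < 0), info = paste(variant, n))
      expect_equal(th, brute_theta(0:n, n, variant), tolerance = 1e-12)
    }
  }
  # saturated frequency at large n approaches -pi/2
  expect_equal(ft_theta(5000, 5000), -pi / 2, tolerance = 0.05)
  expect_error(ft_theta(5, 4), "k <= n")
})

test_that("counts are recovered from rounded percentages", {
  expect_identical(counts_from_percentages(11.1, 18), 2L)
  expect_identical(counts_from_percentages(0, 31), 0L)
  expect_identical(counts_from_percentages(85.7, 7), 6L)
  expect_identical(counts_from_percentages(100, 7), 7L)
  expect_warning(counts_from_percentages(40, 18), "round-trip")
})

test_that("pairwise MMD agrees with the brute-force oracle on random inputs", {
  set.seed(101)
  for (rep in 1:60) {
    r <- sample(1:12, 1)
    nA <- sample(1:40, r, replace = TRUE)
    nB <- sample(1:40, r, replace = TRUE)
    kA <- vapply(nA, function(n) sample(0:n, 1), 0L)
    kB <- vapply(nB, function(n) sample(0:n, 1), 0L)
    variant <- sample(c("freeman-tukey", "asin-mean", "anscombe"), 1)
    got <- mmd_pair(kA, nA, kB, nB, variant = variant)
    want <- brute_mmd(kA, nA, kB, nB, variant)
    expect_equal(got$mmd, want$mmd, tolerance = 1e-12)
    expect_equal(got$sd, want$sd, tolerance = 1e-12)
  }
})

test_that("MMD is symmetric, its SD frequency-free, and diluted by identical traits", {
  kA <- c(2, 5, 0); nA <- c(10, 12, 9)
  kB <- c(7, 1, 3); nB <- c(15, 9, 11)
  ab <- mmd_pair(kA, nA, kB, nB)
  ba <- mmd_pair(kB, nB, kA, nA)
  expect_equal(ab$mmd, ba$mmd)
  expect_equal(ab$sd, ba$sd)
  # SD depends on sample sizes only
  other <- mmd_pair(c(9, 0, 5), nA, c(1, 8, 2), nB)
  expect_equal(ab$sd, other$sd)
  # identical frequencies with r = 1 and n = 10 each: pure correction term
  self <- mmd_pair(4, 10, 4, 10)
  expect_equal(self$mmd, -(1 / 10.5 + 1 / 10.5))
  expect_false(self$significant)
  # appending a trait identical in both groups pulls MMD toward the correction
  plus <- mmd_pair(c(kA, 6), c(nA, 20), c(kB, 6), c(nB, 20))
  expect_lt(plus$mmd, ab$mmd)
})

test_that("matrix assembly flags significance at MMD > 2 SD with zero diagonal", {
  freq <- load_frequencies()
  mm <- mmd_matrix(freq)
  expect_equal(diag(mm$mmd), setNames(rep(0, 19), mm$groups))
  expect_true(isSymmetric(mm$mmd))
  expect_equal(mm$significant[lower.tri(mm$significant)],
               (mm$mmd > 2 * mm$sd)[lower.tri(mm$mmd)])
  expect_error(mmd_matrix(freq[freq$group == "MV", ]), "two groups")
  expect_error(mmd_matrix(freq, traits = "No such trait"), "lacks trait")
})

test_that("two identically-distributed samples are rarely called divergent", {
  # significance calibration: equal underlying frequencies, many replicates
  set.seed(77)
  p <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  n <- 25
  hits <- 0
  reps <- 1000
  for (i in seq_len(reps)) {
    kA <- rbinom(5, n, p)
    kB <- rbinom(5, n, p)
    pair <- mmd_pair(kA, rep(n, 5), kB, rep(n, 5))
    if (pair$significant) hits <- hits + 1
  }
  expect_lte(hits / reps, 0.05)
})

test_that("correlation screening removes duplicated and keeps independent traits", {
  set.seed(5)
  m <- toy_binary(40, 6)
  scr <- correlation_screen(m)
  expect_setequal(scr$retained, colnames(m))  # independent noise survives

  m2 <- cbind(m, dup = m[, 1])
  scr2 <- correlation_screen(m2)
  expect_true("dup" %in% scr2$removed$trait || "g01" %in% scr2$removed$trait)
  expect_equal(length(scr2$retained), 6)
  expect_equal(scr2$r["g01", "dup"], 1)

  # low-n traits are excluded before screening
  m3 <- m
  m3[1:37, 2] <- NA
  scr3 <- correlation_screen(m3)
  expect_true("g02" %in% scr3$removed$trait)
  expect_match(scr3$removed$reason[scr3$removed$trait == "g02"], "fewer than")
})

test_that("phi equals signed sqrt(chi-square / N) on a 2x2 table", {
  # (10,0;0,10): chi2 = 20, N = 20, phi = 1
  x <- rep(c(1, 0), each = 10)
  y <- rep(c(1, 0), each = 10)
  scr <- correlation_screen(cbind(a = x, b = y, c = rep(0:1, 10)))
  expect_equal(scr$r["a", "b"], 1)
  chi <- suppressWarnings(chisq.test(table(x, y), correct = FALSE))
  expect_equal(abs(scr$r["a", "b"]), sqrt(unname(chi$statistic) / 20))
})

test_that("dichotomization applies breakpoints and prefers the left side", {
  defs <- data.frame(trait = c("Carabelli's trait UM1", "Shoveling UI1"),
                     breakpoint = c("ASU 2-7", "3+"), stringsAsFactors = FALSE)
  scores <- data.frame(
    individual_id = c("A", "A", "B", "B", "C"),
    trait = c("Carabelli's trait UM1", "Shoveling UI1",
              "Carabelli's trait UM1", "Carabelli's trait UM1", "Shoveling UI1"),
    side = c("L", "L", "L", "R", "L"),
    grade = c(3, 0, NA, 5, NA), stringsAsFactors = FALSE
  )
  out <- dichotomize(scores, defs)
  expect_true(out$present[out$individual_id == "A" &
                          out$trait == "Carabelli's trait UM1"])
  expect_false(out$present[out$individual_id == "A" & out$trait == "Shoveling UI1"])
  # left missing: the antimere substitutes
  expect_true(out$present[out$individual_id == "B"])
  # both missing stays missing
  expect_true(is.na(out$present[out$individual_id == "C"]))
  expect_error(dichotomize(data.frame(individual_id = "X", trait = "Shoveling UI1",
                                      side = "L", grade = 12),
                           defs), "outside the trait scale")
  expect_error(dichotomize(data.frame(individual_id = "X", trait = "Mystery",
                                      side = "L", grade = 1), defs),
               "no breakpoint definition")
})

test_that("group frequencies count one observation per individual", {
  presence <- data.frame(
    individual_id = rep(c("A", "B", "C", "D"), each = 2),
    trait = rep(c("t1", "t2"), 4),
    present = c(TRUE, FALSE, TRUE, NA, FALSE, TRUE, NA, TRUE),
    stringsAsFactors = FALSE
  )
  groups <- c(A = "g1", B = "g1", C = "g2", D = "g2")
  f <- group_frequencies(presence, groups)
  expect_equal(f$k[f$group == "g1" & f$trait == "t1"], 2L)
  expect_equal(f$n[f$group == "g1" & f$trait == "t2"], 1L)
  expect_equal(f$n[f$group == "g2" & f$trait == "t1"], 1L)
})

test_that("classical MDS reproduces Euclidean configurations", {
  set.seed(9)
  pts <- matrix(rnorm(14), 7, 2)
  d <- as.matrix(dist(pts))
  fit <- classical_mds(d, dims = 2)
  expect_equal(as.matrix(dist(fit$points)), d, tolerance = 1e-9,
               ignore_attr = TRUE)
  # three equidistant points embed as an equilateral triangle
  eq <- matrix(1, 3, 3); diag(eq) <- 0
  tri <- classical_mds(eq, dims = 2)
  dd <- dist(tri$points)
  expect_equal(max(dd) - min(dd), 0, tolerance = 1e-9)
  # negative entries are clamped, excess dims reduced with a warning
  neg <- eq; neg[1, 2] <- neg[2, 1] <- -0.5
  expect_silent(classical_mds(neg, dims = 1))
  expect_warning(classical_mds(eq, dims = 3), "positive eigenvalue")
})

test_that("Ward clustering recovers ultrametric structure", {
  m <- matrix(8, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  m["A", "B"] <- m["B", "A"] <- 1
  m["C", "D"] <- m["D", "C"] <- 2
  diag(m) <- 0
  hc <- ward_dendrogram(m)
  expect_equal(sort(cutree(hc, 2)), sort(c(A = 1, B = 1, C = 2, D = 2)))
  expect_error(ward_dendrogram(matrix(0, 1, 1)), "at least two")
})
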