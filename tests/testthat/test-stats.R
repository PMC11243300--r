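test_that("all-positive differences give the exact two-sided p 2/2^n", {
  r <- signed_rank_test(1:10)
  expect_equal(r$p, 2 / 1024, tolerance = 1e-12)
  expect_equal(r$statistic, sum(1:10))
  expect_false(r$degenerate)
})

test_that("exact p agrees with brute-force enumeration for n <= 12", {
  set.seed(42)
  for (k in 1:8) {
    n <- sample(6:12, 1)
    d <- round(rnorm(n), 2)
    d[d == 0] <- 0.01
    r <- signed_rank_test(d)
    expect_equal(r$p, signed_rank_exact_bruteforce(d), tolerance = 1e-12,
                 label = sprintf("seeded case %d", k))
  }
})

test_that("exact p matches stats::wilcox.test when no ties or zeros occur", {
  set.seed(9)
  d <- rnorm(15)
  r <- signed_rank_test(d)
  w <- wilcox.test(d, exact = TRUE)
  expect_equal(r$p, w$p.value, tolerance = 1e-12)
})

test_that("degenerate inputs are flagged instead of tested", {
  expect_true(signed_rank_test(c(0.3))$degenerate)
  expect_true(is.na(signed_rank_test(c(0, 0, 0))$p))
  expect_true(signed_rank_test(c(1, -2, 3, -4))$degenerate)  # n < 5 nonzero
})

test_that("Pratt handling ranks zeros before dropping them", {
  d <- c(0, 1, 2, 3, 4, 5)
  r_pratt <- signed_rank_test(d, zeros = "pratt")
  r_drop <- signed_rank_test(d, zeros = "wilcoxon")
  # with the zero occupying rank 1, Pratt ranks are 2..6; dropped ranks 1..5
  expect_equal(r_pratt$statistic, sum(2:6))
  expect_equal(r_drop$statistic, sum(1:5))
})

test_that("spearman matrix: monotone pairs, sign flips, constant flags", {
  x <- data.frame(a = 1:20, b = rnorm(20), c = rep(1, 20))
  y <- data.frame(d1 = (1:20)^3, d2 = -(1:20))
  r <- spearman_matrix(x, y)
  expect_equal(r$rho["a", "d1"], 1)
  expect_equal(r$rho["a", "d2"], -1)
  expect_true(all(is.na(r$rho["c", ])))
  expect_true(any(grepl("^c:", r$undefined)))
})

test_that("independent samples rarely show large rank correlation", {
  set.seed(5)
  hits <- 0
  for (k in 1:200) {
    x <- runif(100); y <- runif(100)
    if (abs(cor(x, y, method = "spearman")) >= 0.3) hits <- hits + 1
  }
  expect_lt(hits / 200, 0.02)
})

test_that("cut-height sensitivity reports exactly the engineered flip", {
  set.seed(1)
  n <- 30
  base <- abs(rnorm(n)) + 0.5
  mk <- function(shift) data.frame(
    case = 1:n, indicator = "IND", rigid = base,
    compliant = base + shift)
  # strong effect at 8.0, none at 8.1 (shuffled signs)
  t8 <- mk(0.3); t8$cut_height <- 8
  t79 <- mk(0.3); t79$cut_height <- 7.9
  flip_shift <- sample(c(-1, 1), n, replace = TRUE) * 0.01
  t81 <- data.frame(case = 1:n, indicator = "IND", rigid = base,
                    compliant = base + flip_shift, cut_height = 8.1)
  tab <- rbind(t8, t79, t81)
  res <- sensitivity_rerun(tab)
  expect_equal(nrow(res$report), 3)
  expect_equal(res$flips$cut_height, 8.1)
  # identical tables at all heights: zero flips
  tab2 <- rbind(t8, transform(t8, cut_height = 7.9),
                transform(t8, cut_height = 8.1))
  expect_equal(nrow(sensitivity_rerun(tab2)$flips), 0)
})
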