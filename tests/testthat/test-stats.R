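test_that("the clinical fixture loads with the printed labels and values", {
  tab <- read_table1()
  expect_equal(nrow(tab), 24L)
  expect_equal(sum(tab$motor_decline == "yes"), 7L)
  expect_equal(tab$edema_volume_mm3[tab$case == 19], 17875)
  expect_equal(min(tab$ltd_mm), 2.3)
  expect_true(all(tab$edema_volume_mm3 > 0))
})

test_that("AUC equals the trapezoidal ROC integral on random data", {
  set.seed(50)
  for (i in 1:50) {
    n <- sample(10:40, 1)
    vals <- sample(round(rnorm(n), sample(0:2, 1)))  # induce ties sometimes
    labs <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(labs)) < 2) next
    r <- roc(vals, labs, larger = "b")
    expect_equal(r$auc, oracle_auc_trapezoid(vals, labs, "b"),
                 tolerance = 1e-12)
  }
})

test_that("AUC limits and direction flip behave canonically", {
  r <- roc(c(1, 2, 3, 10, 11, 12), rep(c("lo", "hi"), each = 3), larger = "hi")
  expect_equal(r$auc, 1)
  r2 <- roc(c(1, 2, 3, 1, 2, 3), rep(c("lo", "hi"), each = 3), larger = "hi")
  expect_equal(r2$auc, 0.5)
  set.seed(51)
  vals <- rnorm(30)  # continuous: no ties
  labs <- rep(c("x", "y"), 15)
  expect_equal(roc(vals, labs, larger = "y")$auc,
               1 - roc(vals, labs, larger = "x")$auc)
  expect_error(roc(1:5, rep("a", 5), larger = "a"), "parameter error")
})

test_that("Youden cutoff equals an exhaustive threshold scan", {
  set.seed(52)
  for (i in 1:50) {
    n <- sample(8:30, 1)
    vals <- round(rnorm(n), 1)
    labs <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(labs)) < 2) next
    r <- roc(vals, labs, larger = "b")
    expect_equal(youden(r)$j, oracle_youden_scan(vals, labs, "b"),
                 tolerance = 1e-12)
  }
  # perfect separation and useless classifier
  expect_equal(youden(roc(c(1, 2, 8, 9), c("a", "a", "b", "b"), "b"))$j, 1)
  expect_equal(youden(roc(c(1, 2, 1, 2), c("a", "a", "b", "b"), "b"))$j, 0)
})

test_that("AUC cross-checks against an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(53)
  vals <- rnorm(40)
  labs <- sample(c(0, 1), 40, replace = TRUE)
  r <- roc(vals, labs, larger = 1)
  p <- pROC::roc(labs, vals, direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(p)), tolerance = 1e-12)
})

test_that("signed-rank W and exact p match hand ranking and enumeration", {
  x <- c(1, -2, 3, -4, 5); y <- rep(0, 5)
  w <- wilcoxon_signed_rank(x, y)
  expect_equal(w$w, 6)                       # negative ranks 2 + 4
  expect_equal(w$p, oracle_wilcoxon_enum(x, y))
  # constant shift: all differences one sign
  set.seed(54)
  a <- rnorm(8); b <- a - 1
  expect_equal(wilcoxon_signed_rank(b, a)$w, 0)
  # n = 10 exact p against full enumeration, with and without ties
  for (i in 1:5) {
    x <- round(rnorm(10), 1); y <- round(rnorm(10), 1)
    if (any(x == y)) x <- x + 0.05
    w <- wilcoxon_signed_rank(x, y)
    expect_equal(w$p, oracle_wilcoxon_enum(x, y), tolerance = 1e-12)
    expect_gt(w$p, 0); expect_lte(w$p, 1)
    # symmetry under swapping the pair
    expect_equal(wilcoxon_signed_rank(y, x)$p, w$p)
  }
})

test_that("tie-free exact p agrees with the base signed-rank test", {
  set.seed(55)
  x <- rnorm(10); y <- rnorm(10)
  ours <- wilcoxon_signed_rank(x, y)
  base <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(ours$p, base$p.value, tolerance = 1e-12)
})

test_that("degenerate signed-rank inputs error", {
  expect_error(wilcoxon_signed_rank(1:6, 1:6), "degenerate")
  expect_error(wilcoxon_signed_rank(c(1, 2, 3, 4), c(0, 0, 0, 0)),
               "fewer than 5")
})

test_that("large-sample signed-rank p uses a tie-corrected normal tail", {
  set.seed(56)
  x <- rnorm(30); y <- rnorm(30)
  w <- wilcoxon_signed_rank(x, y)
  expect_equal(w$method, "normal-approximation")
  base <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                             correct = TRUE)
  expect_equal(w$p, base$p.value, tolerance = 1e-10)
})

test_that("the barycentric embedding hits its vertices and centroid", {
  expect_equal(unname(ternary_coordinates(1, 0, 0)), matrix(c(0, 0), 1))
  expect_equal(unname(ternary_coordinates(0, 1, 0)), matrix(c(1, 0), 1))
  expect_equal(unname(ternary_coordinates(0, 0, 1)),
               matrix(c(0.5, sqrt(3) / 2), 1))
  expect_equal(unname(ternary_coordinates(1 / 3, 1 / 3, 1 / 3)),
               matrix(c(0.5, sqrt(3) / 6), 1), tolerance = 1e-12)
  expect_error(ternary_coordinates(0.5, 0.2, 0.2), "validation error")
})
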