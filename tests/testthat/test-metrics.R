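test_that("c_index matches brute-force pair counting, including ties", {
  expect_equal(c_index(c(1, 2, 2, 3), c(0, 0, 1, 1)), 0.875)
  expect_equal(c_index(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1.0)

  set.seed(41)
  for (rep in 1:30) {
    n <- sample(4:100, 1)
    scores <- sample(round(rnorm(n), sample(0:1, 1)))  # forces ties
    outcomes <- rbinom(n, 1, 0.4)
    if (length(unique(outcomes)) < 2) next
    expect_equal(c_index(scores, outcomes), brute_cindex(scores, outcomes))
  }
})

test_that("c_index is rank-based and class-symmetric", {
  set.seed(7)
  scores <- rnorm(60); outcomes <- rbinom(60, 1, 0.5)
  c0 <- c_index(scores, outcomes)
  # invariant under strictly increasing transforms
  expect_equal(c_index(exp(scores), outcomes), c0)
  expect_equal(c_index(rank(scores), outcomes), c0)
  # negating scores flips discrimination
  expect_equal(c_index(-scores, outcomes), 1 - c0)
  expect_error(c_index(scores, rep(1, 60)), "both classes")
})

test_that("DeLong SE matches pROC and the Monte-Carlo sampling SD", {
  skip_if_not_installed("pROC")
  set.seed(11)
  scores <- rnorm(80); outcomes <- rbinom(80, 1, 0.4)
  r <- pROC::roc(outcomes, scores, quiet = TRUE, direction = "<")
  expect_equal(c_index(scores, outcomes), as.numeric(pROC::auc(r)))
  expect_equal(c_index_se(scores, outcomes), sqrt(pROC::var(r)),
               tolerance = 1e-10)

  # degenerate scores: chance discrimination, no pair variability
  expect_equal(c_index(rep(1, 20), rep(0:1, 10)), 0.5)
  expect_equal(c_index_se(rep(1, 20), rep(0:1, 10)), 0)

  # analytic SE tracks the empirical SD of C under the null...
  set.seed(12)
  draw <- function(n) {
    s <- runif(n); y <- rbinom(n, 1, 0.5)
    c(c = c_index(s, y), se = c_index_se(s, y))
  }
  r200 <- replicate(400, draw(200))
  expect_equal(mean(r200["se", ]) / sd(r200["c", ]), 1, tolerance = 0.15)
  # ...and shrinks by ~sqrt(2) when n doubles
  r400 <- replicate(400, draw(400))
  expect_equal(mean(r200["se", ]) / mean(r400["se", ]), sqrt(2),
               tolerance = 0.1)
})

test_that("roc_points has proper endpoints and integrates to the C-index", {
  perfect <- roc_points(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(perfect[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(perfect[nrow(perfect), ]), c(fpr = 1, tpr = 1))
  expect_true(any(perfect$fpr == 0 & perfect$tpr == 1))

  flat <- roc_points(rep(2, 10), rep(0:1, 5))
  expect_equal(nrow(flat), 2)
  expect_equal(trapezoid_area(flat$fpr, flat$tpr), 0.5)

  set.seed(13)
  for (rep in 1:20) {
    n <- sample(10:120, 1)
    scores <- round(rnorm(n), 1)          # plenty of ties
    outcomes <- rbinom(n, 1, 0.5)
    if (length(unique(outcomes)) < 2) next
    pts <- roc_points(scores, outcomes)
    expect_true(all(diff(pts$fpr) >= 0), info = "fpr nondecreasing")
    expect_true(all(diff(pts$tpr) >= 0), info = "tpr nondecreasing")
    expect_equal(trapezoid_area(pts$fpr, pts$tpr),
                 c_index(scores, outcomes))
  }
})

test_that("calibration deciles partition the sample lowest-first", {
  tab <- calibration_deciles(seq(0.05, 0.95, length.out = 10),
                             rep(0:1, 5))
  expect_equal(tab$count, rep(1L, 10))
  expect_equal(sum(tab$count), 10)

  set.seed(14)
  p <- runif(23); y <- rbinom(23, 1, p)
  tab23 <- calibration_deciles(p, y)
  expect_equal(tab23$count, c(3L, 3L, 3L, rep(2L, 7)))
  expect_equal(sum(tab23$count), 23)
  expect_true(all(diff(tab23$mean_pred) >= 0))

  expect_error(calibration_deciles(runif(9), rbinom(9, 1, 0.5)), "n >= 10")
})
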