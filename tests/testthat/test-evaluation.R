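# Trapezoidal AUC oracle over the empirical ROC curve.
trapezoid_auc <- function(roc) {
  fpr <- 1 - roc$curve$specificity
  tpr <- roc$curve$sensitivity
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

test_that("ROC handles the separable and uninformative extremes", {
  gold <- rep(c("responder", "non_responder"), each = 10)
  sep <- c(runif(10, -90, -60), runif(10, -20, 30))
  roc <- roc_analysis(sep, gold)
  expect_equal(roc$auc, 1)
  expect_equal(roc$youden_j, 1)
  flat <- roc_analysis(rep(-10, 20), gold)
  expect_equal(flat$auc, 0.5)  # tie-corrected
  expect_error(roc_analysis(sep, rep("responder", 20)), "both classes")
})

test_that("rank AUC equals trapezoidal AUC and Youden beats every cut", {
  set.seed(99)
  for (i in 1:500) {
    n <- sample(6:30, 1)
    gold <- sample(c("responder", "non_responder"), n, replace = TRUE)
    if (length(unique(gold)) < 2) next
    changes <- round(runif(n, -90, 60), sample(0:1, 1))  # force ties
    roc <- roc_analysis(changes, gold)
    expect_equal(roc$auc, trapezoid_auc(roc), tolerance = 1e-12)
    j_all <- roc$curve$sensitivity + roc$curve$specificity - 1
    expect_equal(roc$youden_j, max(j_all), tolerance = 1e-12)
    opt <- youden_optimal(roc)
    expect_equal(opt$youden_j, max(j_all), tolerance = 1e-12)
    expect_true(opt$threshold %in%
                  roc$curve$threshold[j_all == max(j_all)])
  }
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(10:40, 1)
    gold <- c("responder", "non_responder",
              sample(c("responder", "non_responder"), n - 2,
                     replace = TRUE))
    changes <- round(runif(n, -90, 60), 1)
    mine <- roc_analysis(changes, gold)$auc
    ref <- pROC::roc(factor(gold, c("non_responder", "responder")),
                     -changes, quiet = TRUE, direction = "<")
    expect_equal(mine, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  }
})

test_that("confusion statistics reproduce a hand-tabulated table", {
  st <- confusion_stats(tp = 8, tn = 9, fp = 1, fn = 2)
  expect_equal(st$sensitivity, 0.8)
  expect_equal(st$specificity, 0.9)
  expect_equal(st$ppv, 8 / 9)
  expect_equal(st$npv, 9 / 11)
  expect_equal(st$accuracy, 0.85)
  expect_equal(st$youden_j, 0.7)

  perfect <- confusion_stats(50, 50, 0, 0)
  expect_true(all(unlist(perfect[c("sensitivity", "specificity", "ppv",
                                   "npv", "accuracy")]) == 1))
  undef <- confusion_stats(0, 10, 0, 5)
  expect_true(is.na(undef$ppv))  # no positive calls: PPV undefined
})

test_that("accuracy decomposes as the class-weighted mix of sens/spec", {
  set.seed(11)
  for (i in 1:100) {
    cts <- sample(0:40, 4, replace = TRUE)
    if (cts[1] + cts[4] == 0 || cts[2] + cts[3] == 0) next
    st <- confusion_stats(cts[1], cts[2], cts[3], cts[4])
    P <- cts[1] + cts[4]; N <- cts[2] + cts[3]
    expect_equal(st$accuracy,
                 (st$sensitivity * P + st$specificity * N) / (P + N))
  }
})

test_that("the chi-squared statistic matches the closed form", {
  closed <- function(a, b, c2, d) {
    n <- a + b + c2 + d
    n * (a * d - b * c2)^2 /
      ((a + b) * (c2 + d) * (a + c2) * (b + d))
  }
  expect_equal(chi_squared_2x2(25, 25, 25, 25)$statistic, 0)
  expect_equal(chi_squared_2x2(25, 25, 25, 25)$p_value, 1)
  # imbalance without association: chi-squared exactly 0
  tbl <- chi_squared_2x2(40, 10, 40, 10)
  expect_equal(tbl$statistic, closed(40, 40, 10, 10), tolerance = 1e-12)
  expect_equal(tbl$statistic, 0, tolerance = 1e-12)
  set.seed(21)
  for (i in 1:500) {
    x <- sample(1:50, 4, replace = TRUE)
    got <- chi_squared_2x2(x[1], x[2], x[3], x[4])
    # table rows are PET calls: (tp, fn) over (fp, tn)
    expect_equal(got$statistic, closed(x[1], x[4], x[3], x[2]),
                 tolerance = 1e-10)
    # invariant under swapping rows together with columns
    swapped <- chi_squared_2x2(x[2], x[1], x[4], x[3])
    expect_equal(swapped$statistic, got$statistic, tolerance = 1e-10)
  }
  zeromarg <- chi_squared_2x2(0, 10, 0, 10)
  expect_true(is.na(zeromarg$statistic))
  expect_true(is.na(zeromarg$p_value))
})

test_that("comparing an ROC curve with itself is a null result", {
  set.seed(5)
  gold <- sample(c("responder", "non_responder"), 60, replace = TRUE,
                 prob = c(0.5, 0.5))
  ch <- runif(60, -80, 40) - 20 * (gold == "responder")
  out <- compare_auc(ch, ch, gold)
  expect_equal(out$z, 0, tolerance = 1e-12)
  expect_equal(out$p_value, 1, tolerance = 1e-12)
})

test_that("a strong AUC gap on 200 cases is detected", {
  set.seed(6)
  gold <- rep(c("responder", "non_responder"), each = 100)
  strong <- c(rnorm(100, -60, 10), rnorm(100, 0, 10))   # AUC ~ 1
  weak <- c(rnorm(100, -32, 20), rnorm(100, -28, 20))   # AUC ~ 0.55
  out <- compare_auc(strong, weak, gold)
  expect_gt(out$auc_a, 0.9)
  expect_lt(out$auc_b, 0.7)
  expect_lt(out$p_value, 0.05)
})

test_that("the DeLong variance is consistent with the bootstrap", {
  set.seed(8)
  n <- 200
  gold <- rep(c("responder", "non_responder"), each = n / 2)
  ch <- c(rnorm(n / 2, -45, 18), rnorm(n / 2, -15, 18))
  resp <- factor(gold, c("non_responder", "responder"))
  r <- pROC::roc(resp, -ch, quiet = TRUE, direction = "<")
  v_delong <- pROC::var(r, method = "delong")
  boot <- replicate(2000, {
    ix <- c(sample(which(gold == "responder"), replace = TRUE),
            sample(which(gold == "non_responder"), replace = TRUE))
    roc_analysis(ch[ix], gold[ix])$auc
  })
  expect_equal(v_delong, var(boot), tolerance = 0.2)
})

test_that("metrics with indistinguishable AUCs group together", {
  set.seed(13)
  n <- 120
  gold <- rep(c("responder", "non_responder"), each = n / 2)
  sep <- c(rnorm(n / 2, -55, 22), rnorm(n / 2, 0, 22))
  tbl <- cbind(suv_max = sep,
               suv_peak = sep + rnorm(n, 0, 2),     # nearly identical
               mv = rnorm(n, -30, 25))              # uninformative
  groups <- auc_groups(tbl, gold)
  in_same <- function(a, b) any(vapply(groups, function(g)
    all(c(a, b) %in% g), logical(1)))
  expect_true(in_same("suv_max", "suv_peak"))
  expect_false(in_same("suv_max", "mv"))
})
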