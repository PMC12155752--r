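test_that("confusion metrics reproduce the reference worked examples", {
  swin <- metrics_from_counts(confusion_counts(tp = 160, fn = 13,
                                               tn = 114, fp = 51))
  expect_equal(round(swin$precision, 3), 0.758)
  expect_equal(round(swin$f1, 3), 0.833)
  expect_equal(round(swin$accuracy, 3), 0.811)
  expect_equal(round(swin$sensitivity, 3), 0.925)
  expect_equal(round(swin$specificity, 3), 0.691)
  resnet <- metrics_from_counts(confusion_counts(137, 36, 120, 45))
  expect_equal(round(resnet$precision, 3), 0.753)
  expect_equal(round(resnet$f1, 3), 0.772)
})

test_that("zero denominators are flagged undefined rather than zeroed", {
  m <- metrics_from_counts(confusion_counts(tp = 0, fn = 0, tn = 5, fp = 0))
  expect_true(is.na(m$precision))
  expect_true(is.na(m$sensitivity))
  expect_equal(m$specificity, 1)
  expect_setequal(m$undefined, c("sensitivity", "precision", "f1"))
  expect_error(confusion_counts(-1, 0, 0, 0), "non-negative")
})

test_that("metrics agree with brute-force tallies over random settings", {
  set.seed(33)
  for (i in 1:1000) {
    n <- sample(4:40, 1)
    truth <- sample(c("A", "B"), n, replace = TRUE)
    pred <- sample(c("A", "B"), n, replace = TRUE)
    rec <- data.frame(true_label = truth, predicted_label = pred)
    m <- metrics_from_counts(count_predictions(rec))
    expect_equal(m$accuracy, mean(truth == pred))
    if (any(truth == "A"))
      expect_equal(m$sensitivity,
                   mean(pred[truth == "A"] == "A"))
  }
})

test_that("rank AUC equals the brute-force pairwise count", {
  lab <- c("A", "A", "A", "B", "B", "B", "B", "A")
  sc <- c(0.9, 0.8, 0.35, 0.4, 0.35, 0.1, 0.8, 0.6)
  brute <- function(lab, sc) {
    pos <- sc[lab == "A"]; neg <- sc[lab == "B"]
    s <- 0
    for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
    s / (length(pos) * length(neg))
  }
  expect_identical(roc_auc(lab, sc), brute(lab, sc))
  expect_equal(roc_auc(c("A", "B"), c(1, 0)), 1)
  expect_equal(roc_auc(rep(c("A", "B"), 5), rep(0.5, 10)), 0.5)
  # invariance under strictly increasing transforms
  set.seed(4)
  lab2 <- sample(c("A", "B"), 30, replace = TRUE, prob = c(0.5, 0.5))
  s2 <- rnorm(30)
  expect_equal(roc_auc(lab2, s2), roc_auc(lab2, exp(s2)))
  expect_equal(roc_auc(lab2, s2), roc_auc(lab2, rank(s2)))
  expect_error(roc_auc(rep("A", 5), 1:5), "both classes")
})

test_that("bootstrap intervals bracket the point estimate and degenerate cleanly", {
  set.seed(6)
  rec <- data.frame(
    true_label = rep(c("A", "B"), c(30, 30)),
    score = c(rnorm(30, 0.7, 0.2), rnorm(30, 0.4, 0.2)))
  rec$predicted_label <- ifelse(rec$score >= 0.5, "A", "B")
  for (m in c("accuracy", "sensitivity", "auc")) {
    ci <- bootstrap_ci(rec, m, n_boot = 500, seed = 9)
    point <- mcmae:::metric_from_records(rec, m)
    expect_lte(ci[["low"]], point)
    expect_gte(ci[["high"]], point)
  }
  perfect <- data.frame(true_label = rep(c("A", "B"), 10),
                        predicted_label = rep(c("A", "B"), 10),
                        score = rep(c(1, 0), 10))
  expect_equal(as.numeric(bootstrap_ci(perfect, "accuracy", 200, 1)), c(1, 1))
  expect_error(bootstrap_ci(rec, "accuracy", n_boot = 100), "200")
})

test_that("bootstrap accuracy intervals attain nominal coverage", {
  set.seed(5)
  nsim <- 500
  covered <- logical(nsim)
  for (i in seq_len(nsim)) {
    rec <- data.frame(true_label = rep(c("A", "B"), c(173, 165)))
    correct <- runif(338) < 0.8
    rec$predicted_label <- ifelse(correct, rec$true_label,
                                  ifelse(rec$true_label == "A", "B", "A"))
    ci <- bootstrap_ci(rec, "accuracy", n_boot = 500, seed = i)
    covered[i] <- ci[["low"]] <= 0.8 && 0.8 <= ci[["high"]]
  }
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("DeLong test is internally consistent and matches pROC", {
  set.seed(9)
  n <- 60
  lab <- rep(c("A", "B"), each = n / 2)
  s1 <- rnorm(n) + (lab == "A")
  s2 <- 0.7 * s1 + rnorm(n, 0, 0.6)
  dl <- delong_test(lab, s1, s2)
  expect_identical(dl$auc1, roc_auc(lab, s1))
  expect_identical(dl$auc2, roc_auc(lab, s2))
  # identical score vectors: z = 0, p = 1 by convention
  same <- delong_test(lab, s1, s1)
  expect_equal(same$z, 0); expect_equal(same$p, 1)
  skip_if_not_installed("pROC")
  r1 <- pROC::roc(lab, s1, levels = c("B", "A"), direction = "<", quiet = TRUE)
  r2 <- pROC::roc(lab, s2, levels = c("B", "A"), direction = "<", quiet = TRUE)
  rt <- pROC::roc.test(r1, r2, method = "delong")
  expect_equal(dl$z, unname(rt$statistic), tolerance = 1e-10)
  expect_equal(dl$p, rt$p.value, tolerance = 1e-10)
})

test_that("DeLong agrees with a paired permutation oracle on a toy set", {
  set.seed(21)
  n <- 30
  lab <- rep(c("A", "B"), each = 15)
  u <- rnorm(n)
  s1 <- u + (lab == "A") * 0.8 + rnorm(n, 0, 0.5)
  s2 <- u + (lab == "A") * 0.4 + rnorm(n, 0, 0.5)
  dl <- delong_test(lab, s1, s2)
  # null: swap the two models' scores per subject at random
  obs <- abs(roc_auc(lab, s1) - roc_auc(lab, s2))
  perm <- replicate(20000, {
    sw <- runif(n) < 0.5
    a <- ifelse(sw, s2, s1); b <- ifelse(sw, s1, s2)
    abs(roc_auc(lab, a) - roc_auc(lab, b))
  })
  p_perm <- (1 + sum(perm >= obs - 1e-12)) / 20001
  expect_lt(abs(dl$p - p_perm), 0.05)
})

test_that("DeLong keeps its nominal type-I error under the null", {
  set.seed(2024)
  nsim <- 1000
  rej <- 0
  for (i in seq_len(nsim)) {
    u <- rnorm(100)
    s1 <- u + rnorm(100); s2 <- u + rnorm(100)
    lab <- rep(c("A", "B"), 50)
    rej <- rej + (delong_test(lab, s1, s2)$p < 0.05)
  }
  expect_gte(rej / nsim, 0.03)
  expect_lte(rej / nsim, 0.07)
})

test_that("the full metric report mirrors its components", {
  set.seed(11)
  rec <- data.frame(
    true_label = rep(c("A", "B"), c(25, 25)),
    score = c(runif(25, 0.3, 1), runif(25, 0, 0.7)))
  rec$predicted_label <- ifelse(rec$score >= 0.5, "A", "B")
  rep_full <- metric_report(rec, n_boot = 200, seed = 2)
  expect_equal(rep_full$auc, roc_auc(rec$true_label, rec$score))
  for (m in c("accuracy", "sensitivity", "specificity", "precision", "f1")) {
    ci <- rep_full$ci95[[m]]
    expect_lte(ci[["low"]], rep_full[[m]])
    expect_gte(ci[["high"]], rep_full[[m]])
  }
})
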