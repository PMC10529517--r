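test_that("confusion counts match a naive loop on random vectors", {
  expect_equal(confusion_counts(c(1, 0, 1), c(1, 0, 1)),
               list(TP = 2L, TN = 1L, FP = 0L, FN = 0L))
  expect_equal(confusion_counts(c(1, 0), c(0, 1)),
               list(TP = 0L, TN = 0L, FP = 1L, FN = 1L))
  set.seed(1)
  y <- rbinom(200, 1, 0.4); p <- rbinom(200, 1, 0.5)
  cc <- confusion_counts(y, p)
  loop <- c(TP = 0, TN = 0, FP = 0, FN = 0)
  for (i in 1:200) {
    k <- if (y[i] == 1 && p[i] == 1) "TP" else if (y[i] == 0 && p[i] == 0)
      "TN" else if (y[i] == 0) "FP" else "FN"
    loop[k] <- loop[k] + 1
  }
  expect_equal(unlist(cc), loop)
  expect_error(confusion_counts(c(1, 0), c(1)), "equal")
})

test_that("basic metrics follow the closed forms and degenerate to 0", {
  perfect <- basic_metrics(list(TP = 5, TN = 5, FP = 0, FN = 0))
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  m <- basic_metrics(list(TP = 50, TN = 40, FP = 5, FN = 5))
  expect_equal(m$accuracy, 0.9)
  expect_equal(m$precision, 50 / 55)
  expect_equal(m$recall, 50 / 55)
  expect_equal(m$f1, 10 / 11)
  deg <- basic_metrics(list(TP = 0, TN = 10, FP = 0, FN = 0))
  expect_equal(deg$precision, 0)
  expect_true("precision" %in% deg$degenerate)
})

test_that("kappa: perfect agreement, constructed table, and error cases", {
  expect_equal(cohens_kappa(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  # 2x2 table a=20 (1,1), b=5 (1,0), c=10 (0,1), d=15 (0,0):
  # P0 = 0.7, PC = 0.5*0.6 + 0.5*0.4 = 0.5, kappa = 0.4
  y <- rep(c(1, 1, 0, 0), c(20, 5, 10, 15))
  p <- rep(c(1, 0, 1, 0), c(20, 5, 10, 15))
  expect_equal(cohens_kappa(y, p), 0.4)
  expect_error(cohens_kappa(c(1, 1), c(1, 1)), "undefined")
})

test_that("kappa of independent raters tends to zero", {
  set.seed(2)
  y <- rbinom(10000, 1, 0.5)
  p <- rbinom(10000, 1, 0.5)
  expect_lt(abs(cohens_kappa(y, p)), 0.05)
})

test_that("IoU geometry: identity, disjoint, symmetry, scale invariance", {
  a <- boxes_df(0, 0, 9, 9)
  expect_equal(box_iou(a, a), 1)
  expect_equal(box_iou(a, boxes_df(20, 20, 30, 30)), 0)
  set.seed(3)
  for (i in 1:10) {
    b1 <- random_box(50); b2 <- random_box(50)
    expect_equal(box_iou(b1, b2), box_iou(b2, b1))
    s <- runif(1, 0.5, 3)
    expect_equal(box_iou(b1, b2), box_iou(b1 * s, b2 * s), tolerance = 1e-12)
  }
  expect_error(box_iou(boxes_df(0, 0, 1, 1), list(x_min = 0, y_min = 0,
                                                  x_max = 0, y_max = 1)),
               "degenerate")
})

test_that("two equal squares offset by one-ninth overlap at IoU 64/98", {
  a <- boxes_df(0, 0, 9, 9)
  b <- boxes_df(1, 1, 10, 10)
  expect_equal(box_iou(a, b), 64 / 98)
})

test_that("match_iou picks the best truth box for the primary prediction", {
  truth <- rbind(boxes_df(0, 0, 10, 10), boxes_df(30, 30, 40, 45))
  expect_equal(match_iou(boxes_df(30, 30, 40, 45), truth), 1)
  expect_equal(match_iou(empty_boxes(), truth), 0)
  set.seed(4)
  for (i in 1:5) {
    truth3 <- do.call(rbind, lapply(1:3, function(.) random_box(64)))
    pred <- random_box(64)
    expect_equal(match_iou(pred, truth3),
                 max(sapply(1:3, function(j) box_iou(pred, truth3[j, ]))))
  }
})

test_that("AUC: separation, randomness, and the Mann-Whitney identity", {
  y <- c(0, 0, 1, 1)
  expect_equal(roc_auc(y, c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  expect_error(roc_auc(c(1, 1), c(0.5, 0.6)), "both classes")
  set.seed(5)
  yr <- rbinom(2000, 1, 0.5)
  sr <- runif(2000)
  expect_lt(abs(roc_auc(yr, sr)$auc - 0.5), 0.05)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    yy <- c(0, 1, rbinom(n, 1, 0.5))
    ss <- round(runif(n + 2), 2) # duplicates force tie handling
    expect_equal(roc_auc(yy, ss)$auc, oracle_auc_mann_whitney(yy, ss),
                 tolerance = 1e-10)
  }
})

test_that("metrics report assembles and round-trips through JSON", {
  set.seed(6)
  y <- rbinom(50, 1, 0.5)
  s <- ifelse(y == 1, runif(50, 0.4, 1), runif(50, 0, 0.6))
  rep <- metrics_report(y, s, ious = c(0.4, 0.6))
  expect_equal(rep$mean_iou, 0.5)
  expect_equal(rep$n, 50)
  expect_equal(rep$n_boxed, 2)
  expect_true(rep$auc >= 0 && rep$auc <= 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_metrics_report(rep, path)
  back <- read_metrics_report(path)
  expect_equal(back$accuracy, rep$accuracy)
  expect_equal(back$kappa, rep$kappa)
  expect_equal(back$mean_iou, 0.5)
})
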