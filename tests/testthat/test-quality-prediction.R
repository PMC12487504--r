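feature_cols_for_test <- function() {
  paste0("A", rep(1:3, each = 3), rep(1:3, 3))
}

small_set <- function(seed = 42, n_high = 10, n_low = 10) {
  generate_dataset(synthetic_spec(n_high = n_high, n_low = n_low,
                                  seed = seed))
}

test_that("subgroups are sampled per the design constraints", {
  set <- small_set(n_high = 30, n_low = 10)
  high <- filter_quality(set, "high")
  sgs <- make_subgroups(high, n_subgroups = 30, size = 7, seed = 1)
  expect_length(sgs, 30L)
  for (sg in sgs) {
    expect_length(unique(sg$member_sessions), 7L)
    expect_true(all(grepl("^high_", sg$member_sessions)))
  }
  # a pool smaller than the subgroup allows recurrence across subgroups
  low <- filter_quality(set, "low")
  sgl <- make_subgroups(low, n_subgroups = 10, size = 7, seed = 1)
  all_members <- unlist(lapply(sgl, `[[`, "member_sessions"))
  expect_gt(max(table(all_members)), 1)
  # deterministic under seed
  expect_identical(make_subgroups(high, 5, seed = 3),
                   make_subgroups(high, 5, seed = 3))
  # pool of 5 cannot form subgroups of 7
  five <- session_set(filter_quality(set, "high")$sessions[1:5])
  expect_error(make_subgroups(five, 2, size = 7), "exceeds pool")
})

test_that("subgroup features are flattened row-stochastic transition rows", {
  set <- small_set(n_high = 10, n_low = 10)
  sg <- make_subgroups(filter_quality(set, "high"), 3, seed = 2)
  row <- subgroup_features(sg[[1]], set)
  fc <- paste0("A", rep(1:3, each = 3), rep(1:3, 3))
  feats <- as.numeric(row[1, fc])
  expect_true(all(feats >= 0 & feats <= 1))
  for (r in 0:2) {
    expect_equal(sum(feats[r * 3 + 1:3]), 1, tolerance = 1e-9)
  }
  expect_identical(row$label, "high")
  # identical subgroup + config twice -> identical features
  row2 <- subgroup_features(sg[[1]], set)
  expect_identical(as.numeric(row[1, fc]), as.numeric(row2[1, fc]))
  # features track the generator truth for a 7-session subgroup
  err <- max(abs(matrix(feats, 3, 3, byrow = TRUE) -
                   default_profiles()$high$A))
  expect_lt(err, 0.15)
  # missing member sessions are a validation error
  bad <- sg[[1]]; bad$member_sessions[1] <- "nope"
  expect_error(subgroup_features(bad, set), "not found")
})

test_that("LOOCV folds never leak the held-out subgroup", {
  set <- small_set()
  sgs <- c(make_subgroups(filter_quality(set, "high"), 4, seed = 1),
           make_subgroups(filter_quality(set, "low"), 4, seed = 1))
  rows <- do.call(rbind, lapply(sgs, subgroup_features, sessions = set))
  # fold disjointness by subgroup_id is structural: ids are unique and each
  # row is predicted exactly once from a model trained without it
  preds <- loocv_predict(rows)
  expect_identical(sort(preds$subgroup_id), sort(rows$subgroup_id))
  expect_false(anyDuplicated(preds$subgroup_id) > 0)
  rows_dup <- rbind(rows, rows[1, ])
  expect_error(loocv_predict(rows_dup), "duplicate")
})

test_that("metric bundle matches direct hand evaluation on a 10-item fixture", {
  truth <- c("high", "high", "high", "high", "high",
             "low", "low", "low", "low", "low")
  pred <- c("high", "high", "high", "high", "low",
            "low", "low", "low", "high", "low")
  prob <- c(0.1, 0.2, 0.3, 0.15, 0.7, 0.9, 0.8, 0.6, 0.4, 0.95)
  m <- compute_metrics(truth, pred, prob)
  expect_equal(m$accuracy, 0.8)
  # low: tp=4 fp=1 fn=1 tn=4
  expect_equal(m$per_class$low$precision, 4 / 5)
  expect_equal(m$per_class$low$recall_sensitivity, 4 / 5)
  expect_equal(m$per_class$low$specificity, 4 / 5)
  expect_equal(m$per_class$low$f1, 2 * 0.8 * 0.8 / 1.6)
  # binary symmetry: specificity of one class = recall of the other
  expect_equal(m$per_class$high$specificity,
               m$per_class$low$recall_sensitivity)
  # confusion rows sum to 1
  expect_equal(rowSums(m$confusion_matrix), c(high = 1, low = 1))
  # AUC: rank statistic equals trapezoidal area and hand count
  expect_equal(m$roc_auc, trapezoid_auc(truth, prob), tolerance = 1e-12)
  # harmonic-mean identity F1 (P + R) = 2 P R
  for (cl in c("high", "low")) {
    p <- m$per_class[[cl]]$precision; r <- m$per_class[[cl]]$recall_sensitivity
    expect_equal(m$per_class[[cl]]$f1 * (p + r), 2 * p * r, tolerance = 1e-12)
  }
})

test_that("AUC tie convention and degenerate prediction flags", {
  truth <- c("high", "low", "high", "low")
  expect_equal(roc_auc(truth, rep(0.5, 4)), 0.5)
  m <- compute_metrics(truth, rep("high", 4), rep(0.5, 4))
  expect_true(m$per_class$low$undefined_precision)
  expect_identical(m$per_class$low$precision, 0)
  # rank AUC == trapezoid AUC on random tied fixtures
  set.seed(42)
  for (i in 1:20) {
    tr <- sample(c("high", "low"), 30, replace = TRUE)
    if (length(unique(tr)) < 2) next
    pr <- sample(seq(0, 1, 0.25), 30, replace = TRUE)
    expect_equal(roc_auc(tr, pr), trapezoid_auc(tr, pr), tolerance = 1e-12)
  }
})

test_that("rank AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  truth <- sample(c("high", "low"), 50, replace = TRUE)
  prob <- runif(50)
  expect_equal(roc_auc(truth, prob),
               as.numeric(pROC::auc(pROC::roc(
                 response = factor(truth, c("high", "low")),
                 predictor = prob, quiet = TRUE, direction = "<"))),
               tolerance = 1e-10)
})

test_that("linearly separable features classify perfectly", {
  set.seed(42)
  n <- 20
  mk_row <- function(i, label, shift) {
    a <- pmin(pmax(c(0.6, 0.3, 0.1) + shift + rnorm(3, 0, 0.01), 0.01), 0.97)
    rows <- rbind(a / sum(a),
                  c(0.3, 0.5, 0.2), c(0.2, 0.3, 0.5))
    data.frame(subgroup_id = sprintf("%s_%02d", label, i),
               t(setNames(as.vector(t(rows)), feature_cols_for_test())),
               label = label, gradient_valid = TRUE,
               stringsAsFactors = FALSE)
  }
  rows <- rbind(
    do.call(rbind, lapply(1:n, mk_row, label = "high", shift = c(0.2, -0.1, -0.1))),
    do.call(rbind, lapply(1:n, mk_row, label = "low", shift = c(-0.3, 0.1, 0.2))))
  preds <- loocv_predict(rows)
  m <- compute_metrics(preds$truth, preds$pred, preds$prob_low)
  expect_equal(m$accuracy, 1.0)
  expect_equal(m$roc_auc, 1.0)
})

test_that("imbalanced design runs end-to-end with both classes reported", {
  set <- small_set(n_high = 12, n_low = 8, seed = 21)
  rep <- loocv_classify(set, hmm_config(max_iter = 60, tol = 1e-4),
                        design = "imbalanced_3to1", n_subgroups = 9,
                        size = 5, n_iterations = 2, seed = 13)
  expect_identical(unname(rep$n_subgroups), c(9L, 3L))
  for (col in c("high_precision", "low_precision", "high_specificity",
                "low_specificity", "accuracy", "roc_auc")) {
    expect_true(is.finite(rep$mean[[col]]))
  }
  expect_equal(rowSums(rep$confusion_matrix), c(high = 1, low = 1),
               tolerance = 1e-9)
})
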