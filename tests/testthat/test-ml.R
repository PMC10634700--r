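test_that("median split labels long strictly above the treated median", {
  p <- data.frame(patient_id = c("A1", "A2", "A3"), cohort = "aCD40",
                  dfs_months = c(2, 9.8, 30))
  lab <- derive_dfs_labels(p)
  expect_identical(lab$dfs_label, c("short", "short", "long"))
  expect_identical(attr(lab, "dfs_median"), 9.8)

  same <- data.frame(patient_id = c("A1", "A2"), cohort = "aCD40",
                     dfs_months = c(5, 5))
  expect_identical(derive_dfs_labels(same)$dfs_label, c("short", "short"))

  p$dfs_months[2] <- NA
  expect_error(derive_dfs_labels(p), "dfs_months")
})

test_that("LOPO folds are one-per-patient, disjoint and exhaustive", {
  rid <- paste0("R", 1:6)
  pid <- rep(c("P1", "P2", "P3"), each = 2)
  lab <- rep(c("a", "b", "a"), each = 2)
  folds <- make_folds_lopo(rid, pid, lab)
  expect_length(folds, 3L)
  for (f in folds) {
    expect_length(f$test, 2L)
    expect_length(f$train, 4L)
    expect_length(intersect(f$test, f$train), 0L)
  }
  expect_setequal(unlist(lapply(folds, `[[`, "test")), rid)

  expect_error(make_folds_lopo("R1", "P1", "a"), "2 patients")
  expect_error(make_folds_lopo(rid, pid, rep("a", 6)), "one class")

  # property over random groupings
  set.seed(31)
  for (i in 1:10) {
    np <- sample(3:8, 1)
    pid <- sample(paste0("P", 1:np), 30, replace = TRUE)
    rid <- paste0("R", 1:30)
    lab <- sample(c("x", "y"), 30, replace = TRUE)
    if (length(unique(lab)) < 2) next
    folds <- make_folds_lopo(rid, pid, lab)
    tests <- unlist(lapply(folds, `[[`, "test"))
    expect_identical(sort(tests), sort(rid))
    expect_identical(anyDuplicated(tests), 0L)
  }
})

test_that("fold preprocessing applies log10+1, train-fitted minmax and clipping", {
  train <- matrix(c(0, 9, 5, 5, 0, 0), 2, 3,
                  dimnames = list(c("r1", "r2"), c("f1", "const", "zero")))
  test <- matrix(c(99, 7, 0), 1, 3,
                 dimnames = list("t1", c("f1", "const", "zero")))
  pp <- preprocess_fold(train, test)
  expect_equal(pp$train[, "f1"], c(r1 = 0, r2 = 1))
  expect_equal(unname(pp$test[, "f1"]), 1)          # log10(100)=2 -> clipped
  expect_true(all(pp$train[, "const"] == 0))        # constant column -> 0
  expect_true(all(pp$test[, "const"] == 0))
  expect_true(all(pp$train[, "zero"] == 0))
  expect_error(preprocess_fold(-train, test), "non-negative")
})

test_that("SMOTE balances classes with convex minority combinations", {
  set.seed(41)
  x <- rbind(matrix(rnorm(20, 5), 10, 2),
             matrix(c(0, 1, 0, 1), 2, 2))
  y <- c(rep("maj", 10), rep("min", 2))
  bal <- balance_train(x, y, seed = 9)
  expect_identical(as.integer(table(bal$y)), c(10L, 10L))
  synth <- bal$x[-(1:12), , drop = FALSE]
  # minority points are (0,0) and (1,1): synthetic points lie on the segment
  expect_true(all(abs(synth[, 1] - synth[, 2]) < 1e-12))
  expect_true(all(synth >= 0 & synth <= 1))

  expect_warning(out <- balance_train(x[1:11, ], y[1:11], seed = 1),
                 "single sample")
  expect_identical(out$x, x[1:11, ])
  expect_error(balance_train(x[1:10, ], y[1:10], seed = 1), "both classes")
})

test_that("elastic-net fits degenerate and separable data sensibly", {
  # all-constant features: all coefficients 0, balanced prevalence 0.5
  x <- matrix(1, 8, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rep(c("pos", "neg"), 4)
  fit <- fit_en_model(x, y, "pos")
  expect_true(all(fit$w == 0))
  expect_equal(stats::plogis(fit$b), 0.5)

  # 1-D separated data: extreme points classified correctly
  x1 <- matrix(c(0, .05, .1, .9, .95, 1), dimnames = list(NULL, "f"))
  y1 <- c(rep("neg", 3), rep("pos", 3))
  f1 <- fit_en_model(x1, y1, "pos")
  expect_gt(stats::plogis(f1$b + 1 * f1$w), 0.5)
  expect_lt(stats::plogis(f1$b + 0 * f1$w), 0.5)

  # duplicating every training row leaves the solution unchanged
  set.seed(51)
  x2 <- matrix(runif(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y2 <- sample(c("pos", "neg"), 20, replace = TRUE)
  f2 <- fit_en_model(x2, y2, "pos")
  # same per-sample lambda: C halves when n doubles under the 1/(C n) map
  f2d <- fit_en_model(rbind(x2, x2), c(y2, y2), "pos", C = 0.5)
  expect_equal(f2$w, f2d$w, tolerance = 1e-5)
  expect_equal(f2$b, f2d$b, tolerance = 1e-5)
})

test_that("pooled scoring reproduces hand-computed metrics", {
  truth <- c(rep("pos", 10), rep("neg", 10))
  prob <- c(rep(0.9, 8), rep(0.1, 2), rep(0.9, 2), rep(0.1, 8))
  s <- score_pooled(truth, prob, "pos")
  expect_equal(s$accuracy, 0.8)   # TP=8 FP=2 FN=2 TN=8
  expect_equal(s$f1, 0.8)
  expect_identical(s$confusion["pos", "pos"], 8L)

  perfect <- score_pooled(truth, c(seq(0.6, 0.9, length.out = 10),
                                   seq(0.1, 0.4, length.out = 10)), "pos")
  expect_equal(perfect$auc, 1)
  flat <- score_pooled(truth, rep(0.5, 20), "pos")
  expect_equal(flat$auc, 0.5)     # midrank ties
  expect_error(score_pooled(rep("pos", 5), runif(5), "pos"), "single class")
})

test_that("linear SHAP matches its closed form and sums to the margin gap", {
  w <- c(f1 = 2, f2 = -1)
  mu <- c(f1 = 0.5, f2 = 0.5)
  X <- matrix(c(1, 0), 1, 2, dimnames = list("r", names(w)))
  s <- linear_shap(w, mu, X)
  expect_equal(unname(s[1, ]), c(1, 0.5))
  expect_equal(sum(s), sum(w * (X[1, ] - mu)))  # = f(x) - f(mu)
})

test_that("LOPO never leaks patients and recovers the planted cohort effect", {
  d <- small_cohort(seed = 61)
  cells <- phenotyped(d)
  fm <- build_feature_matrix(cells, d$regions, default_gating)
  m <- run_lopo(fm, d$regions, d$patients, task = "treatment", site = "IA",
                seed = 2)

  pat_of_region <- stats::setNames(d$regions$patient_id, d$regions$region_id)
  for (f in m$folds) {
    expect_identical(unique(unname(pat_of_region[f$test])), f$patient)
  }
  # every region predicted exactly once
  ia <- d$regions$region_id[d$regions$site == "IA"]
  expect_setequal(m$pooled$region_id, ia)
  expect_identical(anyDuplicated(m$pooled$region_id), 0L)

  expect_gte(m$auc, 0.8)
  top10 <- top_features(m, 10)$feature
  planted <- planted_feature_keys(d$truth$effects, colnames(fm), "treatment")
  expect_gte(length(intersect(top10, planted)), 1L)

  # AUC cross-check against an independent implementation
  proc_auc <- as.numeric(pROC::auc(pROC::roc(
    response = m$pooled$truth, predictor = m$pooled$prob,
    levels = c("naive", "aCD40"), direction = "<", quiet = TRUE)))
  expect_equal(m$auc, proc_auc, tolerance = 1e-12)

  # direction of a nonzero-coefficient feature equals its coefficient sign
  imp <- top_features(m, 5)
  expect_true(all(imp$direction %in% c(-1, 0, 1)))
})

test_that("pooled metrics are invariant to fold execution order", {
  d <- small_cohort(seed = 62, n_naive = 4, n_acd40 = 4, cells = 100)
  cells <- phenotyped(d)
  fm <- build_feature_matrix(cells, d$regions, default_gating)
  m1 <- run_lopo(fm, d$regions, d$patients, task = "treatment", site = "IA",
                 seed = 3)
  # reverse patient order by reversing the region table
  m2 <- run_lopo(fm, d$regions[rev(seq_len(nrow(d$regions))), ],
                 d$patients, task = "treatment", site = "IA", seed = 3)
  expect_equal(sort(m1$pooled$prob), sort(m2$pooled$prob), tolerance = 1e-9)
  expect_equal(m1$accuracy, m2$accuracy)
  expect_equal(m1$auc, m2$auc)
})

test_that("the DFS task restricts to treated regions and rejects NAP", {
  d <- small_cohort(seed = 63)
  cells <- phenotyped(d)
  fm <- build_feature_matrix(cells, d$regions, default_gating)
  patients <- derive_dfs_labels(d$patients)
  m <- run_lopo(fm, d$regions, patients, task = "dfs", site = "IA", seed = 4)
  acd40 <- d$regions$region_id[d$regions$cohort == "aCD40" &
                                 d$regions$site == "IA"]
  expect_setequal(m$pooled$region_id, acd40)
  expect_error(run_lopo(fm, d$regions, patients, task = "dfs", site = "NAP"),
               "NAP")
})
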