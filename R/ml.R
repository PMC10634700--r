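#' Derive long/short disease-free survival labels by median split
#'
#' The median DFS across the treated (aCD40) cohort separates long from
#' short survivors: strictly above the median is "long"; at or below is
#' "short" (a value exactly at the median does not strictly exceed it).
#' Naive patients are left unlabelled.
#'
#' @param patients Patient table with `cohort` and `dfs_months`.
#' @return `patients` with a `dfs_label` column.
#' @export
derive_dfs_labels <- function(patients) {
  trt <- patients$cohort == "aCD40"
  if (any(trt & is.na(patients$dfs_months))) {
    stop("every aCD40 patient needs dfs_months before the median split")
  }
  med <- stats::median(patients$dfs_months[trt])
  lab <- rep(NA_character_, nrow(patients))
  lab[trt] <- ifelse(patients$dfs_months[trt] > med, "long", "short")
  patients$dfs_label <- lab
  attr(patients, "dfs_median") <- med
  patients
}

#' Leave-one-patient-out folds
#'
#' One fold per patient: that patient's regions form the test set and every
#' other patient's regions form the train set, so no patient ever appears
#' on both sides of a split.
#'
#' @param region_ids Region identifiers.
#' @param patient_ids Parallel patient identifier per region.
#' @param labels Parallel class label per region.
#' @return List of folds, each `list(patient, test, train)` of region ids.
#' @export
make_folds_lopo <- function(region_ids, patient_ids, labels) {
  stopifnot(length(region_ids) == length(patient_ids),
            length(region_ids) == length(labels))
  pats <- unique(patient_ids)
  if (length(pats) < 2L) stop("leave-one-patient-out needs at least 2 patients")
  if (length(unique(labels)) < 2L) {
    stop("unlearnable task: only one class present across all regions")
  }
  # region ids inside each fold are sorted so results cannot depend on the
  # incidental row order of the region table
  lapply(pats, function(p) {
    test <- sort(region_ids[patient_ids == p])
    list(patient = p, test = test, train = sort(setdiff(region_ids, test)))
  })
}

#' Per-fold feature preprocessing
#'
#' Applies the fixed transform `x -> log10(x + 1)` elementwise, then a
#' per-column min-max scaler to [0,1] fitted on the train rows only and
#' applied to both sets; test values outside [0,1] after scaling are
#' clipped. Columns constant in the train set map to 0 everywhere
#' (information-free; avoids a zero division).
#'
#' @param train,test Non-negative numeric matrices sharing columns.
#' @return List with transformed `train`, `test`, and the fitted `min`,
#'   `range` vectors.
#' @export
preprocess_fold <- function(train, test) {
  stopifnot(identical(colnames(train), colnames(test)))
  if (any(train < 0) || any(test < 0)) {
    stop("features must be non-negative before the log10+1 transform")
  }
  ltr <- log10(train + 1)
  lte <- log10(test + 1)
  mn <- apply(ltr, 2, min)
  rng <- apply(ltr, 2, max) - mn
  const <- rng == 0
  sc <- function(m, clip) {
    out <- sweep(sweep(m, 2, mn, "-"), 2, ifelse(const, 1, rng), "/")
    out[, const] <- 0
    if (clip) out <- pmin(pmax(out, 0), 1)
    out
  }
  list(train = sc(ltr, clip = FALSE), test = sc(lte, clip = TRUE),
       min = mn, range = rng)
}

#' Balance a training set by SMOTE oversampling
#'
#' Up-samples the minority class to match the majority by synthesising
#' points as convex combinations `x_i + u (x_j - x_i)` of a minority sample
#' and one of its `k` nearest minority neighbors (`k = min(5, m - 1)` for
#' minority count `m`). With fewer than two minority samples the train set
#' is returned unchanged with a warning.
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y Class labels (exactly two classes).
#' @param seed Integer seed for the sampling stream.
#' @param k Neighbor cap.
#' @return List with augmented `x` and `y`.
#' @export
balance_train <- function(x, y, seed = 1, k = 5) {
  tab <- table(y)
  if (length(tab) < 2L) stop("SMOTE needs both classes in the train set")
  if (tab[1] == tab[2]) return(list(x = x, y = y))
  minority <- names(tab)[which.min(tab)]
  m <- min(tab); need <- max(tab) - m
  if (m < 2L) {
    warning("minority class has a single sample; SMOTE skipped")
    return(list(x = x, y = y))
  }
  k <- min(k, m - 1L)
  xm <- x[y == minority, , drop = FALSE]
  d <- as.matrix(stats::dist(xm))
  nn <- apply(d, 1, function(r) order(r)[2:(k + 1L)])
  nn <- matrix(nn, nrow = k)  # k x m
  set.seed(seed)
  i <- sample.int(m, need, replace = TRUE)
  j <- nn[cbind(sample.int(k, need, replace = TRUE), i)]
  u <- stats::runif(need)
  synth <- xm[i, , drop = FALSE] + u * (xm[j, , drop = FALSE] - xm[i, , drop = FALSE])
  rownames(synth) <- sprintf("smote_%d", seq_len(need))
  list(x = rbind(x, synth), y = c(y, rep(minority, need)))
}

#' Fit one elastic-net logistic model
#'
#' Mixed L1/L2-penalised logistic regression at mixing ratio `l1_ratio`
#' (default 0.5, an equal balance of lasso and ridge) and fixed inverse
#' regularization strength `C`, mapped to the per-sample penalty
#' `lambda = 1 / (C * n)` so the objective matches the conventional
#' sum-loss parameterisation. The fit is convex and deterministic.
#'
#' @param x Preprocessed, balanced feature matrix.
#' @param y Class labels.
#' @param positive_class Label encoded as 1.
#' @param C Inverse regularization strength (> 0).
#' @param l1_ratio Elastic-net mixing parameter in [0, 1].
#' @return List with named coefficient vector `w`, intercept `b`, and the
#'   `lambda` used.
#' @export
fit_en_model <- function(x, y, positive_class, C = 1, l1_ratio = 0.5) {
  y01 <- as.integer(y == positive_class)
  lambda <- 1 / (C * nrow(x))
  rng <- apply(x, 2, function(v) max(v) - min(v))
  if (all(rng == 0)) {
    # intercept-only optimum: every coefficient is exactly 0
    p1 <- mean(y01)
    return(list(w = stats::setNames(rep(0, ncol(x)), colnames(x)),
                b = stats::qlogis(min(max(p1, 1e-12), 1 - 1e-12)),
                lambda = lambda))
  }
  xf <- x
  padded <- FALSE
  if (ncol(xf) == 1L) {  # glmnet requires >= 2 columns
    xf <- cbind(xf, .pad = 0)
    padded <- TRUE
  }
  fit <- withCallingHandlers(
    glmnet::glmnet(xf, y01, family = "binomial", alpha = l1_ratio,
                   lambda = lambda, standardize = FALSE,
                   thresh = 1e-9, maxit = 1e6),
    # small-cohort folds legitimately have few regions per class; glmnet's
    # sample-size nag would otherwise fire once per fold
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  if (!is.null(fit$jerr) && fit$jerr != 0) {
    stop("elastic-net solver did not converge (jerr = ", fit$jerr,
         ", npasses = ", fit$npasses, ")")
  }
  cf <- as.numeric(stats::coef(fit))
  w <- cf[-1]
  if (padded) w <- w[-length(w)]
  list(w = stats::setNames(w, colnames(x)), b = cf[1], lambda = lambda)
}

#' Exact SHAP values for a linear model
#'
#' For a linear margin `f(x) = b + w . x` with background point `mu`, the
#' exact Shapley attribution of feature `i` at `x` is
#' `w_i (x_i - mu_i)`; attributions sum to `f(x) - f(mu)` by construction.
#'
#' @param w Named coefficient vector.
#' @param mu Background feature means (same length/order as `w`).
#' @param X Matrix of rows to explain.
#' @return Matrix of SHAP values, one row per row of `X`.
#' @export
linear_shap <- function(w, mu, X) {
  sweep(sweep(X, 2, mu, "-"), 2, w, "*")
}

#' Pooled classification metrics
#'
#' Accuracy and positive-class F1 come from the single confusion matrix
#' pooled over all cross-validation folds; AUC is the rank statistic on
#' pooled positive-class probabilities with midranks for ties.
#'
#' @param truth True labels.
#' @param prob Positive-class probabilities.
#' @param positive_class Label treated as positive.
#' @param threshold Probability cut for the confusion matrix.
#' @return List: `confusion` (2x2), `accuracy`, `f1`, `auc`.
#' @export
score_pooled <- function(truth, prob, positive_class, threshold = 0.5) {
  pos <- truth == positive_class
  if (all(pos) || !any(pos)) {
    stop("AUC undefined: pooled truth contains a single class")
  }
  pred <- prob >= threshold
  tp <- sum(pred & pos); fp <- sum(pred & !pos)
  fn <- sum(!pred & pos); tn <- sum(!pred & !pos)
  confusion <- matrix(c(tp, fn, fp, tn), 2, 2,
                      dimnames = list(truth = c("pos", "neg"),
                                      pred = c("pos", "neg")))
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  r <- rank(prob)  # midranks
  n1 <- sum(pos); n0 <- sum(!pos)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(confusion = confusion, accuracy = (tp + tn) / length(truth),
       f1 = f1, auc = auc)
}

#' Leave-one-patient-out elastic-net classification of tissue regions
#'
#' Runs the full per-site modelling procedure for one task: region labels
#' from patient metadata, one fold per patient, per-fold log10+1 / min-max
#' preprocessing fitted on the train side only, SMOTE balancing of the
#' train side, an elastic-net logistic fit with fixed hyperparameters,
#' prediction of the held-out patient's regions, pooling of all held-out
#' predictions into one confusion matrix, and exact linear SHAP
#' attributions against the fold-train feature mean.
#'
#' @param fm Region-by-feature matrix ([build_feature_matrix()]).
#' @param regions Region metadata.
#' @param patients Patient table; for the DFS task it must carry
#'   `dfs_label` (see [derive_dfs_labels()]).
#' @param task `"treatment"` (naive vs aCD40, all regions of a site) or
#'   `"dfs"` (long vs short, treated cohort only; NAP has too few regions
#'   and is excluded).
#' @param site Histopathologic site to model.
#' @param C,l1_ratio Elastic-net hyperparameters, shared across folds.
#' @param seed Integer seed driving the SMOTE streams.
#' @return A `lopo_en` object: folds, pooled predictions, confusion
#'   matrix, accuracy/F1/AUC, pooled SHAP matrix, per-feature importance
#'   (mean |SHAP|) and direction.
#' @export
run_lopo <- function(fm, regions, patients, task = c("treatment", "dfs"),
                     site, C = 1, l1_ratio = 0.5, seed = 1) {
  task <- match.arg(task)
  stopifnot(site %in% SITES)
  if (task == "dfs" && site == "NAP") {
    stop("the DFS task excludes NAP (too few regions)")
  }
  reg <- regions[regions$site == site, , drop = FALSE]
  if (task == "dfs") {
    reg <- reg[reg$cohort == "aCD40", , drop = FALSE]
    if (!"dfs_label" %in% names(patients)) {
      patients <- derive_dfs_labels(patients)
    }
  }
  reg <- reg[reg$region_id %in% rownames(fm), , drop = FALSE]
  if (!nrow(reg)) stop("no regions of site '", site, "' in the feature matrix")
  if (task == "dfs") {
    lab_by_pat <- stats::setNames(patients$dfs_label, patients$patient_id)
    labels <- stats::setNames(as.character(lab_by_pat[reg$patient_id]),
                              reg$region_id)
    positive_class <- "long"
  } else {
    labels <- stats::setNames(reg$cohort, reg$region_id)
    positive_class <- "aCD40"
  }

  folds <- make_folds_lopo(reg$region_id, reg$patient_id, labels)

  fold_results <- vector("list", length(folds))
  shap_rows <- list(); pooled <- list(); x_rows <- list()
  for (fi in seq_along(folds)) {
    f <- folds[[fi]]
    tr <- fm[f$train, , drop = FALSE]
    te <- fm[f$test, , drop = FALSE]
    pp <- preprocess_fold(tr, te)
    if (length(unique(labels[f$train])) < 2L) {
      stop("fold for patient '", f$patient, "': single-class train set")
    }
    # seed the SMOTE stream from the held-out patient id so results do not
    # depend on fold execution order
    pat_seed <- sum(utf8ToInt(f$patient) * seq_along(utf8ToInt(f$patient)))
    bal <- balance_train(pp$train, as.character(labels[f$train]),
                         seed = (seed * 1009L + pat_seed) %% 2147483629L)
    fit <- fit_en_model(bal$x, bal$y, positive_class, C = C,
                        l1_ratio = l1_ratio)
    mu <- colMeans(pp$train)  # background: fold-train mean (pre-SMOTE)
    margin <- drop(pp$test %*% fit$w) + fit$b
    prob <- stats::plogis(margin)
    s <- linear_shap(fit$w, mu, pp$test)
    fold_results[[fi]] <- list(
      patient = f$patient, test = f$test, w = fit$w, b = fit$b,
      lambda = fit$lambda, mu = mu,
      base = drop(sum(fit$w * mu)) + fit$b
    )
    shap_rows[[fi]] <- s
    x_rows[[fi]] <- pp$test
    pooled[[fi]] <- data.frame(
      region_id = f$test, patient_id = f$patient,
      truth = as.character(labels[f$test]), prob = prob, margin = margin,
      stringsAsFactors = FALSE)
  }
  pooled <- do.call(rbind, pooled)
  shap <- do.call(rbind, shap_rows)
  X <- do.call(rbind, x_rows)
  pooled$pred <- ifelse(pooled$prob >= 0.5, positive_class,
                        setdiff(unique(labels), positive_class)[1])

  metrics <- score_pooled(pooled$truth, pooled$prob, positive_class)
  importance <- colMeans(abs(shap))
  direction <- vapply(seq_len(ncol(shap)), function(j) {
    if (stats::sd(X[, j]) == 0 || stats::sd(shap[, j]) == 0) return(0)
    sign(stats::cor(X[, j], shap[, j]))
  }, numeric(1))
  names(direction) <- colnames(shap)

  structure(
    list(task = task, site = site, positive_class = positive_class,
         hyperparams = list(C = C, l1_ratio = l1_ratio), seed = seed,
         folds = fold_results, pooled = pooled, shap = shap,
         confusion = metrics$confusion, accuracy = metrics$accuracy,
         f1 = metrics$f1, auc = metrics$auc,
         importance = importance, direction = direction,
         labels = labels),
    class = "lopo_en"
  )
}

#' @export
print.lopo_en <- function(x, ...) {
  cat(sprintf(
    "Leave-one-patient-out elastic net (%s task, site %s)\n", x$task, x$site))
  cat(sprintf("  %d folds, %d pooled regions; positive class '%s'\n",
              length(x$folds), nrow(x$pooled), x$positive_class))
  cat(sprintf("  accuracy %.3f | F1 %.3f | AUC %.3f\n",
              x$accuracy, x$f1, x$auc))
  invisible(x)
}

#' @export
summary.lopo_en <- function(object, n = 15, ...) {
  tf <- top_features(object, n)
  cat(sprintf("Task %s / site %s: accuracy %.3f, F1 %.3f, AUC %.3f\n",
              object$task, object$site, object$accuracy, object$f1,
              object$auc))
  cat("Pooled confusion matrix:\n")
  print(object$confusion)
  cat(sprintf("Top %d features by mean |SHAP| (direction = class pushed):\n",
              nrow(tf)))
  print(tf, row.names = FALSE)
  invisible(tf)
}

#' Top-ranked features of a fitted LOPO model
#'
#' @param model A `lopo_en` object.
#' @param n Number of features.
#' @return Data frame with `feature`, `importance` (mean |SHAP|) and
#'   `direction` (+1 pushes toward the positive class, -1 away, 0 inert).
#' @export
top_features <- function(model, n = 15) {
  imp <- model$importance
  ord <- order(-imp, names(imp))
  top <- utils::head(ord, n)
  data.frame(feature = names(imp)[top], importance = as.numeric(imp[top]),
             direction = as.numeric(model$direction[names(imp)[top]]),
             stringsAsFactors = FALSE)
}

#' Share of total SHAP importance carried by the top k features
#'
#' @param model A `lopo_en` object.
#' @param k Number of leading features.
#' @return Fraction in [0, 1].
#' @export
top_importance_share <- function(model, k = 30) {
  imp <- sort(model$importance, decreasing = TRUE)
  if (sum(imp) == 0) return(0)
  sum(utils::head(imp, k)) / sum(imp)
}
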