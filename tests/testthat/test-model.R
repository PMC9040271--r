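# Labelling rules, splitting, logistic fitting, metric oracles,
# peak-format selection and the repeated-split experiment.

test_that("median threshold follows the order statistics", {
  expect_equal(median_threshold(c(a = 0, b = 1, c = 2)), 1.0)
  expect_equal(median_threshold(c(0, 1, 2, 3)), 1.5)
  expect_warning(tb <- median_threshold(rep(4.2, 10)), "degenerate")
  expect_equal(tb, 4.2)
  expect_error(median_threshold(numeric(0)), "empty")
})

test_that("binarise sends ties at the threshold to OFF", {
  expr <- c(g1 = 0, g2 = 1, g3 = 2, g4 = 3)
  lab <- binarise(expr, 1.5, rule = "median")
  expect_equal(unname(lab), c(0L, 0L, 1L, 1L), ignore_attr = TRUE)
  expect_equal(unname(binarise(c(a = 2, b = 2.0001), 2)), c(0L, 1L), ignore_attr = TRUE)
  zeros <- binarise(c(a = 0, b = 0, c = 5), 0)
  expect_equal(unname(zeros), c(0L, 0L, 1L), ignore_attr = TRUE)
  expect_equal(attr(lab, "t_bar"), 1.5)
  expect_error(binarise(expr, -1), "nonnegative")
})

test_that("median labelling balances tie-free expression to within one gene", {
  set.seed(21)
  for (n in c(11, 50, 201)) {
    expr <- stats::setNames(rlnorm(n), paste0("g", 1:n))
    lab <- binarise(expr, median_threshold(expr), rule = "median")
    expect_lte(abs(sum(lab == 0) - sum(lab == 1)), 1)
    expect_gte(sum(lab == 0), floor(n / 2))  # ties (median itself) go OFF
  }
})

test_that("valley threshold lands between the modes of a bimodal mixture", {
  set.seed(22)
  expr <- c(rlnorm(600, log(0.05), 0.8), rlnorm(400, log(50), 0.8))
  names(expr) <- paste0("g", seq_along(expr))
  tb <- valley_threshold(expr)
  expect_gt(tb, 0.3)
  expect_lt(tb, 25)
  # the planted valley separates the two components almost perfectly
  truth <- rep(c(0L, 1L), c(600, 400))
  expect_gte(mean((expr > tb) == truth), 0.99)
})

test_that("valley threshold falls back to the median for unimodal data", {
  set.seed(23)
  expr <- stats::setNames(rlnorm(500, log(5), 0.3), paste0("g", 1:500))
  expect_warning(tb <- valley_threshold(expr), "median")
  expect_equal(tb, median(expr))
})

test_that("splits are ceil-balanced thirds, disjoint and reproducible", {
  sp <- split_dataset(19802, seed = 1)
  expect_equal(lengths(sp[c("train", "val", "test")]),
               c(train = 6601L, val = 6601L, test = 6600L))
  expect_equal(lengths(split_dataset(3, 1)[1:3]),
               c(train = 1L, val = 1L, test = 1L))
  expect_error(split_dataset(2, 1), "at least 3")

  for (n in c(10, 101, 1234)) {
    sp <- split_dataset(n, seed = n)
    idx <- c(sp$train, sp$val, sp$test)
    expect_equal(sort(idx), seq_len(n))
    sizes <- lengths(sp[c("train", "val", "test")])
    expect_lte(max(sizes) - min(sizes), 1)
    expect_true(all(diff(sizes) <= 0))  # train >= val >= test
  }
  expect_identical(split_dataset(100, 7), split_dataset(100, 7))
  expect_false(identical(split_dataset(100, 7)$train,
                         split_dataset(100, 8)$train))
})

test_that("AUROC equals the all-pairs concordance oracle", {
  set.seed(24)
  for (rep in 1:50) {
    n <- sample(4:30, 1)
    labels <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # provoke ties
    expect_equal(auroc(scores, labels), oracle_auroc(scores, labels))
  }
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(auroc(rep(1, 10), rep(0:1, 5)), 0.5)
  expect_warning(expect_true(is.na(auroc(1:4, rep(1, 4)))), "one class")
})

test_that("AUROC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(25)
  scores <- runif(200)
  labels <- rbinom(200, 1, plogis(3 * scores - 1.5))
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auroc(scores, labels), ref, tolerance = 1e-12)
})

test_that("F1 and AUPR follow their definitions on a worked example", {
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.2, 0.1)
  labels <- c(1, 1, 0, 1, 0, 0)
  # thresholds down the list: prec 1, 1, 2/3, 3/4; recall 1/3, 2/3, 2/3, 1
  expect_equal(aupr(scores, labels), 1/3 * 1 + 1/3 * 1 + 0 + 1/3 * 3/4)
  # at cutoff 0.5: TP 3, FP 1, FN 0
  expect_equal(f1_score(scores, labels), 2 * 3 / (2 * 3 + 1 + 0))
  expect_equal(f1_score(c(0.1, 0.2), c(0, 0)), NA_real_)
  expect_warning(expect_true(is.na(aupr(scores, rep(1, 6)))), "one class")
})

test_that("a separable 1-D problem yields a positive weight and AUROC 1", {
  phi <- matrix(rep(c(0, 10), each = 10), ncol = 1,
                dimnames = list(NULL, "mk"))
  labels <- rep(c(0L, 1L), each = 10)
  fit <- fit_logistic(phi, labels)
  expect_true(fit$separation)
  expect_gt(fit$w[["mk"]], 0)
  expect_equal(auroc(predict(fit, phi), labels), 1.0)
  expect_error(significance_test(fit), "separation")
})

test_that("the fit recovers a planted logistic model within 3 SEs", {
  set.seed(26)
  n <- 5000
  phi <- cbind(phi1 = rlnorm(n, log(3), 0.5), phi2 = rlnorm(n, log(3), 0.5))
  eta <- -1 + 0.8 * phi[, 1] - 0.5 * phi[, 2]
  labels <- rbinom(n, 1, plogis(eta))
  fit <- fit_logistic(phi, labels)
  expect_false(fit$separation)
  expect_equal(length(fit$w), 2L)
  expect_lt(abs(fit$b - (-1)) / fit$se_b, 3)
  expect_lt(abs(fit$w[["phi1"]] - 0.8) / fit$se[["phi1"]], 3)
  expect_lt(abs(fit$w[["phi2"]] - (-0.5)) / fit$se[["phi2"]], 3)
  expect_equal(unname(fit$z), unname(fit$w / fit$se))
})

test_that("fitting rejects degenerate labels and keeps m+1 parameters", {
  phi <- matrix(rlnorm(100 * 5), 100, 5, dimnames = list(NULL, CORE_MARKS))
  expect_error(fit_logistic(phi, rep(1L, 100)), "single class")
  labels <- rep(c(0L, 1L), 50)
  fit <- fit_logistic(phi, labels)
  expect_equal(length(fit$w) + length(fit$b), 6L)
})

test_that("gene order permutation leaves weights and metrics unchanged", {
  fx <- generate_fixture(fixture_spec(n_genes = 300, seed = 31))
  phi <- build_feature_matrix(fx$genes, lapply(fx$tracks, `[[`, "narrow"))
  labels <- binarise(fx$expression, fx$truth$class_threshold)
  fit0 <- fit_logistic(phi, labels)
  set.seed(32)
  perm <- sample.int(nrow(phi))
  fit1 <- fit_logistic(phi[perm, ], labels[perm])
  expect_equal(fit0$w, fit1$w, tolerance = 1e-8)
  expect_equal(fit0$b, fit1$b, tolerance = 1e-8)
  expect_equal(auroc(predict(fit0, phi), labels),
               auroc(predict(fit1, phi[perm, ]), labels[perm]))
})

test_that("hyperparameter search picks the label-informative dialect", {
  fx <- generate_fixture(fixture_spec(
    n_genes = 300, marks = "H3K4me3", w_star = 1.2, sparsity = 0.2,
    informative_dialect = c(H3K4me3 = "gapped"), seed = 33))
  labels <- binarise(fx$expression, fx$truth$class_threshold)
  feature_sets <- list(H3K4me3 = lapply(fx$tracks$H3K4me3, function(pk)
    build_feature_matrix(fx$genes, list(H3K4me3 = pk))[, 1]))
  sp <- split_dataset(300, seed = 34)
  sel <- select_hyperparameters(feature_sets, labels, sp)
  expect_equal(unname(sel$H["H3K4me3"]), "gapped")
  expect_equal(sel$n_evaluated, 3L)

  single <- list(H3K4me3 = feature_sets$H3K4me3["narrow"])
  sel1 <- select_hyperparameters(single, labels, sp)
  expect_equal(sel1$n_evaluated, 1L)
  expect_equal(unname(sel1$H), "narrow")
})

test_that("exhaustive search enumerates the full dialect product", {
  set.seed(35)
  n <- 60
  labels <- rep(c(0L, 1L), n / 2)
  feature_sets <- lapply(stats::setNames(nm = CORE_MARKS), function(h)
    list(narrow = rnorm(n)^2, broad = rnorm(n)^2, gapped = rnorm(n)^2))
  sp <- split_dataset(n, seed = 36)
  sel <- select_hyperparameters(feature_sets, labels, sp)
  expect_equal(sel$n_evaluated, 3L^5)
  # greedy fallback when the product is capped
  expect_message(selg <- select_hyperparameters(feature_sets, labels, sp,
                                                max_exhaustive = 100),
                 "greedy")
  expect_lt(selg$n_evaluated, 3L^5)
})

test_that("selection never returns a strictly dominated configuration", {
  set.seed(37)
  n <- 90
  labels <- rbinom(n, 1, 0.5)
  labels[1:2] <- c(0L, 1L)
  feature_sets <- list(mkA = list(narrow = runif(n), broad = runif(n)),
                       mkB = list(narrow = runif(n), gapped = labels + runif(n)))
  sp <- split_dataset(n, seed = 38)
  sel <- select_hyperparameters(feature_sets, labels, sp)
  for (dA in c("narrow", "broad")) for (dB in c("narrow", "gapped")) {
    phi <- cbind(mkA = feature_sets$mkA[[dA]], mkB = feature_sets$mkB[[dB]])
    fit <- fit_logistic(phi[sp$train, ], labels[sp$train])
    a <- auroc(predict(fit, phi[sp$val, ]), labels[sp$val])
    expect_lte(a, sel$val_auroc + 1e-12)
  }
})

test_that("the repeated-split experiment reports k splits with spread", {
  fx <- generate_fixture(fixture_spec(n_genes = 240, seed = 39))
  phi <- build_feature_matrix(fx$genes, lapply(fx$tracks, `[[`, "narrow"))
  labels <- binarise(fx$expression, median_threshold(fx$expression),
                     rule = "median")
  feature_sets <- lapply(stats::setNames(nm = colnames(phi)),
                         function(h) list(narrow = phi[, h]))
  rep10 <- run_experiment(feature_sets, labels, k = 5, seed = 40)
  expect_equal(nrow(rep10$per_split), 5L)
  expect_true(all(rep10$per_split$auroc >= 0 & rep10$per_split$auroc <= 1))
  expect_gte(rep10$mean[["auroc"]], min(rep10$per_split$auroc))
  expect_lte(rep10$mean[["auroc"]], max(rep10$per_split$auroc))
  expect_gt(rep10$mean[["auroc"]], 0.75)  # planted signal is learnable
  # deterministic under the master seed
  rep10b <- run_experiment(feature_sets, labels, k = 5, seed = 40)
  expect_equal(rep10$per_split$auroc, rep10b$per_split$auroc)
  # k = 1: spread undefined
  rep1 <- run_experiment(feature_sets, labels, k = 1, seed = 41)
  expect_true(is.na(rep1$sd[["auroc"]]))
})
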