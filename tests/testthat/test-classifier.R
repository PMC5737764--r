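test_that("precision and recall follow the TP formulas with NA when undefined", {
  expect_equal(precision(8, 2), 0.8)
  expect_equal(recall(8, 2), 0.8)
  expect_true(is.na(precision(0, 0)))
  expect_true(is.na(recall(0, 0)))
  expect_error(precision(-1, 2), "non-negative",
               class = "varmoi_validation_error")
  set.seed(5)
  for (i in 1:20) {
    tp <- sample(0:30, 1); fp <- sample(0:30, 1); fn <- sample(0:30, 1)
    if (tp + fp > 0) expect_equal(precision(tp, fp), tp / (tp + fp))
    if (tp + fn > 0) expect_equal(recall(tp, fn), tp / (tp + fn))
  }
})

test_that("two-class Hand-Till AUC equals exact pairwise enumeration", {
  set.seed(6)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    lab <- sample(c("benign", "dominant"), n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    s_dom <- round(runif(n), 2)  # rounding forces ties
    scores <- cbind(benign = 1 - s_dom, dominant = s_dom)
    expect_equal(multiclass_auc(scores, lab),
                 brute_auc(s_dom, lab == "dominant"))
  }
})

test_that("multiclass AUC hits 1 on perfect separation and 0.5 on noise", {
  n <- 999
  lab <- rep(c("benign", "dominant", "recessive"), each = n / 3)
  perfect <- t(vapply(lab, function(l) {
    p <- c(benign = 0.05, dominant = 0.05, recessive = 0.05)
    p[l] <- 0.9
    p
  }, numeric(3)))
  expect_equal(multiclass_auc(perfect, lab), 1)
  set.seed(7)
  shuffled <- perfect[sample.int(n), ]
  expect_lt(abs(multiclass_auc(shuffled, lab) - 0.5), 0.05)
  expect_error(multiclass_auc(perfect, rep("benign", n)),
               "two classes", class = "varmoi_validation_error")
})

test_that("pairwise AUC is invariant under strictly monotone transforms", {
  set.seed(8)
  lab <- sample(c("benign", "dominant", "recessive"), 120, replace = TRUE)
  raw <- matrix(runif(360), ncol = 3,
                dimnames = list(NULL, c("benign", "dominant", "recessive")))
  a0 <- multiclass_auc(raw, lab)
  mono <- raw
  mono[, "benign"] <- exp(3 * mono[, "benign"])
  mono[, "dominant"] <- qlogis(mono[, "dominant"] * 0.98 + 0.01)
  mono[, "recessive"] <- mono[, "recessive"]^3
  expect_equal(multiclass_auc(mono, lab), a0)
})

test_that("training is deterministic, separable data scores high, and
           degenerate inputs behave", {
  fm <- simulate_feature_matrix(n_per_class = c(benign = 60, dominant = 60,
                                                recessive = 60),
                                delta = 4, seed = 9)
  m1 <- moi_train(fm, ntree = 150, seed = 42)
  m2 <- moi_train(fm, ntree = 150, seed = 42)
  s1 <- score_variants(m1, fm)
  s2 <- score_variants(m2, fm)
  expect_identical(s1$dominant_score, s2$dominant_score)
  # strong separation: training-set argmax accuracy > 0.95
  acc <- mean(s1$class_call == as.character(fm$labels))
  expect_gt(acc, 0.95)
  # single-class input refused
  fm1 <- fm; fm1$labels <- factor(rep("benign", nrow(fm$x)),
                                  levels = levels(fm$labels))
  expect_error(moi_train(fm1, ntree = 50), "two classes",
               class = "varmoi_validation_error")
  # duplicated rows carrying conflicting labels: no signal, probabilities
  # near the class priors
  set.seed(31)
  base <- matrix(rnorm(30 * 3), 30, 3,
                 dimnames = list(NULL, c("f1", "f2", "f3")))
  xdup <- base[rep(1:30, each = 2), ]
  fmdup <- structure(list(
    x = xdup, ids = data.frame(row = 1:60),
    labels = factor(rep(c("benign", "dominant"), 30),
                    levels = c("benign", "dominant", "recessive")),
    catalogue = default_catalogue(), encoding = list(), fills = NULL),
    class = "moi_matrix")
  md <- moi_train(fmdup, ntree = 400, seed = 1)
  pr <- predict(md$forest, xdup, type = "prob")
  expect_lt(abs(mean(pr[, "benign"]) - 0.5), 0.15)
  expect_lt(abs(mean(pr[, "dominant"]) - 0.5), 0.15)
})

test_that("cross-validation partitions rows, is deterministic, and guards
           small classes", {
  fm <- simulate_feature_matrix(n_per_class = c(benign = 40, dominant = 40,
                                                recessive = 40),
                                delta = 3, seed = 10)
  cv1 <- cross_validate(fm, folds = 5, repeats = 2, ntree = 60, seed = 13)
  cv2 <- cross_validate(fm, folds = 5, repeats = 2, ntree = 60, seed = 13)
  expect_identical(cv1$per_repeat, cv2$per_repeat)
  # partition property: per repeat, confusion totals cover every row once
  tot <- cv1$per_fold[, list(n = sum(tp + fn)), by = "repeat"]
  expect_equal(tot$n, c(120, 120))
  expect_gt(mean(cv1$per_repeat$auc), 0.9)
  tiny <- simulate_feature_matrix(n_per_class = c(benign = 4, dominant = 40,
                                                  recessive = 40),
                                  delta = 1, seed = 1)
  expect_error(cross_validate(tiny, folds = 10, repeats = 1, ntree = 20),
               "fewer than", class = "varmoi_validation_error")
})

test_that("per-gene resampling differs across repeats but not across reruns", {
  fx <- annotated_fixture()
  cv <- cross_validate(fx$ann, labels = fx$labels, folds = 4, repeats = 2,
                       ntree = 60, seed = 3)
  expect_equal(nrow(cv$per_repeat), 2L)
  expect_true(all(cv$per_repeat$auc > 0.8))  # delta = 3 fixture
})

test_that("permutation importance zeroes constants and ranks signal first", {
  fm <- simulate_feature_matrix(n_per_class = c(benign = 70, dominant = 70,
                                                recessive = 70),
                                n_signal = 1, n_noise = 6, delta = 3,
                                seed = 11)
  fm$x <- cbind(fm$x, constant = 5)
  fm$catalogue <- rbind(fm$catalogue,
                        data.frame(name = "constant", type = "numeric",
                                   levels = NA_character_))
  m <- moi_train(fm, ntree = 250, seed = 2)
  imp <- permutation_importance(m)
  expect_equal(imp$importance[imp$feature == "constant"], 0)
  expect_equal(imp$feature[1], "signal01")
  noise_imp <- imp$importance[grepl("^noise", imp$feature)]
  expect_true(all(abs(noise_imp) < max(imp$importance) / 2))
})
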