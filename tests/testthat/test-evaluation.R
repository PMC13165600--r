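test_that("confusion matrices tabulate with the fixed class order", {
  obs <- rep(activity_levels(), each = 10)
  cm <- confusion_matrix(obs, obs)
  expect_equal(unname(diag(unclass(cm))), c(10, 10, 10))
  expect_equal(sum(unclass(cm)) - sum(diag(unclass(cm))), 0)
  expect_equal(rownames(cm), activity_levels())

  single <- confusion_matrix("running", "jumping")
  expect_equal(unclass(single)["jumping", "running"], 1L, ignore_attr = TRUE)
  expect_equal(sum(unclass(single)), 1L)

  expect_error(confusion_matrix("walking", "sprinting"), "level")
})

test_that("percent agreement is the diagonal share of the total", {
  perfect <- as_confusion_matrix(diag(c(5, 7, 9)))
  expect_equal(percent_agreement(perfect), 100)
  wrong <- as_confusion_matrix(matrix(c(0, 3, 3, 3, 0, 3, 3, 3, 0), 3, 3))
  expect_equal(percent_agreement(wrong), 0)
})

test_that("kappa is 1 only at perfect agreement and 0 under degeneracy", {
  expect_equal(cohens_kappa(as_confusion_matrix(diag(c(4, 4, 4)))), 1)
  cm <- as_confusion_matrix(matrix(c(8, 1, 0, 2, 7, 1, 0, 1, 10), 3, 3))
  expect_lt(cohens_kappa(cm), 1)
  degenerate <- as_confusion_matrix(matrix(c(5, 0, 0, 0, 0, 0, 0, 0, 0),
                                           3, 3))
  expect_warning(k <- cohens_kappa(degenerate), "undefined")
  expect_equal(k, 0)
})

test_that("kappa under label permutation is centered on zero", {
  withr::with_seed(31, {
    obs <- sample(activity_levels(), 120, replace = TRUE,
                  prob = c(0.4, 0.2, 0.4))
    pred <- sample(activity_levels(), 120, replace = TRUE)
    kappas <- vapply(1:50, function(i) {
      cohens_kappa(confusion_matrix(sample(obs), pred))
    }, numeric(1))
  })
  se <- sd(kappas) / sqrt(length(kappas))
  expect_lt(abs(mean(kappas)), 3 * se)
})

test_that("one-vs-all AUC hits the extremes on one-hot scores", {
  obs <- rep(activity_levels(), each = 4)
  onehot <- outer(obs, activity_levels(), `==`) * 1
  colnames(onehot) <- activity_levels()
  expect_equal(unname(roc_auc_ova(obs, onehot)$per_class), c(1, 1, 1))

  # anti-ranked scores: every negative outranks every positive
  anti <- 1 - onehot
  expect_equal(unname(roc_auc_ova(obs, anti)$per_class), c(0, 0, 0))
})

test_that("AUC equals the exhaustive pairwise oracle, ties included", {
  obs6 <- c("walking", "walking", "running", "running", "jumping",
            "jumping")
  p <- matrix(c(0.9, 0.6, 0.3, 0.2, 0.1, 0.3,
                0.05, 0.2, 0.5, 0.5, 0.2, 0.3,
                0.05, 0.2, 0.2, 0.3, 0.7, 0.4), 6, 3,
              dimnames = list(NULL, activity_levels()))
  got <- roc_auc_ova(obs6, p)$per_class
  for (cl in activity_levels()) {
    expect_equal(unname(got[cl]), auc_pair_oracle(obs6 == cl, p[, cl]),
                 label = cl)
  }
  withr::with_seed(55, {
    for (i in 1:40) {
      n <- sample(3:12, 1)
      obs <- sample(activity_levels(), n, replace = TRUE)
      scores <- matrix(sample(seq(0, 1, 0.25), 3 * n, replace = TRUE),
                       n, 3, dimnames = list(NULL, activity_levels()))
      got <- suppressWarnings(roc_auc_ova(obs, scores)$per_class)
      for (cl in activity_levels()) {
        expect_equal(unname(got[cl]),
                     auc_pair_oracle(obs == cl, scores[, cl]))
      }
    }
  })
})

test_that("a class absent from the observed labels is excluded with warning", {
  obs <- rep(c("walking", "running"), 5)
  p <- matrix(runif(30), 10, 3, dimnames = list(NULL, activity_levels()))
  expect_warning(auc <- roc_auc_ova(obs, p), "jumping")
  expect_true(is.na(auc$per_class["jumping"]))
  expect_false(is.na(auc$macro))
})

test_that("per-class metrics collapse the 3x3 table to one-vs-rest", {
  obs <- rep(activity_levels(), each = 6)
  cm <- confusion_matrix(obs, obs)
  onehot <- outer(obs, activity_levels(), `==`) * 1
  colnames(onehot) <- activity_levels()
  pc <- per_class_metrics(cm, obs, onehot)
  expect_equal(pc$percent_agreement, rep(100, 3))
  expect_equal(pc$kappa, rep(1, 3))
  expect_equal(pc$roc_auc, rep(1, 3))

  refs <- reference_confusion_matrices()
  collapsed <- binary_collapse(refs$rf, "walking")
  expect_equal(as.vector(collapsed), c(480, 11, 16, 1015))

  # all-"walking" predictor: walking OVA agreement equals its prevalence
  pred <- rep("walking", length(obs))
  cm2 <- confusion_matrix(obs, pred)
  pc2 <- per_class_metrics(cm2)
  expect_equal(pc2$percent_agreement[pc2$activity == "walking"],
               100 * mean(obs == "walking"))
})

test_that("metrics are invariant to observation order", {
  withr::with_seed(70, {
    obs <- sample(activity_levels(), 60, replace = TRUE)
    pred <- sample(activity_levels(), 60, replace = TRUE)
    ord <- sample(60)
  })
  cm1 <- confusion_matrix(obs, pred)
  cm2 <- confusion_matrix(obs[ord], pred[ord])
  expect_identical(cm1, cm2)
  expect_equal(cohens_kappa(cm1), cohens_kappa(cm2))
})

test_that("permutation importance isolates the predictive feature", {
  # feature 1 fully determines the class; the rest are noise
  fm <- separable_matrix(n_participants = 8, windows_each = 9, seed = 17)
  keep <- c("participant_id", "placement", "label", "window_index",
            feature_names()[1:6])
  fm <- fm[, keep]
  for (f in feature_names()[2:6]) {
    fm[[f]] <- withr::with_seed(800 + match(f, feature_names()),
                                rnorm(nrow(fm)))
  }
  spec <- classifier_spec("knn", seed = 2)
  model <- fit_final(fm, spec, data.frame(n_neighbors = 3))
  test_rows <- separable_matrix(n_participants = 4, windows_each = 9,
                                seed = 18)[, keep]
  for (f in feature_names()[2:6]) {
    test_rows[[f]] <- withr::with_seed(900 + match(f, feature_names()),
                                       rnorm(nrow(test_rows)))
  }
  imp <- permutation_importance(model, test_rows, n_repeats = 10, seed = 5)
  expect_equal(imp$feature[1], feature_names()[1])
  expect_true(all(imp$importance[1] >= imp$importance))
  # null features sit within 2 permutation SDs of zero
  null_rows <- imp[imp$feature != feature_names()[1], ]
  expect_true(all(abs(null_rows$importance) <=
                    2 * pmax(null_rows$sd, 1e-9)))
  imp2 <- permutation_importance(model, test_rows, n_repeats = 10, seed = 5)
  expect_identical(imp, imp2)
  expect_error(permutation_importance(model, test_rows, n_repeats = 0),
               "n_repeats")
})

test_that("evaluation reports carry coherent overall and per-class blocks", {
  fm <- separable_matrix()
  test_rows <- separable_matrix(n_participants = 4, seed = 21)
  model <- fit_final(fm, classifier_spec("knn", seed = 1),
                     data.frame(n_neighbors = 3))
  rep <- evaluate_classifier(model, test_rows)
  expect_s3_class(rep, "evaluation_report")
  expect_true(rep$overall$percent_agreement >= 0 &&
                rep$overall$percent_agreement <= 100)
  expect_true(rep$overall$kappa >= -1 && rep$overall$kappa <= 1)
  expect_equal(sum(unclass(rep$confusion)), nrow(test_rows))
  expect_equal(unname(colSums(unclass(rep$confusion))),
               unname(table(activity_factor(test_rows$label)))[
                 seq_along(activity_levels())], ignore_attr = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$overall$percent_agreement,
               rep$overall$percent_agreement)
})
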