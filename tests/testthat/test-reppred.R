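# Template ranking: homolog removal, drift validation, quantile transform,
# SVR training, selection/abstention and the leave-one-out benchmark.

fast_spec <- function(seed = 1L) {
  regression_spec(cost_grid = 10^(-1:3), epsilon_grid = 10^(-3:0),
                  n_folds = 3L, seed = seed)
}

test_that("homolog removal uses the Hamming <= 3 rule with a sharp boundary", {
  tg <- c(T1 = "GILGFVFTL")
  tm <- c(M0 = "GILGFVFTL",   # identical: hamming 0
          M3 = "GILGFVAAA",   # hamming 3
          M4 = "GILGFAAAA",   # hamming 4
          M9 = "AAAAAAAAA")
  pairs <- remove_homologs(tg, tm)
  expect_setequal(pairs$template_id, c("M4", "M9"))
  expect_equal(pairs$hamming[pairs$template_id == "M4"], 4)
  # length mismatch is skipped, not an error
  expect_message(out <- remove_homologs(c(T1 = "GILGFVFTL"),
                                        c(MX = "GILGFVFT")),
                 "length-mismatched")
  expect_equal(nrow(out), 0)
  expect_error(hamming("AB", "ABC"))
})

test_that("drift validation drops models past the limit, found by dialing phi", {
  template <- build_backbone(9, -75, 145)
  expect_true(validate_drift(template, template)$keep)
  # dial phi at P5 until the metric crosses 1.5: D = 2(1-cos d) for a single
  # perturbed angle, so the crossing sits at acos(0.25) = 75.5 degrees
  for (delta in c(20, 45, 60, 75, 76, 90)) {
    phi <- rep(-75, 9); phi[5] <- -75 + delta
    model <- build_backbone(9, phi, 145)
    v <- validate_drift(model, template)
    expect_equal(v$keep, v$dscore <= 1.5)
    expect_equal(v$dscore, 2 * (1 - cos(delta * pi / 180)), tolerance = 1e-9)
  }
  # the stricter template-stability limit removes a relaxed template at 1.2
  phi <- rep(-75, 9); phi[5] <- -75 + 66    # D = 2(1-cos 66) ~ 1.19
  relaxed <- build_backbone(9, phi, 145)
  d <- dscore(relaxed, template)
  expect_true(d > 1.0 && d < 1.5)
  expect_false(validate_drift(relaxed, template, limit = 1.0)$keep)
  expect_true(validate_drift(relaxed, template, limit = 1.5)$keep)
})

test_that("the quantile transform maps training features to uniform [0,1]", {
  set.seed(23)
  x <- cbind(rexp(400), rnorm(400, 10, 3), runif(400, -5, 5))
  qt <- fit_quantile_transform(x)
  u <- predict(qt, x)
  expect_true(all(u >= 0 & u <= 1))
  # near-uniform margins on the training data
  for (j in 1:3) {
    expect_lt(suppressWarnings(ks.test(u[, j], "punif"))$statistic, 0.05)
  }
  # monotone in each feature, clamped outside the training range
  probe <- predict(qt, cbind(c(-1, 0.5, 100), c(0, 10, 100), c(-10, 0, 10)))
  expect_true(all(diff(probe[, 1]) >= 0))
  expect_equal(probe[3, 1], 1)
  expect_equal(probe[1, 2], 0)
  # constant features map to 0.5
  qc <- fit_quantile_transform(cbind(rep(7, 50)))
  expect_true(all(predict(qc, cbind(c(1, 7, 9))) == 0.5))
})

test_that("SVR recovers a planted linear relation with high held-out R2", {
  spec <- synthetic_feature_spec(n_targets = 25, n_templates = 8,
                                 noise_sd = 0.02, seed = 5)
  tab <- make_feature_table(spec)$candidates
  set.seed(99)
  hold <- sample(nrow(tab), 40)
  fit <- train_svr(tab[-hold, ], fast_spec())
  pred <- predict(fit, tab[hold, ])
  r2 <- 1 - sum((tab$true_dscore[hold] - pred)^2) /
    sum((tab$true_dscore[hold] - mean(tab$true_dscore[hold]))^2)
  expect_gt(r2, 0.9)
  expect_true(all(is.finite(predict(fit, tab))))
})

test_that("training rows above the D-score cap are excluded from the fit", {
  spec <- synthetic_feature_spec(n_targets = 10, n_templates = 6, seed = 7)
  tab <- make_feature_table(spec)$candidates
  n_ok <- sum(tab$true_dscore <= 7)
  extra <- tab[1:5, ]
  extra$true_dscore <- 7.5
  fit <- train_svr(rbind(tab, extra), fast_spec())
  expect_equal(fit$n_train, n_ok)
  expect_error(train_svr(tab[1:5, ], fast_spec()), "at least 10")
})

test_that("selection is the argmin of predictions, with the abstention rule", {
  spec <- synthetic_feature_spec(n_targets = 12, n_templates = 6,
                                 noise_sd = 0.05, seed = 9)
  tab <- make_feature_table(spec)$candidates
  fit <- train_svr(tab, fast_spec())
  set.seed(31)
  for (k in 1:50) {
    rows <- tab[sample(nrow(tab), 8), ]
    sel <- rank_and_select(rows, fit)
    expect_false(sel$abstained)
    expect_equal(sel$selected, which.min(predict(fit, rows)))
  }
  # abstention: a minimum prediction at/above the threshold reports nothing
  rows <- tab[tab$true_dscore > 2.2 & tab$true_dscore < 6, ][1:5, ]
  preds <- predict(fit, rows)
  thr <- min(preds) - 0.01
  expect_false(rank_and_select(rows, fit, abstain_threshold = thr + 0.02)$abstained)
  expect_true(rank_and_select(rows, fit,
                              abstain_threshold = min(preds))$abstained)
  none <- rank_and_select(tab[0, ], fit)
  expect_true(none$abstained)
  expect_equal(none$reason, "no_candidates")
})

test_that("leave-one-out benchmark is perfect with oracle features", {
  spec <- synthetic_feature_spec(n_targets = 15, n_templates = 6,
                                 noise_sd = 0, seed = 11)
  tab <- make_feature_table(spec)$candidates
  bench <- loo_benchmark(tab, fast_spec(), baseline_draws = 50L)
  expect_equal(nrow(bench$per_target), 15)
  # every target's planted best template has true D-score <= 1.2 < 1.5, so
  # selection is near-perfect; the RBF regressor can flatten at the extreme
  # low edge of the training range and drop an occasional near-tie, so the
  # bound allows one miss
  expect_gte(bench$summary$accuracy, 14 / 15)
  # while random selection mostly picks dissimilar templates
  expect_lt(bench$summary$random_baseline, 0.4)
})

test_that("random features collapse accuracy toward the random baseline", {
  spec <- synthetic_feature_spec(n_targets = 15, n_templates = 6,
                                 noise_sd = 0, seed = 13)
  tab <- make_feature_table(spec)$candidates
  set.seed(77)
  fc <- grep("^f[0-9]+$", names(tab))
  tab[, fc] <- matrix(rnorm(nrow(tab) * length(fc)), nrow(tab))
  bench <- loo_benchmark(tab, fast_spec(), baseline_draws = 50L)
  # 15 targets, 1 near-native template in 6: random baseline ~1/6; with
  # uninformative features the success count should stay within binomial
  # noise of it (p < 0.51 covers >4 sd)
  expect_lt(bench$summary$accuracy, 0.55)
})

test_that("selected models beat random selection on noisy planted features", {
  spec <- synthetic_feature_spec(n_targets = 32, n_templates = 6,
                                 noise_sd = 0.4, seed = 15)
  tab <- make_feature_table(spec)$candidates
  bench <- loo_benchmark(tab, fast_spec(), baseline_draws = 20L)
  sel_true <- bench$per_target$true_dscore
  set.seed(123)
  rand_true <- vapply(unique(tab$target_id), function(tg) {
    sub <- tab[tab$target_id == tg, ]
    sub$true_dscore[sample.int(nrow(sub), 1)]
  }, 0.0)
  w <- wilcox.test(sel_true, rand_true, alternative = "less", exact = FALSE)
  expect_lt(w$p.value, 0.01)
})

test_that("no leakage: other folds' fits are unchanged by a held-out target", {
  spec <- synthetic_feature_spec(n_targets = 8, n_templates = 5,
                                 noise_sd = 0.1, seed = 17)
  tab <- make_feature_table(spec)$candidates
  # training without target T001 must be identical whether T001's rows are
  # deleted beforehand or excluded inside the fold loop
  train_a <- tab[tab$target_id != "T001", ]
  fit_a <- train_svr(train_a, fast_spec())
  fit_b <- train_svr(tab[tab$target_id != "T001", ], fast_spec())
  expect_identical(fit_a$best, fit_b$best)
  expect_identical(fit_a$transform$refs, fit_b$transform$refs)
  probe <- tab[tab$target_id == "T001", ]
  expect_equal(predict(fit_a, probe), predict(fit_b, probe))
})

test_that("predictor JSON persistence stores a versioned schema", {
  spec <- synthetic_feature_spec(n_targets = 10, n_templates = 5, seed = 19)
  tab <- make_feature_table(spec)$candidates
  fit <- train_svr(tab, fast_spec())
  tmp <- tempfile(fileext = ".json")
  write_predictor_json(fit, tmp)
  js <- jsonlite::fromJSON(tmp)
  expect_equal(js$schema, "phlatlas/dscore_predictor/1")
  expect_equal(js$cost, fit$best$cost)
  expect_equal(length(js$coefs), nrow(fit$svm$SV))
})
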