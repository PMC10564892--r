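# Template ranking by regression: candidate filtering (homolog removal,
# drift validation, D-score > 7 training filter), a uniform quantile
# transform of the per-residue energy features, RBF support-vector
# regression with grid-searched hyperparameters, leave-one-out
# benchmarking and the abstention rule.

#' Hamming distance between equal-length peptide sequences
#' @param a,b one-letter strings of equal length.
#' @return integer count of differing positions.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("length mismatch")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Remove homologous target-template pairs
#'
#' A template is a homolog of a target when their peptide sequences differ
#' at three or fewer positions; such pairs are excluded from modeling and
#' benchmarking.  Length-mismatched pairs are skipped with a note.
#'
#' @param targets named character vector of target peptide sequences.
#' @param templates named character vector of template peptide sequences.
#' @param max_mismatch homolog cutoff (default 3).
#' @return data.frame of allowed pairs: target_id, template_id, hamming.
#' @export
remove_homologs <- function(targets, templates, max_mismatch = 3) {
  rows <- list()
  skipped <- 0L
  for (ti in names(targets)) {
    for (mi in names(templates)) {
      if (nchar(targets[[ti]]) != nchar(templates[[mi]])) {
        skipped <- skipped + 1L
        next
      }
      h <- hamming(targets[[ti]], templates[[mi]])
      if (h > max_mismatch) {
        rows[[length(rows) + 1L]] <- data.frame(
          target_id = ti, template_id = mi, hamming = h,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (skipped > 0) message(skipped, " length-mismatched pairs skipped")
  if (!length(rows)) {
    return(data.frame(target_id = character(), template_id = character(),
                      hamming = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Drift validation of a relaxed model against its template
#'
#' A candidate model is kept only while its backbone stays within
#' `limit` D-score of the template crystal backbone (default 1.5).  The
#' stricter template-level stability limit (1.0) applies when screening
#' template relaxations before atlas reselection.
#'
#' @param model,template `peptide_backbone` objects.
#' @param limit D-score limit (1.5 for models, 1.0 for template stability).
#' @param anchor_class anchor class (default 7).
#' @return list with `keep` and `dscore` (NA with `keep = FALSE` when
#'   dihedrals are undefined).
#' @export
validate_drift <- function(model, template, limit = 1.5, anchor_class = 7) {
  d <- tryCatch(dscore(model, template, anchor_class), error = function(e) NA_real_)
  list(keep = !is.na(d) && d <= limit, dscore = d)
}

# ---- uniform quantile transform -------------------------------------------

#' Fit a uniform quantile transform
#'
#' Maps each feature through its empirical distribution function to an
#' approximately uniform [0, 1] output, interpolating between stored
#' training quantiles.  Out-of-range values clamp to 0/1; constant features
#' map to 0.5.
#'
#' @param x numeric matrix (rows = samples).
#' @param n_quantiles number of stored quantile landmarks (default
#'   `min(nrow(x), 1000)`).
#' @return object of class `quantile_transform`.
#' @export
fit_quantile_transform <- function(x, n_quantiles = min(nrow(x), 1000L)) {
  x <- as.matrix(x)
  probs <- seq(0, 1, length.out = max(n_quantiles, 2L))
  refs <- lapply(seq_len(ncol(x)), function(j) {
    unname(quantile(x[, j], probs = probs, type = 7, na.rm = FALSE))
  })
  structure(list(probs = probs, refs = refs, p = ncol(x),
                 colnames = colnames(x)),
            class = "quantile_transform")
}

#' @rdname fit_quantile_transform
#' @param object a fitted `quantile_transform`.
#' @param newdata matrix with the same columns as the training matrix.
#' @param ... unused.
#' @export
predict.quantile_transform <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  stopifnot(ncol(newdata) == object$p)
  out <- matrix(0, nrow(newdata), ncol(newdata),
                dimnames = dimnames(newdata))
  for (j in seq_len(ncol(newdata))) {
    r <- object$refs[[j]]
    if (max(r) == min(r)) {           # constant training feature
      out[, j] <- 0.5
      next
    }
    # average the forward and reverse interpolants so flat runs (ties) map
    # to the midpoint of their probability mass, as an ECDF-based uniform
    # transform should
    fwd <- approx(r, object$probs, xout = newdata[, j], ties = "min",
                  rule = 2)$y
    rev_ <- approx(rev(-r), rev(1 - object$probs), xout = -newdata[, j],
                   ties = "min", rule = 2)$y
    out[, j] <- (fwd + (1 - rev_)) / 2
  }
  out
}

# ---- SVR training ---------------------------------------------------------

#' Regression specification for template ranking
#'
#' @param cost_grid,epsilon_grid hyperparameter grids (default powers of ten
#'   spanning 1e-4..1e4).
#' @param n_folds inner cross-validation folds for the grid search
#'   (default 5).
#' @param dscore_cap training rows with true D-score above this are dropped
#'   (default 7).
#' @param seed seed for fold assignment.
#' @return list of class `regression_spec`.
#' @export
regression_spec <- function(cost_grid = 10^(-4:4), epsilon_grid = 10^(-4:4),
                            n_folds = 5L, dscore_cap = 7, seed = 1L) {
  stopifnot(length(cost_grid) > 0, length(epsilon_grid) > 0)
  structure(list(cost_grid = cost_grid, epsilon_grid = epsilon_grid,
                 n_folds = n_folds, dscore_cap = dscore_cap, seed = seed),
            class = "regression_spec")
}

.feature_cols <- function(df) grep("^f[0-9]+$", names(df), value = TRUE)

.r_squared <- function(obs, pred) {
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}

#' Train the D-score regressor
#'
#' Drops training rows with true D-score above the cap, fits the uniform
#' quantile transform on the training features, grid-searches the RBF-SVR
#' cost and epsilon by inner cross-validated R-squared, and refits on the
#' full training set with the best pair.  Nothing outside the supplied
#' training rows touches the transform or the grid search.
#'
#' @param training data.frame with `target_id`, `template_id`,
#'   `true_dscore`, and feature columns `f1..fF`.
#' @param spec a [regression_spec()].
#' @return object of class `dscore_predictor` with elements `svm`,
#'   `transform`, `best` (cost, epsilon, cv_r2), `features`.
#' @export
train_svr <- function(training, spec = regression_spec()) {
  fc <- .feature_cols(training)
  if (length(fc) == 0) stop("no feature columns f1..fF")
  training <- training[!is.na(training$true_dscore) &
                         training$true_dscore <= spec$dscore_cap, , drop = FALSE]
  if (nrow(training) < 10) stop("need at least 10 training rows")
  x <- as.matrix(training[, fc, drop = FALSE])
  y <- training$true_dscore
  qt <- fit_quantile_transform(x)
  xt <- predict(qt, x)
  n <- nrow(xt)
  folds <- local({
    set.seed(spec$seed)
    sample(rep_len(seq_len(spec$n_folds), n))
  })
  best <- list(cost = NA, epsilon = NA, cv_r2 = -Inf)
  for (C in spec$cost_grid) {
    for (eps in spec$epsilon_grid) {
      pred <- rep(NA_real_, n)
      for (f in seq_len(spec$n_folds)) {
        tr <- folds != f
        if (sum(tr) < 2 || sum(!tr) < 1) next
        fit <- e1071::svm(x = xt[tr, , drop = FALSE], y = y[tr],
                          type = "eps-regression", kernel = "radial",
                          cost = C, epsilon = eps, scale = FALSE)
        pred[!tr] <- predict(fit, xt[!tr, , drop = FALSE])
      }
      ok <- !is.na(pred)
      r2 <- .r_squared(y[ok], pred[ok])
      if (r2 > best$cv_r2) best <- list(cost = C, epsilon = eps, cv_r2 = r2)
    }
  }
  final <- e1071::svm(x = xt, y = y, type = "eps-regression",
                      kernel = "radial", cost = best$cost,
                      epsilon = best$epsilon, scale = FALSE)
  structure(list(svm = final, transform = qt, best = best, features = fc,
                 n_train = n),
            class = "dscore_predictor")
}

#' @export
print.dscore_predictor <- function(x, ...) {
  cat(sprintf("dscore_predictor: RBF-SVR, cost %g, epsilon %g (cv R2 %.3f), %d features\n",
              x$best$cost, x$best$epsilon, x$best$cv_r2, length(x$features)))
  invisible(x)
}

#' Predict D-scores for candidate models
#'
#' @param object a `dscore_predictor`.
#' @param newdata data.frame with the same feature columns.
#' @param ... unused.
#' @return numeric predicted D-scores.
#' @export
predict.dscore_predictor <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  as.numeric(predict(object$svm, predict(object$transform, x)))
}

#' Rank a target's candidate models and select or abstain
#'
#' Returns the candidate with the lowest predicted D-score.  When an
#' abstention threshold is set (2.0 for non-A02 targets), no model is
#' reported if even the best prediction reaches the threshold.
#'
#' @param candidates data.frame of one target's candidate models (feature
#'   columns `f1..fF`, plus `template_id`).
#' @param predictor a `dscore_predictor`.
#' @param abstain_threshold optional threshold; `NULL` disables abstention.
#' @return list with `selected` (row index or NA), `template_id`,
#'   `predicted`, `abstained`, `reason`.
#' @export
rank_and_select <- function(candidates, predictor, abstain_threshold = NULL) {
  if (nrow(candidates) == 0) {
    return(list(selected = NA_integer_, template_id = NA_character_,
                predicted = NA_real_, abstained = TRUE,
                reason = "no_candidates"))
  }
  pred <- predict(predictor, candidates)
  i <- which.min(pred)
  if (!is.null(abstain_threshold) && pred[i] >= abstain_threshold) {
    return(list(selected = NA_integer_, template_id = NA_character_,
                predicted = pred[i], abstained = TRUE,
                reason = "min_prediction_at_or_above_threshold"))
  }
  list(selected = i, template_id = candidates$template_id[i],
       predicted = pred[i], abstained = FALSE, reason = NA_character_)
}

#' Leave-one-target-out benchmark
#'
#' For each target, all of its rows are removed, the regressor (transform
#' included) is refit on the remaining targets, the held-out target's
#' candidates are ranked, and the selection is scored against the known
#' true D-score: success means the selected model's true D-score is at or
#' below `success_threshold`.
#'
#' @param candidates data.frame of all candidate models (`target_id`,
#'   `template_id`, `true_dscore`, `f1..fF`), already homolog-filtered.
#' @param spec a [regression_spec()].
#' @param success_threshold D-score defining a successful model
#'   (default 1.5, the Delta-7 neighbor criterion).
#' @param abstain_threshold optional abstention threshold passed through to
#'   selection.
#' @param baseline_draws random-template draws per target for the
#'   random-selection baseline (default 100; seeded from `spec$seed`).
#' @return list with `per_target` (data.frame) and `summary` (overall
#'   accuracy, accuracy in the most common target class vs the rest, and
#'   the random baseline).
#' @export
loo_benchmark <- function(candidates, spec = regression_spec(),
                          success_threshold = 1.5, abstain_threshold = NULL,
                          baseline_draws = 100L) {
  fc <- .feature_cols(candidates)
  targets <- unique(candidates$target_id)
  rows <- list()
  for (tg in targets) {
    test <- candidates[candidates$target_id == tg, , drop = FALSE]
    train <- candidates[candidates$target_id != tg, , drop = FALSE]
    out <- tryCatch({
      pr <- train_svr(train, spec)
      sel <- rank_and_select(test, pr, abstain_threshold)
      if (sel$abstained) {
        data.frame(target_id = tg, template_id = NA_character_,
                   predicted = sel$predicted, true_dscore = NA_real_,
                   success = FALSE, abstained = TRUE,
                   reason = sel$reason, stringsAsFactors = FALSE)
      } else {
        td <- test$true_dscore[sel$selected]
        data.frame(target_id = tg, template_id = sel$template_id,
                   predicted = sel$predicted, true_dscore = td,
                   success = td <= success_threshold, abstained = FALSE,
                   reason = NA_character_, stringsAsFactors = FALSE)
      }
    }, error = function(e) {
      data.frame(target_id = tg, template_id = NA_character_,
                 predicted = NA_real_, true_dscore = NA_real_,
                 success = FALSE, abstained = TRUE,
                 reason = conditionMessage(e), stringsAsFactors = FALSE)
    })
    rows[[tg]] <- out
  }
  per_target <- do.call(rbind, rows)
  rownames(per_target) <- NULL
  # Target class = nearest template by true D-score; the most common class
  # plays the role of the dominant backbone.
  nearest <- vapply(targets, function(tg) {
    sub <- candidates[candidates$target_id == tg, , drop = FALSE]
    sub$template_id[which.min(sub$true_dscore)]
  }, "")
  common <- names(sort(table(nearest), decreasing = TRUE))[1]
  in_common <- nearest == common
  # Random-selection baseline.
  base <- local({
    set.seed(spec$seed + 1L)
    mean(vapply(seq_len(baseline_draws), function(k) {
      mean(vapply(targets, function(tg) {
        sub <- candidates[candidates$target_id == tg, , drop = FALSE]
        sub$true_dscore[sample.int(nrow(sub), 1)] <= success_threshold
      }, TRUE))
    }, 0.0))
  })
  summary <- list(
    n_targets = length(targets),
    accuracy = mean(per_target$success),
    accuracy_common_class = mean(per_target$success[in_common]),
    accuracy_other_classes = mean(per_target$success[!in_common]),
    most_common_class = common,
    random_baseline = base)
  list(per_target = per_target, summary = summary)
}

# ---- model persistence ----------------------------------------------------

#' Persist a fitted predictor as JSON
#'
#' Versioned schema storing the hyperparameters, the quantile landmarks and
#' the support vectors/coefficients needed to re-instantiate prediction.
#'
#' @param predictor a `dscore_predictor`.
#' @param path output file.
#' @export
write_predictor_json <- function(predictor, path) {
  s <- predictor$svm
  payload <- list(
    schema = "phlatlas/dscore_predictor/1",
    kernel = "radial", cost = predictor$best$cost,
    epsilon = predictor$best$epsilon, gamma = s$gamma,
    rho = s$rho, coefs = as.numeric(s$coefs),
    support_vectors = unname(as.matrix(s$SV)),
    features = predictor$features,
    transform = list(probs = predictor$transform$probs,
                     refs = predictor$transform$refs))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
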