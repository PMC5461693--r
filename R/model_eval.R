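#' Fit an elastic-net efficiency classifier
#'
#' Features are centered/scaled on the training data (the scaling is stored in
#' the fit), constant columns are dropped with a warning, and the penalty
#' strength is chosen by 10-fold cross-validation on the training set
#' (`lambda.min`). Binary labels are fit with binomial deviance loss by
#' default; `family = "gaussian"` gives the literal least-squares form of the
#' objective.
#'
#' @param x numeric feature matrix (rows = records, named columns).
#' @param y binary labels (0/1).
#' @param alpha elastic-net mixing parameter in `[0, 1]` (1 = lasso, 0 = ridge).
#' @param n_folds folds for the internal lambda cross-validation.
#' @param seed RNG seed for fold assignment.
#' @param family `"binomial"` (default) or `"gaussian"`.
#' @param lambda optional fixed penalty strength; when given, the
#'   cross-validated lambda selection is skipped.
#' @return an `sgrna_enet` fit: coefficients, intercept, `alpha`,
#'   `lambda_penalty`, `feature_names`, `center`, `scale`, `family`.
#' @export
fit_elastic_net <- function(x, y, alpha = 0.5, n_folds = 10L, seed = NULL,
                            family = c("binomial", "gaussian"), lambda = NULL) {
  family <- match.arg(family)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (length(unique(y)) < 2) stop("labels contain a single class")
  if (min(table(y)) < 2) stop("need at least 2 records per class")
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  const <- !is.finite(scl) | scl == 0
  if (any(const)) {
    warning("dropping constant feature column(s): ",
            paste(head(colnames(x)[const], 5), collapse = ", "),
            if (sum(const) > 5) sprintf(" (+%d more)", sum(const) - 5) else "")
    x <- x[, !const, drop = FALSE]
    ctr <- ctr[!const]
    scl <- scl[!const]
  }
  if (ncol(x) == 0) stop("no non-constant features left")
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  local_seed(seed)
  if (is.null(lambda)) {
    cv <- glmnet::cv.glmnet(xs, y, family = family, alpha = alpha,
                            nfolds = min(n_folds, nrow(xs)), standardize = FALSE)
    lambda <- cv$lambda.min
    beta <- as.numeric(stats::coef(cv, s = "lambda.min"))
  } else {
    fit <- glmnet::glmnet(xs, y, family = family, alpha = alpha,
                          lambda = lambda, standardize = FALSE,
                          thresh = 1e-10)
    beta <- as.numeric(stats::coef(fit))
  }
  structure(list(intercept = beta[1],
                 coefficients = setNames(beta[-1], colnames(xs)),
                 alpha = alpha, lambda_penalty = lambda,
                 feature_names = colnames(xs), center = ctr, scale = scl,
                 family = family),
            class = "sgrna_enet")
}

#' @export
print.sgrna_enet <- function(x, ...) {
  cat(sprintf("<sgrna_enet> %d features (%d nonzero), alpha = %g, lambda = %.4g, %s loss\n",
              length(x$coefficients), sum(x$coefficients != 0), x$alpha,
              x$lambda_penalty, x$family))
  invisible(x)
}

#' Predict efficiency scores from a fitted model
#'
#' @param object an `sgrna_enet` fit.
#' @param newx feature matrix whose column names must match the model's
#'   feature names exactly (order-insensitive; extra or missing columns are an
#'   error).
#' @param ... ignored.
#' @return numeric scores in `[0, 1]` for binomial fits (probabilities), the
#'   linear predictor for gaussian fits.
#' @export
predict.sgrna_enet <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  missing <- setdiff(object$feature_names, colnames(newx))
  extra <- setdiff(colnames(newx), object$feature_names)
  if (length(missing) || length(extra)) {
    stop("feature name mismatch; missing: [",
         paste(head(missing, 5), collapse = ", "), "], extra: [",
         paste(head(extra, 5), collapse = ", "), "]")
  }
  xs <- sweep(sweep(newx[, object$feature_names, drop = FALSE], 2, object$center),
              2, object$scale, "/")
  eta <- drop(xs %*% object$coefficients) + object$intercept
  if (object$family == "binomial") plogis(eta) else eta
}

#' Serialize / deserialize a fitted model as JSON
#'
#' The document is self-describing: feature names, scaling, coefficients and
#' hyperparameters, written at full numeric precision so reloaded models
#' reproduce scores exactly.
#'
#' @param model an `sgrna_enet`.
#' @param path JSON file.
#' @return `write_model`: the path, invisibly; `read_model`: the model.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$coefficients <- unlist(m$coefficients)
  m$center <- unlist(m$center)
  m$scale <- unlist(m$scale)
  structure(m, class = "sgrna_enet")
}

#' Area under the ROC curve
#'
#' Mann-Whitney form: the fraction of (efficient, inefficient) pairs ranked
#' concordantly, ties counted 1/2.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1), both classes present.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-index operating point
#'
#' Scans the observed scores as candidate cutpoints (predict efficient when
#' `score >= cutpoint`) and returns the one maximizing `J = Se + Sp - 1`;
#' ties resolve to the lowest such cutpoint.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1), both classes present.
#' @return list with `cutpoint`, `youden_j`, `sensitivity`, `specificity`.
#' @export
youden_cutpoint <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required")
  cand <- sort(unique(scores))
  se <- vapply(cand, function(t) sum(scores >= t & labels == 1) / n1, numeric(1))
  sp <- vapply(cand, function(t) sum(scores < t & labels == 0) / n0, numeric(1))
  j <- se + sp - 1
  best <- which(j >= max(j) - 1e-12)[1]   # lowest cutpoint among ties
  list(cutpoint = cand[best], youden_j = j[best], sensitivity = se[best],
       specificity = sp[best])
}

#' DeLong test for two correlated ROC curves
#'
#' Compares the AUCs of two score vectors computed on the same test records
#' (paired design) using DeLong's variance estimate; two-sided p-value.
#' Identical score vectors give p = 1 by convention; a degenerate variance
#' estimate raises an error.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels binary labels (0/1).
#' @return list with `auc_a`, `auc_b`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(labels))
  a <- auc_score(scores_a, labels)
  b <- auc_score(scores_b, labels)
  if (isTRUE(all.equal(scores_a, scores_b))) {
    return(list(auc_a = a, auc_b = b, p_value = 1))
  }
  ra <- pROC::roc(labels, scores_a, levels = c(0, 1), direction = "<", quiet = TRUE)
  rb <- pROC::roc(labels, scores_b, levels = c(0, 1), direction = "<", quiet = TRUE)
  tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  p <- as.numeric(tst$p.value)
  if (!is.finite(p)) stop("degenerate variance in DeLong test")
  list(auc_a = a, auc_b = b, p_value = p)
}

# stratified fold labels: near-equal class balance in every fold
stratified_folds <- function(y, n_splits) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    folds[idx] <- sample(rep_len(seq_len(n_splits), length(idx)))
  }
  folds
}

eval_split <- function(x_train, y_train, x_test, y_test, alpha = 0.5,
                       family = "binomial") {
  fit <- suppressWarnings(fit_elastic_net(x_train, y_train, alpha = alpha,
                                          family = family))
  # test columns are subset to the fit's surviving (non-constant) features
  scores <- predict(fit, x_test[, fit$feature_names, drop = FALSE])
  yj <- youden_cutpoint(scores, y_test)
  data.frame(auc = auc_score(scores, y_test), youden_j = yj$youden_j,
             sensitivity = yj$sensitivity, specificity = yj$specificity,
             cutpoint = yj$cutpoint, n_test = length(y_test))
}

eval_cv <- function(x, y, n_splits = 3L, iterations = 10L, alpha = 0.5,
                    seed = 1L, family = "binomial") {
  local_seed(seed)
  out <- list()
  for (it in seq_len(iterations)) {
    folds <- stratified_folds(y, n_splits)
    for (f in seq_len(n_splits)) {
      r <- eval_split(x[folds != f, , drop = FALSE], y[folds != f],
                      x[folds == f, , drop = FALSE], y[folds == f],
                      alpha = alpha, family = family)
      r$iteration <- it
      r$fold <- f
      out[[length(out) + 1L]] <- r
    }
  }
  do.call(rbind, out)
}

#' Run an evaluation protocol
#'
#' Three protocols: `"cv3x10"` splits the training dataset into 3 equal
#' stratified parts, evaluates each part against a model trained on the other
#' two, and averages over `iterations` random re-splits; `"cross_dataset"`
#' trains once on `train` and evaluates on `test`; `"leave_one_gene_out"`
#' holds out each gene in turn, pools the held-out predictions and reports a
#' single operating point.
#'
#' @param protocol one of `"cv3x10"`, `"cross_dataset"`, `"leave_one_gene_out"`.
#' @param train labeled `sgrna_dataset` used for training.
#' @param test labeled `sgrna_dataset` (required for `"cross_dataset"`).
#' @param feature_classes feature classes to include (see [feature_blocks()]).
#' @param alpha elastic-net mixing parameter.
#' @param seed RNG seed controlling fold assignment; runs are reproducible
#'   given the seed.
#' @param iterations random re-splits for `"cv3x10"`.
#' @param config per-class feature options (see [feature_blocks()]).
#' @param family model loss (see [fit_elastic_net()]).
#' @return an `sg_eval` object: list with `protocol`, `feature_classes`,
#'   per-split `results` data.frame and averaged `summary`.
#' @export
run_protocol <- function(protocol = c("cv3x10", "cross_dataset", "leave_one_gene_out"),
                         train, test = NULL, feature_classes = FEATURE_CLASSES,
                         alpha = 0.5, seed = 1L, iterations = 10L,
                         config = list(), family = "binomial") {
  protocol <- match.arg(protocol)
  if (all(is.na(train$label))) stop("training dataset is unlabeled")
  x <- bind_feature_blocks(feature_blocks(train, feature_classes, config))
  y <- train$label
  if (protocol == "cv3x10") {
    res <- eval_cv(x, y, n_splits = 3L, iterations = iterations, alpha = alpha,
                   seed = seed, family = family)
  } else if (protocol == "cross_dataset") {
    if (is.null(test)) stop("cross_dataset protocol needs a test dataset")
    xt <- bind_feature_blocks(feature_blocks(test, feature_classes, config))
    res <- eval_split(x, y, xt, test$label, alpha = alpha, family = family)
  } else {
    genes <- train$gene
    if (all(is.na(genes))) stop("leave_one_gene_out needs gene ids")
    if (length(unique(genes)) < 2) stop("leave_one_gene_out needs >= 2 genes")
    local_seed(seed)
    scores <- rep(NA_real_, nrow(x))
    for (g in unique(genes)) {
      hold <- genes == g
      fit <- suppressWarnings(fit_elastic_net(x[!hold, , drop = FALSE], y[!hold],
                                              alpha = alpha, family = family))
      scores[hold] <- predict(fit, x[hold, fit$feature_names, drop = FALSE])
    }
    yj <- youden_cutpoint(scores, y)
    res <- data.frame(auc = auc_score(scores, y), youden_j = yj$youden_j,
                      sensitivity = yj$sensitivity, specificity = yj$specificity,
                      cutpoint = yj$cutpoint, n_test = length(y))
  }
  metrics <- c("auc", "youden_j", "sensitivity", "specificity")
  structure(list(protocol = protocol, feature_classes = feature_classes,
                 results = res, summary = colMeans(res[metrics])),
            class = "sg_eval")
}

#' @export
print.sg_eval <- function(x, ...) {
  cat(sprintf("<sg_eval %s> classes: %s\n", x$protocol,
              paste(x$feature_classes, collapse = "+")))
  print(round(x$summary, 3))
  invisible(x)
}

#' Enumerate feature-class combinations
#' @param classes feature-class names.
#' @return list of all non-empty subsets (255 for the 8 classes).
#' @export
feature_class_combinations <- function(classes = FEATURE_CLASSES) {
  unlist(lapply(seq_along(classes), function(k) {
    combn(classes, k, simplify = FALSE)
  }), recursive = FALSE)
}

#' Sweep feature-class combinations
#'
#' Evaluates every requested combination of feature classes under one
#' protocol, on identical fold assignments (same seed), and reports the
#' combination with the maximum AUC ("Comb Feature").
#'
#' @inheritParams run_protocol
#' @param combinations list of class subsets; defaults to all non-empty
#'   subsets of `feature_classes` (255 for all 8).
#' @return data.frame with one row per combination (`combination`,
#'   `n_classes`, `auc`, `youden_j`, `sensitivity`, `specificity`), sorted by
#'   decreasing AUC; the best row first.
#' @export
sweep_combinations <- function(train, test = NULL, protocol = "cv3x10",
                               feature_classes = FEATURE_CLASSES,
                               combinations = NULL, alpha = 0.5, seed = 1L,
                               iterations = 10L, config = list()) {
  if (is.null(combinations)) combinations <- feature_class_combinations(feature_classes)
  blocks <- feature_blocks(train, feature_classes, config)
  x_all <- lapply(blocks, bind_feature_blocks)
  y <- train$label
  x_test <- if (!is.null(test)) {
    lapply(feature_blocks(test, feature_classes, config), bind_feature_blocks)
  }
  rows <- lapply(combinations, function(cmb) {
    x <- do.call(cbind, x_all[cmb])
    res <- if (protocol == "cv3x10") {
      eval_cv(x, y, 3L, iterations, alpha, seed)
    } else if (protocol == "cross_dataset") {
      eval_split(x, y, do.call(cbind, x_test[cmb]), test$label, alpha)
    } else stop("sweep supports cv3x10 and cross_dataset")
    data.frame(combination = paste(cmb, collapse = "+"), n_classes = length(cmb),
               auc = mean(res$auc), youden_j = mean(res$youden_j),
               sensitivity = mean(res$sensitivity),
               specificity = mean(res$specificity))
  })
  out <- do.call(rbind, rows)
  out[order(-out$auc), , drop = FALSE]
}

#' Rank single features by logistic-regression BIC
#'
#' Each feature is fit alone in a logistic regression against the efficiency
#' label within each dataset; `BIC = -2 loglik + 2 ln(n)` (intercept + slope).
#' BICs are averaged across datasets and ranked ascending (smaller = more
#' informative). Constant features reduce to the intercept-only likelihood
#' plus the slope's `ln(n)` penalty; non-converging fits are flagged and
#' ranked last.
#'
#' @param datasets list of labeled `sgrna_dataset`s.
#' @param feature_classes classes whose features enter the ranking.
#' @param config feature options.
#' @return data.frame (`feature`, `mean_bic`, `flagged`, `rank`), ordered by
#'   rank.
#' @export
rank_features_bic <- function(datasets, feature_classes = FEATURE_CLASSES,
                              config = list()) {
  rank_features_engine(datasets, feature_classes, config, function(x, y) {
    n <- length(y)
    if (sd(x) == 0) {
      ll <- logistic_loglik(rep(mean(y), n), y)
      return(c(-2 * ll + 2 * log(n), 0))
    }
    fit <- suppressWarnings(glm(y ~ x, family = binomial()))
    c(-2 * as.numeric(stats::logLik(fit)) + 2 * log(n), as.numeric(!fit$converged))
  }, descending = FALSE)
}

#' Rank single features by AUC
#'
#' Per-feature AUC against the label, orientation-corrected as
#' `max(AUC, 1 - AUC)`, averaged across datasets and ranked descending.
#' Constant features score 0.5.
#'
#' @inheritParams rank_features_bic
#' @return data.frame (`feature`, `mean_auc`, `flagged`, `rank`).
#' @export
rank_features_auc <- function(datasets, feature_classes = FEATURE_CLASSES,
                              config = list()) {
  out <- rank_features_engine(datasets, feature_classes, config, function(x, y) {
    if (sd(x) == 0) return(c(0.5, 0))
    a <- auc_score(x, y)
    c(max(a, 1 - a), 0)
  }, descending = TRUE)
  names(out)[names(out) == "mean_bic"] <- "mean_auc"
  out
}

rank_features_engine <- function(datasets, feature_classes, config, score_fun,
                                 descending) {
  if (inherits(datasets, "sgrna_dataset")) datasets <- list(datasets)
  per_ds <- lapply(datasets, function(d) {
    x <- bind_feature_blocks(feature_blocks(d, feature_classes, config))
    t(apply(x, 2, score_fun, y = d$label))
  })
  feats <- colnames(bind_feature_blocks(feature_blocks(datasets[[1]], feature_classes, config)))
  score <- rowMeans(do.call(cbind, lapply(per_ds, function(m) m[, 1])))
  flagged <- rowSums(do.call(cbind, lapply(per_ds, function(m) m[, 2]))) > 0
  ord <- order(flagged, if (descending) -score else score)
  out <- data.frame(feature = feats, mean_bic = score, flagged = flagged)[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

logistic_loglik <- function(p, y) sum(y * log(p) + (1 - y) * log(1 - p))

local_seed <- function(seed) if (!is.null(seed)) set.seed(as.integer(seed))
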