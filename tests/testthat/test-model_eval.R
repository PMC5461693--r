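test_that("AUC equals pair concordance and trapezoidal ROC integration", {
  expect_equal(auc_score(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc_score(c(0.9, 0.3, 0.7, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(auc_score(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(auc_score(1:3, c(1, 1, 1)), "both classes")
  set.seed(61)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    y <- c(rep(1, 5), sample(0:1, n - 5, replace = TRUE))
    y[1:2] <- 0:1
    s <- round(runif(n), 2)  # force some ties
    if (length(unique(y)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, levels = c(0, 1),
                                          direction = "<", quiet = TRUE)))
    expect_equal(auc_score(s, y), ref)
  }
})

test_that("Youden cutpoint maximizes Se + Sp - 1 over observed thresholds", {
  yj <- youden_cutpoint(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(yj$youden_j, 1)
  expect_equal(yj$sensitivity + yj$specificity - 1, yj$youden_j)
  # single distinct score still yields a valid operating point
  expect_equal(youden_cutpoint(rep(0.4, 4), c(1, 0, 1, 0))$youden_j, 0)
  set.seed(62)
  for (i in 1:20) {
    n <- 30
    y <- sample(0:1, n, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), 1)
    yj <- youden_cutpoint(s, y)
    # exhaustive scan oracle over all observed thresholds
    js <- vapply(sort(unique(s)), function(t) {
      mean(s[y == 1] >= t) + mean(s[y == 0] < t) - 1
    }, numeric(1))
    expect_equal(yj$youden_j, max(js))
  }
})

test_that("elastic net separates a perfect single-feature signal", {
  set.seed(63)
  n <- 200
  y <- rep(0:1, each = n / 2)
  x <- cbind(sig = y + rnorm(n, 0, 0.1), noise = rnorm(n))
  tr <- sample(n, 150)
  fit <- fit_elastic_net(x[tr, ], y[tr], seed = 1)
  expect_equal(auc_score(predict(fit, x[-tr, ]), y[-tr]), 1.0)
})

test_that("pure-noise features give chance-level held-out AUC", {
  set.seed(64)
  aucs <- replicate(20, {
    n <- 120
    y <- rep(0:1, each = n / 2)
    x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
    tr <- sample(n, 80)
    fit <- suppressWarnings(fit_elastic_net(x[tr, ], y[tr], seed = 1))
    auc_score(predict(fit, x[-tr, ]), y[-tr])
  })
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("ridge fit matches an independent penalized-likelihood solver", {
  set.seed(65)
  n <- 300
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(n, 1, plogis(0.5 * x[, 1] - x[, 2]))
  lam <- 0.05
  fit <- fit_elastic_net(x, y, alpha = 0, lambda = lam)
  xs <- scale(x)
  obj <- function(b) {
    eta <- b[1] + xs %*% b[-1]
    -mean(y * eta - log(1 + exp(eta))) + lam / 2 * sum(b[-1]^2)
  }
  opt <- optim(rep(0, 4), obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(unname(fit$coefficients), opt$par[-1], tolerance = 1e-4)
  expect_equal(fit$intercept, opt$par[1], tolerance = 1e-4)
})

test_that("fit errors and warnings match the contracts", {
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_elastic_net(x, rep(1, 20)), "single class")
  xc <- cbind(x, const = 1)
  w <- testthat::capture_warnings(fit <- fit_elastic_net(xc, rep(0:1, 10), seed = 1))
  expect_true(any(grepl("constant", w)))
  expect_false("const" %in% fit$feature_names)
  expect_error(predict(fit, xc), "mismatch")
})

test_that("serialized models reproduce scores exactly", {
  set.seed(66)
  x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rbinom(50, 1, plogis(x[, 1]))
  y[1:2] <- 0:1
  fit <- suppressWarnings(fit_elastic_net(x, y, seed = 1))
  tf <- withr::local_tempfile(fileext = ".json")
  write_model(fit, tf)
  fit2 <- read_model(tf)
  expect_equal(predict(fit2, x), predict(fit, x), tolerance = 1e-14)
})

test_that("DeLong test is symmetric, self-comparison gives p = 1", {
  set.seed(67)
  n <- 150
  y <- rep(0:1, length.out = n)
  sa <- plogis(y + rnorm(n))
  sb <- plogis(0.8 * y + rnorm(n))
  expect_equal(delong_test(sa, sa, y)$p_value, 1)
  d1 <- delong_test(sa, sb, y)
  d2 <- delong_test(sb, sa, y)
  expect_equal(d1$p_value, d2$p_value)
  expect_equal(d1$auc_a, d2$auc_b)
})

test_that("DeLong p agrees with a paired permutation null", {
  set.seed(68)
  n <- 200
  y <- rep(0:1, each = n / 2)
  base <- rnorm(n)
  sa <- plogis(0.8 * y + base + rnorm(n, 0, 0.6))
  sb <- plogis(0.55 * y + base + rnorm(n, 0, 0.6))
  p_dl <- delong_test(sa, sb, y)$p_value
  p_perm <- perm_auc_test(sa, sb, y, n_perm = 2000, seed = 3)
  mc <- 2 * sqrt(max(p_perm * (1 - p_perm), 0.01) / 2000)
  expect_lt(abs(p_dl - p_perm), 0.08 + mc)
})

test_that("BIC ranking matches a direct likelihood-maximization oracle", {
  # tiny six-record set, grid/optim oracle
  x <- c(-1.2, -0.5, 0.1, 0.4, 1.0, 1.7)
  y <- c(0, 0, 1, 0, 1, 1)
  ds_bic <- function(x, y) {
    nll <- function(b) -sum(y * (b[1] + b[2] * x) - log(1 + exp(b[1] + b[2] * x)))
    -2 * -optim(c(0, 0), nll, method = "BFGS",
                control = list(reltol = 1e-14))$value + 2 * log(length(y))
  }
  fit <- glm(y ~ x, family = binomial())
  expect_equal(-2 * as.numeric(logLik(fit)) + 2 * log(6), ds_bic(x, y),
               tolerance = 1e-3)

  ds <- generate_sgrna_data(synth_preset("tt-negative", n = 300, seed = 71))
  rk <- rank_features_bic(ds, "Freq")
  tt <- rk$mean_bic[rk$feature == "Freq.freq_TT"]
  xf <- bind_feature_blocks(feature_blocks(ds, "Freq"))[, "Freq.freq_TT"]
  expect_equal(tt, ds_bic(xf, ds$label), tolerance = 1e-3)
  # constant feature reduces to intercept-only likelihood + slope penalty:
  # six identical sequences make every feature constant
  labs <- c(1, 0, 1, 0, 1, 1)
  ds_const <- tiny_dataset(rep("ACGTACGTTTACGGATCCAT", 6), labels = labs)
  rk_const <- rank_features_bic(ds_const, "Freq")
  p0 <- mean(labs)
  ll0 <- sum(labs * log(p0) + (1 - labs) * log(1 - p0))
  expect_true(all(abs(rk_const$mean_bic - (-2 * ll0 + 2 * log(6))) < 1e-9))
})

test_that("AUC ranking orientation-corrects anti-correlated features", {
  set.seed(72)
  ds <- generate_sgrna_data(synth_preset("tt-negative", n = 400, seed = 72))
  rk <- rank_features_auc(ds, "Freq")
  # TT frequency is negatively associated; orientation max(AUC, 1-AUC)
  # still puts it on top
  expect_equal(rk$feature[1], "Freq.freq_TT")
  raw <- auc_score(bind_feature_blocks(feature_blocks(ds, "Freq"))[, "Freq.freq_TT"],
                   ds$label)
  expect_lt(raw, 0.5)
  expect_equal(rk$mean_auc[1], 1 - raw)
})

test_that("protocols are reproducible and validate their inputs", {
  ds <- generate_sgrna_data(synth_preset("tt-negative", n = 180, seed = 73))
  e1 <- run_protocol("cv3x10", ds, feature_classes = "Freq", iterations = 2,
                     seed = 5)
  e2 <- run_protocol("cv3x10", ds, feature_classes = "Freq", iterations = 2,
                     seed = 5)
  expect_identical(e1$results, e2$results)
  expect_equal(nrow(e1$results), 6)  # 3 folds x 2 iterations

  ds2 <- generate_sgrna_data(synth_preset("tt-negative", n = 150, seed = 74))
  ex <- run_protocol("cross_dataset", ds, test = ds2, feature_classes = "Freq",
                     seed = 1)
  expect_equal(nrow(ex$results), 1)
  expect_equal(ex$results$n_test, 150)

  one_gene <- ds
  one_gene$gene <- "gene001"
  expect_error(run_protocol("leave_one_gene_out", one_gene,
                            feature_classes = "Freq"), ">= 2 genes")
  unlabeled <- ds
  unlabeled$label <- NA_integer_
  expect_error(run_protocol("cv3x10", unlabeled, feature_classes = "Freq"),
               "unlabeled")
})

test_that("combination sweep enumerates subsets and beats its own singletons", {
  expect_length(feature_class_combinations(), 255)
  ds <- generate_sgrna_data(synth_preset("tt-negative", n = 200, seed = 75))
  cls <- c("Freq", "Thermo")
  sw <- sweep_combinations(ds, protocol = "cv3x10", feature_classes = cls,
                           iterations = 1, seed = 4)
  expect_equal(nrow(sw), 3)
  best <- sw$auc[1]
  singles <- sw$auc[sw$n_classes == 1]
  expect_gte(max(sw$auc), max(singles))
  # same folds: singleton rows equal individual protocol runs
  e <- run_protocol("cv3x10", ds, feature_classes = "Freq", iterations = 1,
                    seed = 4)
  expect_equal(sw$auc[sw$combination == "Freq"], unname(e$summary["auc"]))
})

test_that("standardization comes from the training data only", {
  set.seed(76)
  x <- matrix(rnorm(100), 50, 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(50, 1, plogis(2 * x[, 1]))
  y[1:2] <- 0:1
  fit <- suppressWarnings(fit_elastic_net(x, y, seed = 1))
  expect_equal(fit$center, colMeans(x)[fit$feature_names])
  # shifting the test matrix shifts predictions (no re-standardization)
  p1 <- predict(fit, x)
  p2 <- predict(fit, x + 10)
  if (any(fit$coefficients != 0)) expect_false(isTRUE(all.equal(p1, p2)))
})
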