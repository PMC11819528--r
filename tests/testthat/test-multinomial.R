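counts_to_df <- function(m) {
  df <- as.data.frame(as.table(m))
  names(df) <- c("level", "outcome", "n")
  df
}

test_that("contingency OR matches the closed form and handles zeros", {
  m <- matrix(c(10, 10, 10, 10, 10, 10), nrow = 2,
              dimnames = list(c("a", "b"),
                              c("recovered", "high", "low")))
  expect_equal(contingency_or(m, "b", "high")$or, 1)
  m2 <- reference_count_matrix("sex")
  got <- contingency_or(m2, "male", "high_growth_nr")
  expect_equal(got$or, (607 * 7756) / (906 * 5971), tolerance = 1e-12)
  expect_equal(round(got$or, 2), 0.87)
  # CI from the log-scale variance sum
  se <- sqrt(1 / 607 + 1 / 7756 + 1 / 906 + 1 / 5971)
  expect_equal(got$conf.low, exp(log(got$or) - qnorm(0.975) * se))
  mz <- m; mz["b", "high"] <- 0
  expect_error(contingency_or(mz, "b", "high"), "zero cell")
  expect_s3_class(contingency_or(mz, "b", "high", correction = 0.5),
                  "tbl_df")
})

test_that("the Newton MLE agrees with the contingency closed form", {
  set.seed(17)
  for (i in 1:10) {
    m <- matrix(rpois(6, 80) + 1, nrow = 2,
                dimnames = list(c("base", "lev"), c("ref", "o1", "o2")))
    fit <- fit_multinomial(counts_to_df(m), outcome ~ level, ref = "ref",
                           weights = n)
    expect_true(fit$converged)
    for (oc in c("o1", "o2")) {
      expect_equal(exp(fit$coefficients["levellev", oc]),
                   contingency_or(m, "lev", oc)$or, tolerance = 1e-6)
    }
  }
})

test_that("the fit agrees with an independent multinomial implementation", {
  skip_if_not_installed("nnet")
  set.seed(31)
  n <- 600
  x1 <- rnorm(n)
  x2 <- factor(sample(c("p", "q", "r"), n, replace = TRUE))
  eta1 <- -0.5 + 0.8 * x1 + 0.5 * (x2 == "q")
  eta2 <- -1 - 0.6 * x1 + 0.9 * (x2 == "r")
  pr <- cbind(1, exp(eta1), exp(eta2))
  y <- factor(apply(pr, 1, function(p) sample(3, 1, prob = p)),
              labels = c("A", "B", "C"))
  df <- data.frame(y = y, x1 = x1, x2 = x2)
  ours <- fit_multinomial(df, y ~ x1 + x2)
  ref <- nnet::multinom(y ~ x1 + x2, df, trace = FALSE, reltol = 1e-12)
  expect_equal(unname(ours$coefficients), unname(t(coef(ref))),
               tolerance = 1e-4)
  expect_equal(ours$loglik, -ref$value, tolerance = 1e-8)
  # log-likelihood never decreases over Newton iterations
  expect_true(all(diff(ours$ll_trace) >= -1e-10))
})

test_that("relabelling the baseline level inverts the OR exactly", {
  m <- reference_count_matrix("sex")
  df <- counts_to_df(m)
  f1 <- fit_multinomial(df, outcome ~ level, ref = "recovered", weights = n)
  df$level <- relevel(df$level, "male")
  f2 <- fit_multinomial(df, outcome ~ level, ref = "recovered", weights = n)
  expect_equal(exp(f1$coefficients["levelmale", ]),
               1 / exp(f2$coefficients["levelfemale", ]),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("rank deficiency and separation are reported, not silent", {
  df <- data.frame(y = factor(rep(c("A", "B", "C"), 20)),
                   x = rnorm(60))
  df$x2 <- 2 * df$x
  expect_error(fit_multinomial(df, y ~ x + x2), "rank deficient")
  # perfect separation: no finite MLE, flagged as non-converged
  sep <- data.frame(y = factor(rep(c("A", "B"), each = 20)),
                    x = rep(c(0, 1), each = 20))
  fit <- suppressWarnings(fit_multinomial(sep, y ~ x, max_iter = 50))
  expect_false(fit$converged)
  expect_error(wald_test(fit, "x"), "converge")
})

test_that("the joint Wald test matches its quadratic-form definition", {
  m <- reference_count_matrix("age_cat")
  fit <- fit_multinomial(counts_to_df(m), outcome ~ level,
                         ref = "recovered", weights = n)
  w <- wald_test(fit, "level")
  expect_equal(w$df, 4)  # 2 non-baseline levels x 2 contrasts
  # manual quadratic form over the same coefficients
  idx <- which(rep(fit$assign, 2) == 1)
  b <- as.vector(fit$coefficients)[idx]
  V <- fit$vcov[idx, idx]
  expect_equal(w$statistic, as.numeric(t(b) %*% solve(V, b)))
  expect_error(wald_test(fit, "nope"), "unknown variable")
  # a 1-df coefficient at 1.96 SE gives p ~ 0.05
  z <- qnorm(0.975)
  expect_equal(pchisq(z^2, 1, lower.tail = FALSE), 0.05, tolerance = 1e-4)
})

test_that("VIF matches its R-squared definition", {
  # exactly orthogonal mean-zero columns: VIF 1
  set.seed(14)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(120), 40, 3))))
  X <- Q[, 2:4]  # orthonormal and orthogonal to the intercept
  v <- vif_screen(X)
  expect_equal(v$vif, rep(1, 3), tolerance = 1e-10)
  # exact correlation 0.6 by construction: VIF = 1 / (1 - 0.36)
  u <- qr.Q(qr(cbind(1, matrix(rnorm(80), 40, 2))))[, 2:3]
  x1 <- u[, 1]
  x2 <- 0.6 * u[, 1] + sqrt(1 - 0.36) * u[, 2]
  v <- vif_screen(cbind(x1 = x1, x2 = x2))
  expect_equal(v$vif, rep(1.5625, 2), tolerance = 1e-10)
  expect_true(all(v$flagged))  # 1.5625 >= 1.5 screening threshold
  # duplicated column: VIF diverges and is flagged
  v <- vif_screen(cbind(a = x1, b = x1, c = x2))
  expect_true(all(is.infinite(v$vif[1:2])) && all(v$flagged[1:2]))
  expect_error(vif_screen(cbind(x1, rep(1, 40))), "constant")
  expect_error(vif_screen(cbind(x1)), "2 predictors")
})

test_that("multiclass AUC agrees with a pairwise binary-AUC oracle", {
  skip_if_not_installed("pROC")
  set.seed(12)
  n <- 150
  y <- factor(sample(c("A", "B", "C"), n, replace = TRUE))
  P <- matrix(runif(3 * n), n, 3, dimnames = list(NULL, c("A", "B", "C")))
  P <- P / rowSums(P)
  pairs <- combn(c("A", "B", "C"), 2, simplify = FALSE)
  want <- mean(purrr::map_dbl(pairs, function(pr) {
    i <- pr[1]; j <- pr[2]
    sub <- y %in% pr
    a_ij <- as.numeric(suppressMessages(
      pROC::auc(y[sub] == i, P[sub, i], direction = "<")))
    a_ji <- as.numeric(suppressMessages(
      pROC::auc(y[sub] == j, P[sub, j], direction = "<")))
    (a_ij + a_ji) / 2
  }))
  expect_equal(multiclass_auc(y, P), want, tolerance = 1e-10)
})

test_that("classification metrics behave at the reference points", {
  # deterministic separable toy data
  df <- data.frame(y = factor(rep(c("A", "B", "C"), each = 30)),
                   x = rep(c(-4, 0, 4), each = 30) + rnorm(90, 0, 0.1))
  fit <- suppressWarnings(fit_multinomial(df, y ~ x, max_iter = 200))
  mm <- model_metrics(fit)
  expect_equal(mm$accuracy, 1)
  expect_equal(mm$auc, 1)
  # constant probabilities are uninformative: AUC exactly 1/2
  y <- factor(rep(c("A", "B", "C"), 20))
  P <- matrix(1 / 3, 60, 3, dimnames = list(NULL, levels(y)))
  expect_equal(multiclass_auc(y, P), 0.5)
  # labels independent of predictors, balanced classes
  set.seed(77)
  df <- data.frame(y = factor(sample(rep(c("A", "B", "C"), 400))),
                   x = rnorm(1200))
  mm <- model_metrics(fit_multinomial(df, y ~ x))
  expect_equal(mm$accuracy, 1 / 3, tolerance = 0.06)
  expect_equal(mm$auc, 0.5, tolerance = 0.05)
})

test_that("complete-case handling drops and counts missing rows", {
  df <- data.frame(y = factor(rep(c("A", "B", "C"), 30)),
                   x = c(NA, rnorm(89)))
  fit <- fit_multinomial(df, y ~ x)
  expect_equal(fit$n, 89)
  expect_equal(fit$n_dropped, 1)
})
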