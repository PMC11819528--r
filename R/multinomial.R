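#' Odds ratio from a predictor-by-outcome contingency table
#'
#' Closed-form univariate multinomial odds ratio: for a table of counts
#' with predictor levels as rows and outcome categories as columns,
#' \deqn{OR = \frac{n[level, outcome] \, n[baseline, ref]}
#'                 {n[baseline, outcome] \, n[level, ref]}}
#' with a Wald 95\% CI on the log scale
#' (`log OR +/- z * sqrt(sum of reciprocal cells)`). This equals the
#' maximum-likelihood estimate from a univariate multinomial logistic
#' regression with a single categorical predictor.
#'
#' @param counts numeric matrix of counts, predictor levels x outcome
#'   categories, with dimnames.
#' @param level predictor level of interest (row name).
#' @param outcome outcome category of interest (column name).
#' @param baseline baseline predictor level; default the first row.
#' @param ref reference outcome category; default the first column.
#' @param conf.level confidence level for the CI.
#' @param correction continuity correction added to each cell when any of
#'   the four cells is zero (default 0, i.e. zero cells are an error).
#' @return one-row tibble: `level`, `outcome`, `or`, `conf.low`,
#'   `conf.high`.
#' @export
contingency_or <- function(counts, level, outcome,
                           baseline = rownames(counts)[1],
                           ref = colnames(counts)[1],
                           conf.level = 0.95, correction = 0) {
  cells <- c(counts[level, outcome], counts[baseline, ref],
             counts[baseline, outcome], counts[level, ref])
  if (any(cells == 0)) {
    if (correction <= 0) {
      stop("contingency_or(): zero cell; set `correction` (e.g. 0.5) to ",
           "apply a continuity correction", call. = FALSE)
    }
    cells <- cells + correction
  }
  log_or <- log(cells[1]) + log(cells[2]) - log(cells[3]) - log(cells[4])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  tibble::tibble(level = level, outcome = outcome, or = exp(log_or),
                 conf.low = exp(log_or - z * se),
                 conf.high = exp(log_or + z * se))
}

#' Multinomial logistic regression by Newton-Raphson
#'
#' Fits a baseline-category multinomial logistic model by full Newton
#' iteration on the multinomial log-likelihood. Standard errors come from
#' the inverse observed information. Convergence is declared when the
#' largest absolute score component falls below `tol` (default 1e-8);
#' iteration stops after `max_iter` steps with `converged = FALSE`, which
#' is also the signature of data separation.
#'
#' @param data data frame with the outcome and predictors.
#' @param formula model formula; the left-hand side must be a factor (or
#'   coercible) with at least 2 levels.
#' @param ref reference (baseline) outcome level; default the factor's
#'   first level.
#' @param weights optional case weights (e.g. frequencies when fitting
#'   from an aggregated table).
#' @param max_iter,tol Newton iteration controls.
#' @return object of class `nr_multinom`: coefficient matrix (predictors x
#'   non-reference outcomes), `se`, `vcov`, `loglik`, `converged`,
#'   `iterations`, fitted probabilities, and term metadata for
#'   [wald_test()]. Complete-case analysis: rows with missing model
#'   variables are dropped and counted in `n_dropped`.
#' @export
fit_multinomial <- function(data, formula, ref = NULL, weights = NULL,
                            max_iter = 100, tol = 1e-8) {
  data <- as.data.frame(data)
  wq <- substitute(weights)
  w_all <- if (is.null(wq)) NULL else eval(wq, data, parent.frame())
  vars <- all.vars(formula)
  keep <- stats::complete.cases(data[, vars, drop = FALSE])
  if (!is.null(w_all)) keep <- keep & !is.na(w_all)
  n_dropped <- sum(!keep)
  data <- data[keep, , drop = FALSE]
  w <- if (is.null(w_all)) rep(1, nrow(data)) else w_all[keep]

  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- droplevels(as.factor(stats::model.response(mf)))
  if (!is.null(ref)) y <- stats::relevel(y, ref = ref)
  K <- nlevels(y)
  if (K < 2) stop("outcome needs at least 2 observed levels", call. = FALSE)
  terms_obj <- attr(mf, "terms")
  X <- stats::model.matrix(terms_obj, mf)
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    collinear <- setdiff(colnames(X), colnames(X)[qrX$pivot[seq_len(qrX$rank)]])
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(collinear, collapse = ", "), call. = FALSE)
  }
  C <- K - 1
  Y <- matrix(0, nrow(X), C)
  for (j in seq_len(C)) Y[, j] <- as.numeric(y == levels(y)[j + 1])

  B <- matrix(0, p, C)
  loglik_at <- function(B) {
    eta <- X %*% B
    m <- pmax(apply(eta, 1, max), 0)  # log-sum-exp guard
    lse <- m + log(exp(-m) + rowSums(exp(eta - m)))
    sum(w * (rowSums(Y * eta) - lse))
  }
  probs_at <- function(B) {
    eta <- X %*% B
    m <- pmax(apply(eta, 1, max), 0)
    denom <- exp(-m) + rowSums(exp(eta - m))
    exp(eta - m) / denom
  }
  ll <- loglik_at(B)
  ll_trace <- ll
  converged <- FALSE
  iter <- 0
  info <- NULL
  while (iter < max_iter) {
    iter <- iter + 1
    P <- probs_at(B)
    score <- as.vector(crossprod(X, w * (Y - P)))
    info <- matrix(0, p * C, p * C)
    for (j in seq_len(C)) {
      for (k in seq_len(j)) {
        wjk <- if (j == k) w * P[, j] * (1 - P[, j]) else -w * P[, j] * P[, k]
        blk <- crossprod(X, X * wjk)
        ri <- (j - 1) * p + seq_len(p); ci <- (k - 1) * p + seq_len(p)
        info[ri, ci] <- blk
        info[ci, ri] <- t(blk)
      }
    }
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) break
    new_B <- B + matrix(step, p, C)
    new_ll <- loglik_at(new_B)
    halvings <- 0
    while (new_ll < ll - 1e-12 && halvings < 30) {
      step <- step / 2
      new_B <- B + matrix(step, p, C)
      new_ll <- loglik_at(new_B)
      halvings <- halvings + 1
    }
    B <- new_B; ll <- new_ll
    ll_trace <- c(ll_trace, ll)
  }
  # diverging coefficients with a vanishing score are the signature of
  # separation: there is no finite MLE, so flag the fit as not converged
  if (converged && max(abs(B)) > 12) converged <- FALSE
  vcov <- tryCatch(solve(info), error = function(e) matrix(NA, p * C, p * C))
  se <- matrix(sqrt(pmax(diag(vcov), 0)), p, C)
  dimnames(B) <- dimnames(se) <- list(colnames(X), levels(y)[-1])
  P <- probs_at(B)
  fitted <- cbind(1 - rowSums(P), P)
  colnames(fitted) <- levels(y)

  structure(list(
    coefficients = B, se = se, vcov = vcov, loglik = ll,
    ll_trace = ll_trace, converged = converged, iterations = iter,
    levels = levels(y), ref = levels(y)[1],
    n = nrow(X), n_dropped = n_dropped, weights = w,
    y = y, fitted = fitted,
    assign = attr(X, "assign"), term_labels = attr(terms_obj, "term.labels"),
    terms = terms_obj, xlevels = stats::.getXlevels(terms_obj, mf),
    formula = formula, call = match.call()
  ), class = "nr_multinom")
}

#' @export
print.nr_multinom <- function(x, ...) {
  cat("Multinomial logistic fit (reference:", x$ref, ")\n")
  cat("n =", x$n, "; log-likelihood =", format(x$loglik),
      "; converged:", x$converged, "in", x$iterations, "iterations\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
predict.nr_multinom <- function(object, newdata = NULL,
                                type = c("probs", "class"), ...) {
  type <- match.arg(type)
  P <- if (is.null(newdata)) {
    object$fitted
  } else {
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, newdata, xlev = object$xlevels,
                             na.action = stats::na.pass)
    X <- stats::model.matrix(tt, mf)
    eta <- X %*% object$coefficients
    m <- pmax(apply(eta, 1, max), 0)
    denom <- exp(-m) + rowSums(exp(eta - m))
    probs <- exp(eta - m) / denom
    out <- cbind(1 - rowSums(probs), probs)
    colnames(out) <- object$levels
    out
  }
  if (type == "probs") return(P)
  factor(object$levels[max.col(P)], levels = object$levels)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a multinomial fit
#'
#' Broom-style coefficient table: one row per (outcome contrast, term),
#' with Wald z statistics and optional exponentiation to odds ratios.
#'
#' @param x an `nr_multinom` fit.
#' @param exponentiate report odds ratios and OR-scale confidence bounds.
#' @param conf.level confidence level.
#' @param ... unused.
#' @return tibble with columns `y.level`, `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @export
tidy.nr_multinom <- function(x, exponentiate = FALSE, conf.level = 0.95,
                             ...) {
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  out <- purrr::map_dfr(colnames(x$coefficients), function(lev) {
    b <- unname(x$coefficients[, lev]); s <- unname(x$se[, lev])
    tibble::tibble(
      y.level = lev, term = rownames(x$coefficients),
      estimate = b, std.error = s, statistic = b / s,
      p.value = 2 * stats::pnorm(-abs(b / s)),
      conf.low = b - z * s, conf.high = b + z * s
    )
  })
  if (exponentiate) {
    out <- dplyr::mutate(out, estimate = exp(.data$estimate),
                         conf.low = exp(.data$conf.low),
                         conf.high = exp(.data$conf.high))
  }
  out
}

#' Glance at a multinomial fit
#' @param x an `nr_multinom` fit.
#' @param ... unused.
#' @return one-row tibble: log-likelihood, deviance, AIC, `df`, `n`,
#'   convergence status and iteration count.
#' @export
glance.nr_multinom <- function(x, ...) {
  df <- length(x$coefficients)
  tibble::tibble(logLik = x$loglik, deviance = -2 * x$loglik,
                 AIC = -2 * x$loglik + 2 * df, df = df, nobs = x$n,
                 converged = x$converged, iterations = x$iterations)
}

#' Joint Wald test for one model variable
#'
#' Chi-square test that all coefficients belonging to `variable` (all its
#' dummy levels, across both non-reference outcome contrasts) are zero,
#' using the joint coefficient covariance of the fit.
#'
#' @param fit converged `nr_multinom` fit.
#' @param variable a term label from the model formula.
#' @return one-row tibble: `variable`, `statistic`, `df`, `p.value`.
#' @export
wald_test <- function(fit, variable) {
  if (!fit$converged) {
    stop("wald_test(): fit did not converge", call. = FALSE)
  }
  ti <- match(variable, fit$term_labels)
  if (is.na(ti)) {
    stop("unknown variable '", variable, "'; model terms: ",
         paste(fit$term_labels, collapse = ", "), call. = FALSE)
  }
  p <- nrow(fit$coefficients)
  C <- ncol(fit$coefficients)
  cols <- which(fit$assign == ti)
  idx <- as.vector(outer(cols, (seq_len(C) - 1) * p, `+`))
  b <- as.vector(fit$coefficients)[idx]
  V <- fit$vcov[idx, idx, drop = FALSE]
  stat <- as.numeric(t(b) %*% solve(V, b))
  tibble::tibble(variable = variable, statistic = stat, df = length(idx),
                 p.value = stats::pchisq(stat, df = length(idx),
                                         lower.tail = FALSE))
}

#' Variance inflation factors for a design matrix
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing each (dummy-encoded)
#' predictor column on all the others plus an intercept. Values at or
#' above `threshold` are flagged as collinear.
#'
#' @param X numeric design matrix *without* an intercept column (use
#'   `model.matrix(...)[, -1]`), or a data frame of numeric predictors.
#' @param threshold flagging cut-off; the screening rule used here is
#'   VIF < 1.5.
#' @return tibble: `term`, `vif`, `flagged`.
#' @export
vif_screen <- function(X, threshold = 1.5) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("vif_screen(): need at least 2 predictors",
                        call. = FALSE)
  if (any(apply(X, 2, stats::var) == 0)) {
    stop("vif_screen(): constant column; VIF undefined", call. = FALSE)
  }
  vifs <- purrr::map_dbl(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  })
  tibble::tibble(term = colnames(X), vif = vifs, flagged = vifs >= threshold)
}

# Rank-based AUC of `scores` separating positives from negatives (ties
# handled by midranks).
auc_rank <- function(scores_pos, scores_neg) {
  n1 <- length(scores_pos); n2 <- length(scores_neg)
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Multiclass AUC
#'
#' Hand-Till construction (default): the average over unordered class
#' pairs (i, j) of `[A(i|j) + A(j|i)] / 2`, where `A(i|j)` is the
#' two-class AUC of the class-i predicted probability separating class i
#' from class j. A one-vs-rest macro average is available.
#'
#' @param y observed class factor.
#' @param probs matrix of predicted probabilities, columns named by class.
#' @param method `"hand_till"` or `"macro_ovr"`.
#' @return scalar AUC in \[0, 1\].
#' @export
multiclass_auc <- function(y, probs, method = c("hand_till", "macro_ovr")) {
  method <- match.arg(method)
  y <- as.factor(y)
  lv <- levels(y)
  if (method == "hand_till") {
    pairs <- utils::combn(lv, 2, simplify = FALSE)
    mean(purrr::map_dbl(pairs, function(pr) {
      i <- pr[1]; j <- pr[2]
      ii <- y == i; jj <- y == j
      a_ij <- auc_rank(probs[ii, i], probs[jj, i])
      a_ji <- auc_rank(probs[jj, j], probs[ii, j])
      (a_ij + a_ji) / 2
    }))
  } else {
    mean(purrr::map_dbl(lv, function(l) {
      auc_rank(probs[y == l, l], probs[y != l, l])
    }))
  }
}

#' Classification metrics for a multinomial fit
#'
#' In-sample (or new-data) accuracy, multiclass AUC and the confusion
#' matrix, with predicted class taken as the highest predicted
#' probability.
#'
#' @param fit converged `nr_multinom` fit.
#' @param data optional new data; default uses the fitting data.
#' @param auc_method passed to [multiclass_auc()].
#' @return list of class `model_metrics`: `accuracy`, `auc`, `confusion`.
#' @export
model_metrics <- function(fit, data = NULL, auc_method = "hand_till") {
  if (is.null(data)) {
    probs <- fit$fitted
    y <- fit$y
  } else {
    probs <- predict(fit, newdata = data, type = "probs")
    y <- factor(data[[all.vars(fit$formula)[1]]], levels = fit$levels)
  }
  pred <- factor(fit$levels[max.col(probs)], levels = fit$levels)
  structure(list(
    accuracy = mean(pred == y),
    auc = multiclass_auc(y, probs, method = auc_method),
    confusion = table(observed = y, predicted = pred)
  ), class = "model_metrics")
}

#' @export
print.model_metrics <- function(x, ...) {
  cat(sprintf("Accuracy = %.1f%%; multiclass AUC = %.1f%%\n",
              100 * x$accuracy, 100 * x$auc))
  print(x$confusion)
  invisible(x)
}
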