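#' Paired sample container
#'
#' Two equal-length score vectors linked by participant (e.g. the same
#' task at two time points). Missing pairs are not allowed.
#'
#' @param time1,time2 numeric vectors of equal length >= 3, same units.
#' @return an object of class `paired_sample`.
#' @export
paired_sample <- function(time1, time2) {
  if (length(time1) != length(time2)) stop("vectors must have equal length")
  if (length(time1) < 3) stop("need at least 3 pairs")
  if (anyNA(time1) || anyNA(time2)) stop("missing pairs are not allowed")
  structure(list(time1 = as.numeric(time1), time2 = as.numeric(time2),
                 n = length(time1)),
            class = "paired_sample")
}

#' Pearson product-moment correlation with two-sided p
#'
#' @param x,y equal-length numeric vectors (n >= 3), both with nonzero
#'   variance.
#' @return list with `r`, `df` (= n - 2) and the two-sided `p` from the t
#'   distribution.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("degenerate input: zero variance")
  r <- cor(x, y)
  df <- n - 2
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt(df / (1 - r^2))
    2 * pt(-abs(tval), df)
  }
  list(r = r, df = df, p = p)
}

#' Paired t test
#'
#' t statistic on the within-pair differences with `df = n - 1` and a
#' two-sided p. Identical vectors give `t = 0` (a well-defined no-change
#' outcome); nonzero constant differences have zero variance and are
#' rejected as degenerate.
#'
#' @param sample a [paired_sample()].
#' @return list with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t <- function(sample) {
  stopifnot(inherits(sample, "paired_sample"))
  d <- sample$time2 - sample$time1
  n <- length(d)
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, df = n - 1, p = 1, mean_diff = 0))
    }
    stop("degenerate input: constant nonzero differences")
  }
  tval <- mean(d) / (sd(d) / sqrt(n))
  list(t = tval, df = n - 1, p = 2 * pt(-abs(tval), n - 1),
       mean_diff = mean(d))
}

#' One-way analysis of variance
#'
#' Classical between/within mean-square F with `df1 = k - 1`,
#' `df2 = N - k`. All-equal data give `F = 0` (not an error).
#'
#' @param groups a list of >= 2 numeric vectors, each of length >= 2.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need >= 2 groups")
  if (any(vapply(groups, length, 1L) < 2)) stop("each group needs >= 2 values")
  k <- length(groups)
  ns <- vapply(groups, length, 1L)
  N <- sum(ns)
  gm <- mean(unlist(groups))
  means <- vapply(groups, mean, 1)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  df1 <- k - 1
  df2 <- N - k
  if (ssw == 0) {
    Fv <- if (ssb == 0) 0 else Inf
  } else {
    Fv <- (ssb / df1) / (ssw / df2)
  }
  list(F = Fv, df1 = df1, df2 = df2,
       p = pf(Fv, df1, df2, lower.tail = FALSE))
}

#' Empirical logit transform for proportion scores
#'
#' `ln((p + eps) / (1 - p + eps))` with `eps = 1 / (2 * n_units)`, so the
#' boundary proportions 0 and 1 map to finite values. For MOT session
#' accuracies the natural unit count is trials x targets (150 at
#' defaults). With `n_units = Inf` (eps = 0) this is the plain logit.
#'
#' @param p proportion(s) in `[0, 1]`.
#' @param n_units number of binary units behind the proportion
#'   (default 150).
#' @return the transformed value(s).
#' @export
logit_percent <- function(p, n_units = 150) {
  if (any(p < 0 | p > 1)) stop("proportions must lie in [0, 1]")
  eps <- 1 / (2 * n_units)
  log((p + eps) / (1 - p + eps))
}

#' Hierarchical regression specification
#'
#' Names the outcome and the two ordered predictor blocks of a
#' hierarchical OLS analysis (block 2 must contain all of block 1 plus at
#' least one addition), together with per-variable transforms applied
#' before fitting: `"log"` (natural log, e.g. for driving experience) or
#' `"logit"` (empirical logit via [logit_percent()], for proportions).
#'
#' @param outcome outcome column name.
#' @param block1 character vector of block-1 predictor names.
#' @param block2 character vector of block-2 predictor names (superset of
#'   `block1`).
#' @param transforms named character vector, values in
#'   `c("log", "logit")`, names being column names.
#' @param logit_n_units `n_units` for the logit transform (default 150).
#' @return an object of class `regression_spec`.
#' @export
regression_spec <- function(outcome, block1, block2,
                            transforms = character(), logit_n_units = 150) {
  if (!all(block1 %in% block2)) stop("block2 must contain all block1 predictors")
  if (length(setdiff(block2, block1)) < 1) {
    stop("block2 must add at least one predictor")
  }
  if (length(transforms) && !all(transforms %in% c("log", "logit"))) {
    stop("transforms must be 'log' or 'logit'")
  }
  structure(list(outcome = outcome, block1 = block1, block2 = block2,
                 transforms = transforms, logit_n_units = logit_n_units),
            class = "regression_spec")
}

apply_transforms <- function(data, spec) {
  for (v in intersect(names(spec$transforms), names(data))) {
    data[[v]] <- switch(spec$transforms[[v]],
                        log = log(data[[v]]),
                        logit = logit_percent(data[[v]], spec$logit_n_units))
  }
  data
}

#' Fit one block of a hierarchical OLS model
#'
#' Least-squares fit with intercept on the complete cases of the
#' requested block's predictors. Reports, per predictor, the raw slope
#' `b`, its standard error, the standardized slope `beta` (the slope
#' after z-scoring outcome and predictors), `t` and two-sided `p`; plus
#' the model F against the intercept-only model, R-squared, adjusted
#' R-squared `1 - (1 - R2)(n - 1)/(n - p - 1)`, and the residual sum of
#' squares used by [compare_nested()].
#'
#' @param spec a [regression_spec()].
#' @param data a data.frame (e.g. a [simulate_cohort()] table).
#' @param block which predictor block to fit, 1 or 2.
#' @return an object of class `model_fit`.
#' @export
fit_ols <- function(spec, data, block = 1) {
  stopifnot(inherits(spec, "regression_spec"), block %in% c(1, 2))
  preds <- if (block == 1) spec$block1 else spec$block2
  vars <- c(spec$outcome, preds)
  if (!all(vars %in% names(data))) {
    stop("missing columns: ", paste(setdiff(vars, names(data)), collapse = ", "))
  }
  data <- apply_transforms(data[vars], spec)
  data <- data[complete.cases(data), , drop = FALSE]
  n <- nrow(data)
  p <- length(preds)
  if (n < p + 2) stop("need at least predictors + 2 complete cases")
  fml <- stats::as.formula(paste(spec$outcome, "~",
                                 paste(preds, collapse = " + ")))
  fit <- lm(fml, data = data)
  if (fit$rank < p + 1) stop("rank-deficient design")
  sm <- summary(fit)
  ct <- sm$coefficients[preds, , drop = FALSE]
  sy <- sd(data[[spec$outcome]])
  sx <- vapply(preds, function(v) sd(data[[v]]), 1)
  coefs <- data.frame(
    term = preds,
    b = ct[, 1], se = ct[, 2],
    beta = ct[, 1] * sx / sy,
    t = ct[, 3], p = ct[, 4],
    row.names = NULL)
  rss <- sum(resid(fit)^2)
  r2 <- sm$r.squared
  structure(list(
    outcome = spec$outcome, predictors = preds, block = block,
    coefficients = coefs,
    F = unname(sm$fstatistic[1]),
    df1 = unname(sm$fstatistic[2]), df2 = unname(sm$fstatistic[3]),
    r_squared = r2,
    adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - p - 1),
    rss = rss, n = n, lm_fit = fit
  ), class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("OLS fit:", x$outcome, "~", paste(x$predictors, collapse = " + "),
      sprintf("  (n = %d)\n", x$n))
  print(format(x$coefficients, digits = 3), row.names = FALSE)
  cat(sprintf("F(%g, %g) = %.3f, R2 = %.3f, adj R2 = %.3f\n",
              x$df1, x$df2, x$F, x$r_squared, x$adj_r_squared))
  invisible(x)
}

#' Compare two nested OLS fits (F-change)
#'
#' `F_change = ((RSS1 - RSS2) / df_num) / (RSS2 / df_den)` where `df_num`
#' is the number of added predictors and `df_den = n - p2 - 1`; the p
#' value comes from the F distribution. The fits must share outcome and n,
#' and fit1's predictors must be a strict subset of fit2's.
#'
#' @param fit1,fit2 [fit_ols()] results, fit1 nested in fit2.
#' @return list with `F_change`, `df_num`, `df_den`, `p_change`.
#' @export
compare_nested <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "model_fit"), inherits(fit2, "model_fit"))
  if (fit1$outcome != fit2$outcome || fit1$n != fit2$n) {
    stop("fits must share outcome and sample")
  }
  added <- setdiff(fit2$predictors, fit1$predictors)
  if (!all(fit1$predictors %in% fit2$predictors) || length(added) == 0) {
    stop("fit1 must be strictly nested in fit2")
  }
  df_num <- length(added)
  df_den <- fit2$n - length(fit2$predictors) - 1
  Fc <- ((fit1$rss - fit2$rss) / df_num) / (fit2$rss / df_den)
  Fc <- max(Fc, 0)
  list(F_change = Fc, df_num = df_num, df_den = df_den,
       p_change = pf(Fc, df_num, df_den, lower.tail = FALSE))
}

#' Pillai-trace multivariate group test
#'
#' Tests whether group membership predicts a set of outcome variables
#' jointly, optionally partialling out a covariate (entered as a regressor
#' in the multivariate linear model; the hypothesis matrix is the group
#' term's). The Pillai trace `V = sum(lambda / (1 + lambda))` over the
#' eigenvalues of `E^-1 H` is converted to an approximate F by the
#' standard transformation.
#'
#' @param outcomes numeric matrix or data.frame of outcome columns.
#' @param group group labels (coerced to factor, >= 2 levels).
#' @param covariate optional numeric covariate (e.g. age).
#' @return list with `V`, `F`, `df1`, `df2`, `p`.
#' @export
pillai_group_test <- function(outcomes, group, covariate = NULL) {
  Y <- as.matrix(outcomes)
  storage.mode(Y) <- "double"
  group <- factor(group)
  n <- nrow(Y)
  g <- nlevels(group)
  if (g < 2) stop("need >= 2 groups")
  p <- ncol(Y)
  if (n <= p + g) stop("need n > outcomes + groups")
  X_red <- matrix(1, n, 1)
  if (!is.null(covariate)) X_red <- cbind(X_red, as.numeric(covariate))
  X_full <- cbind(X_red, stats::model.matrix(~group)[, -1, drop = FALSE])
  res_full <- Y - X_full %*% qr.coef(qr(X_full), Y)
  res_red <- Y - X_red %*% qr.coef(qr(X_red), Y)
  E <- crossprod(res_full)
  H <- crossprod(res_red) - E
  if (rcond(E) < 1e-12) stop("singular error matrix")
  lam <- Re(eigen(solve(E, H), only.values = TRUE)$values)
  lam[lam < 0] <- 0
  V <- sum(lam / (1 + lam))
  q <- g - 1                      # hypothesis df
  v <- n - ncol(X_full)           # error df
  s <- min(p, q)
  m <- (abs(p - q) - 1) / 2
  nn <- (v - p - 1) / 2
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * nn + s + 1)
  Fv <- (df2 / df1) * (V / (s - V))
  list(V = V, F = Fv, df1 = df1, df2 = df2,
       p = pf(Fv, df1, df2, lower.tail = FALSE))
}

#' Test-retest reliability report
#'
#' Bundles the two standard session-stability analyses: a paired t test
#' for a mean shift between time points, and a Pearson correlation for
#' rank stability of individuals, together with per-time descriptives
#' (n, min, max, median, mean, SD).
#'
#' @param sample a [paired_sample()].
#' @return an object of class `reliability_report`: `descriptives`
#'   (data.frame, one row per time point), `paired_t`, `pearson`.
#' @export
test_retest <- function(sample) {
  stopifnot(inherits(sample, "paired_sample"))
  desc <- function(x, label) {
    data.frame(time = label, n = length(x), min = min(x), max = max(x),
               median = median(x), mean = mean(x), sd = sd(x))
  }
  structure(list(
    descriptives = rbind(desc(sample$time1, "time1"),
                         desc(sample$time2, "time2")),
    paired_t = paired_t(sample),
    pearson = pearson_r(sample$time1, sample$time2)
  ), class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  print(format(x$descriptives, digits = 4), row.names = FALSE)
  cat(sprintf("paired t(%d) = %.3f, p = %.4f\n",
              x$paired_t$df, x$paired_t$t, x$paired_t$p))
  cat(sprintf("Pearson r(%d) = %.3f, p = %.4f\n",
              x$pearson$df, x$pearson$r, x$pearson$p))
  invisible(x)
}
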