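#' Build the segmented-regression design matrix
#'
#' Constructs the design for an interrupted time series with one or two
#' interruptions at 1-based month indices `m1` (and optionally `m2`):
#'
#' \deqn{Y_t = \beta_0 + \beta_1 t + \beta_2 I_1(t) + \beta_3 s_1(t) +
#'       \beta_4 I_2(t) + \beta_5 s_2(t) + \epsilon_t}
#'
#' where the level indicator \eqn{I_k(t)} is 1 from the interruption month
#' on, and the post-interruption clock \eqn{s_k(t)} is 0 before it and
#' \eqn{t - (m_k - 1)} afterwards (so it equals 1 in the interruption
#' month itself).  With `m2 = NULL` the second-interruption columns are
#' omitted, giving the one-interruption variant of the model.
#'
#' @param n_months Series length.
#' @param m1 First interruption month index (level switches at `t = m1`).
#' @param m2 Optional second interruption month index, `> m1`.
#' @return Data frame with columns `time`, `nims`, `time_after_nims` and,
#'   when `m2` is given, `covid`, `time_after_covid`; attributes `m1`,
#'   `m2`.  Class `its_design`.
#' @export
#' @examples
#' d <- build_design(60, 29, 50)
#' d[28:30, ]
build_design <- function(n_months, m1, m2 = NULL) {
  if (n_months < 3) stop("n_months must be at least 3")
  if (m1 <= 1 || m1 > n_months) stop("m1 must satisfy 1 < m1 <= n_months")
  if (!is.null(m2) && (m2 <= m1 || m2 > n_months)) {
    stop("m2 must satisfy m1 < m2 <= n_months")
  }
  t <- seq_len(n_months)
  # recommended practice: >= 12 observations before and after the
  # evaluated intervention (the first interruption)
  if (m1 - 1 < 12 || n_months - m1 + 1 < 12) {
    warning("fewer than 12 months before or after the first interruption; ",
            "interrupted time-series estimates may be unstable")
  }
  design <- data.frame(
    time = t,
    nims = as.integer(t >= m1),
    time_after_nims = pmax(0L, t - (m1 - 1L))
  )
  if (!is.null(m2)) {
    design$covid <- as.integer(t >= m2)
    design$time_after_covid <- pmax(0L, t - (m2 - 1L))
  }
  attr(design, "m1") <- m1
  attr(design, "m2") <- m2
  class(design) <- c("its_design", "data.frame")
  design
}

design_matrix <- function(design) {
  X <- cbind(intercept = 1, as.matrix(as.data.frame(design)))
  storage.mode(X) <- "double"
  X
}

term_labels <- function(design) {
  c("intercept", colnames(as.data.frame(design)))
}

new_its_fit <- function(estimator, coefficients, rho, sigma, loglik,
                        residuals, fitted, t_index, design, y,
                        dw = NA_real_, dw_p = NA_real_, df_residual = NA_real_) {
  structure(
    list(
      estimator = estimator,
      coefficients = coefficients,
      rho = rho,
      sigma = sigma,
      loglik = loglik,
      residuals = residuals,
      fitted = fitted,
      t_index = t_index,
      design = design,
      y = y,
      dw = dw,
      dw_p = dw_p,
      df_residual = df_residual,
      m1 = attr(design, "m1"),
      m2 = attr(design, "m2"),
      n = length(residuals)
    ),
    class = "its_fit"
  )
}

#' @export
print.its_fit <- function(x, ...) {
  cat(sprintf("Segmented interrupted time-series fit (%s), n = %d\n",
              x$estimator, x$n))
  if (!is.null(x$m2)) {
    cat(sprintf("Interruptions at months %d and %d\n", x$m1, x$m2))
  } else {
    cat(sprintf("Interruption at month %d\n", x$m1))
  }
  tab <- x$coefficients
  tab$estimate <- sprintf("%.4f", tab$estimate)
  tab$se <- sprintf("%.4f", tab$se)
  tab$statistic <- sprintf("%.2f", tab$statistic)
  tab$p_value <- format_p(x$coefficients$p_value)
  print(tab, row.names = FALSE)
  cat(sprintf("sigma = %.4f, rho = %.3f, Durbin-Watson = %.4f (p = %s)\n",
              x$sigma, x$rho, x$dw, format_p(x$dw_p)))
  invisible(x)
}

format_p <- function(p) {
  out <- ifelse(is.na(p), "NA",
         ifelse(p < 0.001, "<.001", sub("^0", "", sprintf("%.3f", p))))
  out
}

prepare_its_inputs <- function(design, y) {
  X <- design_matrix(design)
  if (length(y) != nrow(X)) {
    stop("y must have one value per design row (", nrow(X), ")")
  }
  keep <- is.finite(y)
  if (!all(keep)) {
    warning(sum(!keep), " month(s) with missing outcome dropped (listwise); ",
            "design rows keep their calendar time")
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  list(X = X, y = y, t_index = which(keep))
}

#' Ordinary least squares fit of the segmented model
#'
#' Classical linear-model fit of the interrupted time-series design with
#' exact t-based inference on `n - p` residual degrees of freedom.
#' Months with missing outcome values are dropped listwise (their design
#' rows keep the true calendar time), with a warning.
#'
#' @param design An [build_design()] object.
#' @param y Numeric outcome series, one value per design row (percentages
#'   in the claims pipeline).
#' @return An `its_fit` object.
#' @export
fit_ols <- function(design, y) {
  inp <- prepare_its_inputs(design, y)
  X <- inp$X
  yy <- inp$y
  fit <- stats::lm.fit(X, yy)
  n <- length(yy)
  p <- ncol(X)
  res <- stats::residuals(fit)
  rss <- sum(res^2)
  sigma2 <- rss / (n - p)
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * diag(xtx_inv))
  est <- stats::coef(fit)
  tval <- est / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  coefs <- data.frame(
    term = term_labels(design),
    estimate = unname(est),
    se = unname(se),
    statistic = unname(tval),
    p_value = unname(pval),
    stringsAsFactors = FALSE
  )
  sigma_ml <- sqrt(rss / n)
  loglik <- -n / 2 * (log(2 * pi * sigma_ml^2) + 1)
  new_its_fit(
    estimator = "OLS", coefficients = coefs, rho = 0,
    sigma = sqrt(sigma2), loglik = loglik,
    residuals = unname(res), fitted = unname(fit$fitted.values),
    t_index = inp$t_index, design = design, y = y,
    df_residual = n - p
  )
}

#' Durbin-Watson test for first-order serial correlation
#'
#' Computes the Durbin-Watson statistic
#' \eqn{d = \sum_t (e_t - e_{t-1})^2 / \sum_t e_t^2} of a residual series
#' and a two-sided p-value.  Under independence `d` is close to 2; values
#' toward 0 indicate positive, toward 4 negative first-order
#' autocorrelation.
#'
#' Two p-value methods are available.  `"normal"` (default) matches a
#' normal distribution to the exact null mean and variance of `d`.  When
#' the regression design `X` is supplied the classical moment formulas for
#' least-squares residuals are used
#' (\eqn{E[d] = \mathrm{tr}(AM)/(n-p)} with `A` the differencing quadratic
#' form and `M` the residual-maker matrix); without `X` the cruder
#' large-sample approximation \eqn{d \sim N(2, 4/n)} is used.
#' `"bootstrap"` builds the null distribution by Monte-Carlo permutation
#' of the residuals.
#'
#' @param residuals Numeric residual series (length >= 3) in time order.
#' @param method `"normal"` or `"bootstrap"`.
#' @param n_boot Number of permutations for the bootstrap method.
#' @param X Optional design matrix the residuals came from; sharpens the
#'   normal approximation to the design's exact null moments.
#' @return List with `statistic` and `p_value` (two-sided).
#' @export
#' @examples
#' durbin_watson(rnorm(60))
durbin_watson <- function(residuals, method = c("normal", "bootstrap"),
                          n_boot = 2000, X = NULL) {
  method <- match.arg(method)
  e <- residuals[is.finite(residuals)]
  n <- length(e)
  if (n < 3) stop("need at least 3 residuals")
  denom <- sum(e^2)
  if (denom == 0) {
    warning("all residuals are zero; Durbin-Watson statistic undefined")
    return(list(statistic = NA_real_, p_value = NA_real_))
  }
  d <- sum(diff(e)^2) / denom
  if (method == "normal") {
    if (is.null(X)) {
      mean_d <- 2
      var_d <- 4 / n
    } else {
      stopifnot(nrow(X) == n)
      p <- ncol(X)
      # A: quadratic form of the squared first differences (tridiagonal)
      A <- diag(c(1, rep(2, n - 2), 1))
      A[cbind(1:(n - 1), 2:n)] <- -1
      A[cbind(2:n, 1:(n - 1))] <- -1
      M <- diag(n) - X %*% chol2inv(chol(crossprod(X))) %*% t(X)
      AM <- A %*% M
      tr1 <- sum(diag(AM))
      tr2 <- sum(AM * t(AM))
      mean_d <- tr1 / (n - p)
      var_d <- 2 * (tr2 - tr1^2 / (n - p)) / ((n - p) * (n - p + 2))
    }
    z <- (d - mean_d) / sqrt(var_d)
    pval <- 2 * stats::pnorm(-abs(z))
  } else {
    boot <- replicate(n_boot, {
      eb <- sample(e)
      sum(diff(eb)^2) / sum(eb^2)
    })
    pval <- min(1, 2 * min(mean(boot <= d), mean(boot >= d)))
  }
  list(statistic = d, p_value = pval)
}

# Exact Gaussian log-likelihood of the regression with stationary AR(1)
# errors, profiled over (beta, sigma) at a fixed rho.  For a gapless
# series the Prais-Winsten transform gives the likelihood in O(n); with
# gaps (listwise-deleted months) the general AR(1) correlation matrix
# rho^|t_i - t_j| is used via its Cholesky factor.
ar1_profile <- function(rho, X, y, t_index) {
  n <- length(y)
  gapless <- all(diff(t_index) == 1)
  if (gapless) {
    w1 <- sqrt(1 - rho^2)
    ys <- c(w1 * y[1], y[-1] - rho * y[-n])
    Xs <- rbind(w1 * X[1, ], X[-1, , drop = FALSE] - rho * X[-n, , drop = FALSE])
    logdet_R <- -log(1 - rho^2)
  } else {
    R <- rho^abs(outer(t_index, t_index, "-"))
    L <- chol(R)
    ys <- backsolve(L, y, transpose = TRUE)
    Xs <- backsolve(L, X, transpose = TRUE)
    logdet_R <- 2 * sum(log(diag(L)))
  }
  qx <- qr(Xs)
  beta <- qr.coef(qx, ys)
  rss <- sum(qr.resid(qx, ys)^2)
  sigma2 <- rss / n
  loglik <- -n / 2 * (log(2 * pi * sigma2) + 1) - logdet_R / 2
  list(loglik = loglik, beta = beta, sigma2 = sigma2, Xs = Xs)
}

#' Maximum-likelihood fit with stationary AR(1) errors
#'
#' Fits the segmented model by maximizing the exact Gaussian likelihood of
#' a linear regression whose errors follow a stationary first-order
#' autoregression \eqn{\epsilon_t = \rho \epsilon_{t-1} + u_t}.  The
#' likelihood is profiled: for each candidate \eqn{\rho} the generalized
#' least-squares coefficients and error variance have closed forms, and
#' the resulting one-dimensional profile is maximized over
#' \eqn{\rho \in [-0.99, 0.99]} by golden-section search.
#'
#' Standard errors come from the observed information at the optimum
#' (the GLS covariance for the coefficients, the profile curvature for
#' \eqn{\rho}); p-values use the large-sample normal reference.
#'
#' @inheritParams fit_ols
#' @param rho_bounds Search interval for the autocorrelation parameter.
#' @return An `its_fit` object with `estimator = "AR1-ML"`.
#' @export
fit_ar1_ml <- function(design, y, rho_bounds = c(-0.99, 0.99)) {
  inp <- prepare_its_inputs(design, y)
  X <- inp$X
  yy <- inp$y
  t_index <- inp$t_index
  opt <- stats::optimize(
    function(r) ar1_profile(r, X, yy, t_index)$loglik,
    interval = rho_bounds, maximum = TRUE, tol = 1e-8
  )
  rho_hat <- opt$maximum
  prof <- ar1_profile(rho_hat, X, yy, t_index)
  if (!all(is.finite(prof$beta))) {
    stop("AR(1) maximum-likelihood fit failed to converge: ",
         "non-finite coefficients at rho = ", signif(rho_hat, 4))
  }
  n <- length(yy)
  sigma2 <- prof$sigma2
  cov_beta <- sigma2 * chol2inv(chol(crossprod(prof$Xs)))
  se <- sqrt(diag(cov_beta))
  est <- prof$beta
  zval <- est / se
  pval <- 2 * stats::pnorm(-abs(zval))
  coefs <- data.frame(
    term = term_labels(design),
    estimate = unname(est),
    se = unname(se),
    statistic = unname(zval),
    p_value = unname(pval),
    stringsAsFactors = FALSE
  )
  fitted <- drop(X %*% est)
  new_its_fit(
    estimator = "AR1-ML", coefficients = coefs, rho = rho_hat,
    sigma = sqrt(sigma2), loglik = prof$loglik,
    residuals = yy - fitted, fitted = fitted,
    t_index = t_index, design = design, y = y,
    df_residual = n - ncol(X)
  )
}

#' Fit the segmented model with Durbin-Watson-guided estimator choice
#'
#' Fits ordinary least squares first and tests the residuals for
#' first-order serial correlation with [durbin_watson()].  If the test is
#' significant at `alpha`, the model is refitted by exact AR(1) maximum
#' likelihood ([fit_ar1_ml()]) and that fit is returned; otherwise the OLS
#' fit is returned.  Either way the OLS Durbin-Watson statistic and its
#' p-value are carried on the returned object for reporting.
#'
#' @inheritParams fit_ols
#' @param alpha Significance level for the serial-correlation test.
#' @param estimator `"auto"` (default, the Durbin-Watson rule), or force
#'   `"ols"` / `"ar1"`.
#' @param dw_method Passed to [durbin_watson()].
#' @return An `its_fit` object.
#' @export
#' @examples
#' d <- build_design(60, 29, 50)
#' y <- 0.8 + 0.004 * d$time + 0.17 * d$nims + rnorm(60, sd = 0.2)
#' fit_its(d, y)
fit_its <- function(design, y, alpha = 0.05,
                    estimator = c("auto", "ols", "ar1"),
                    dw_method = "normal") {
  estimator <- match.arg(estimator)
  ols <- fit_ols(design, y)
  dw <- durbin_watson(ols$residuals, method = dw_method,
                      X = design_matrix(design)[ols$t_index, , drop = FALSE])
  ols$dw <- dw$statistic
  ols$dw_p <- dw$p_value
  use_ar1 <- switch(estimator,
    auto = !is.na(dw$p_value) && dw$p_value < alpha,
    ols = FALSE,
    ar1 = TRUE
  )
  if (!use_ar1) return(ols)
  ar1 <- fit_ar1_ml(design, y)
  ar1$dw <- dw$statistic
  ar1$dw_p <- dw$p_value
  ar1
}

its_coef <- function(fit, term) {
  i <- match(term, fit$coefficients$term)
  if (is.na(i)) stop("fit has no coefficient '", term, "'")
  fit$coefficients$estimate[i]
}

#' Post-interruption slope
#'
#' The slope of the outcome after an interruption is the baseline trend
#' plus the accumulated trend changes: after the first interruption it is
#' \eqn{\beta_1 + \beta_3}; after the second, \eqn{\beta_1 + \beta_3 +
#' \beta_5}.
#'
#' @param fit An `its_fit`.
#' @param which `"after_first"` or `"after_second"`.
#' @return The post-interruption slope (scalar).
#' @export
#' @examples
#' d <- build_design(60, 29, 50)
#' f <- fit_ols(d, 0.79 + 0.004 * d$time + 0.027 * d$time_after_nims)
#' post_slope(f, "after_first")
post_slope <- function(fit, which = c("after_first", "after_second")) {
  which <- match.arg(which)
  s <- its_coef(fit, "time") + its_coef(fit, "time_after_nims")
  if (which == "after_second") {
    if (is.null(fit$m2)) {
      stop("fit has a single interruption; 'after_second' is undefined")
    }
    s <- s + its_coef(fit, "time_after_covid")
  }
  s
}

#' Fitted segment lines and counterfactual extensions
#'
#' Returns, for every month of the design, the model-fitted mean together
#' with the counterfactual lines used in interruption plots: the
#' pre-interruption model extended forward by setting all terms of later
#' interruptions to zero.  `counterfactual_baseline` extends the
#' pre-first-interruption line (\eqn{\beta_0 + \beta_1 t}) over the whole
#' window; `counterfactual_pre_second` (two-interruption fits only)
#' extends the post-first-interruption model past the second interruption
#' by zeroing its level and trend terms.
#'
#' @param fit An `its_fit`.
#' @param design Optionally a different design (e.g. a longer grid for
#'   extrapolation); defaults to the fit's own design.
#' @return Data frame with columns `time`, `fitted`,
#'   `counterfactual_baseline` and, when applicable,
#'   `counterfactual_pre_second`.
#' @export
predict_lines <- function(fit, design = fit$design) {
  X <- design_matrix(design)
  beta <- fit$coefficients$estimate
  out <- data.frame(
    time = as.data.frame(design)$time,
    fitted = drop(X %*% beta)
  )
  X0 <- X
  X0[, setdiff(colnames(X), c("intercept", "time"))] <- 0
  out$counterfactual_baseline <- drop(X0 %*% beta)
  if (!is.null(attr(design, "m2"))) {
    X1 <- X
    X1[, c("covid", "time_after_covid")] <- 0
    out$counterfactual_pre_second <- drop(X1 %*% beta)
  }
  out
}

#' Residual autocorrelation diagnostics
#'
#' Sample autocorrelation (from lag 0) and partial autocorrelation (from
#' lag 1) of the fit residuals, with the usual \eqn{\pm 1.96/\sqrt{n}}
#' white-noise bounds, for goodness-of-fit review.
#'
#' @param fit An `its_fit`.
#' @param max_lag Largest lag (default 20, capped at `n - 2`).
#' @return List with data frames `acf` and `pacf` (columns `lag`, `value`)
#'   and the scalar `bound`.
#' @export
residual_diagnostics <- function(fit, max_lag = 20) {
  e <- fit$residuals
  n <- length(e)
  max_lag <- min(max_lag, n - 2)
  if (max_lag < 1) stop("need at least max_lag + 2 residuals")
  a <- stats::acf(e, lag.max = max_lag, plot = FALSE, demean = TRUE)
  p <- stats::pacf(e, lag.max = max_lag, plot = FALSE, demean = TRUE)
  list(
    acf = data.frame(lag = 0:max_lag, value = drop(a$acf)),
    pacf = data.frame(lag = 1:max_lag, value = drop(p$acf)),
    bound = 1.96 / sqrt(n)
  )
}
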