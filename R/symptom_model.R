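#' Standardize predictor columns
#'
#' Centers and scales every column to zero mean and unit SD, recording the
#' per-column center and scale so the transform can be undone.
#'
#' @param x Numeric matrix or data frame of predictors.
#' @return Matrix of the same shape with attributes `center` and `scale`.
#' @export
standardize_predictors <- function(x) {
  m <- as.matrix(x)
  if (!is.numeric(m)) abort("Predictors must be numeric.")
  ctr <- colMeans(m)
  scl <- apply(m, 2, sd)
  if (any(scl == 0)) {
    bad <- colnames(m)[scl == 0]
    if (is.null(bad)) bad <- which(scl == 0)
    abort(paste0("Zero-SD column(s): ", paste(bad, collapse = ", ")))
  }
  out <- sweep(sweep(m, 2, ctr), 2, scl, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' Undo [standardize_predictors()]
#' @param x A standardized matrix carrying `center`/`scale` attributes.
#' @return The matrix on its original scale.
#' @export
unstandardize_predictors <- function(x) {
  ctr <- attr(x, "center")
  scl <- attr(x, "scale")
  if (is.null(ctr) || is.null(scl)) abort("Missing standardization record.")
  out <- sweep(sweep(unclass(x), 2, scl, "*"), 2, ctr, "+")
  attr(out, "center") <- NULL
  attr(out, "scale") <- NULL
  out
}

#' Elastic-net fit with cross-validated penalty
#'
#' Fits the elastic net (penalty `lambda * [alpha * ||b||_1 +
#' (1 - alpha) * ||b||_2^2 / 2]`) over a logarithmic lambda path and picks
#' lambda by k-fold cross-validation minimizing mean squared prediction
#' error, with seed-controlled fold assignment. The predictors are expected
#' already standardized; the response is left on its original scale.
#'
#' The solver follows the usual penalized-regression convention of measuring
#' the ridge component relative to the response's (population) SD, so the
#' objective at the reported `lambda` is `RSS / (2n) + lambda * [alpha *
#' ||b||_1 + (1 - alpha) / (2 * sd_n(y)) * ||b||_2^2]`. At `alpha = 1`
#' (lasso) this is exactly the plain objective; at intermediate `alpha` it
#' amounts to a slight reweighting of the mixing that is absorbed by the
#' cross-validated choice of `lambda` and does not affect which predictors
#' are nonzero at a given penalty strength.
#'
#' @param x Standardized predictor matrix (n x p, n >= 10 recommended).
#' @param y Numeric response.
#' @param alpha Elastic-net mixing in (0, 1]; 0.5 approaches the elastic
#'   net midway between lasso and ridge, 1 is the lasso.
#' @param seed Integer seed for the fold assignment.
#' @param nfolds Number of CV folds (default 10).
#' @param nlambda Length of the lambda path (default 100).
#' @param lambda_rule `"1se"` (default: the sparsest lambda within one
#'   standard error of the CV minimum, which keeps the bootstrap inclusion
#'   counts well calibrated at small n) or `"min"` (the CV-minimizing
#'   lambda, more inclusive).
#' @param penalty_factor Optional per-predictor penalty multipliers
#'   (0 = never penalized, i.e. always included); default 1 for all.
#' @return List with `coef` (named vector, no intercept), `intercept`,
#'   `lambda`, `lambda_path`, `cv_mse`, `degenerate` (TRUE when the
#'   response is constant, in which case all coefficients are zero).
#' @export
elastic_net_fit <- function(x, y, alpha = 0.5, seed = 1, nfolds = 10,
                            nlambda = 100, lambda_rule = c("1se", "min"),
                            penalty_factor = NULL) {
  lambda_rule <- match.arg(lambda_rule)
  x <- as.matrix(x)
  n <- nrow(x)
  if (length(y) != n) abort("`x` and `y` sizes disagree.")
  if (alpha <= 0 || alpha > 1) abort("`alpha` must be in (0, 1].")
  p <- ncol(x)
  empty <- stats::setNames(rep(0, p), colnames(x))
  if (sd(y) == 0) {
    return(list(coef = empty, intercept = mean(y), lambda = Inf,
                lambda_path = numeric(0), cv_mse = numeric(0),
                degenerate = TRUE))
  }
  if (is.null(penalty_factor)) penalty_factor <- rep(1, p)
  full <- glmnet::glmnet(x, y, alpha = alpha, standardize = FALSE,
                         nlambda = nlambda, penalty.factor = penalty_factor)
  lambda_path <- full$lambda
  nfolds_eff <- min(nfolds, n)
  foldid <- with_seed(derive_seed(seed, 7L),
                      sample(rep(seq_len(nfolds_eff), length.out = n)))
  sqerr <- matrix(NA_real_, n, length(lambda_path))
  for (k in seq_len(nfolds_eff)) {
    tr <- foldid != k
    fit_k <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr], alpha = alpha,
                            standardize = FALSE, lambda = lambda_path,
                            penalty.factor = penalty_factor)
    pred <- predict(fit_k, x[!tr, , drop = FALSE])
    got <- seq_len(ncol(pred))
    sqerr[!tr, got] <- (y[!tr] - pred)^2
  }
  cv_mse <- colMeans(sqerr)
  ok <- which(!is.na(cv_mse))
  i_min <- ok[which.min(cv_mse[ok])]
  if (lambda_rule == "1se") {
    se <- apply(sqerr, 2, function(col) {
      sd(col, na.rm = TRUE) / sqrt(sum(!is.na(col)))
    })
    bound <- cv_mse[i_min] + se[i_min]
    i_sel <- ok[ok <= i_min & cv_mse[ok] <= bound]
    i_min <- if (length(i_sel)) min(i_sel) else i_min
  }
  lambda <- lambda_path[i_min]
  beta <- as.numeric(coef(full, s = lambda, exact = FALSE))
  list(coef = stats::setNames(beta[-1], colnames(x)), intercept = beta[1],
       lambda = lambda, lambda_path = lambda_path, cv_mse = cv_mse,
       degenerate = FALSE)
}

#' Bootstrapping-enhanced elastic-net variable selection (VIP)
#'
#' For each of `B` bootstrap resamples of the rows (resample b uses seed
#' `seed + b`), fits [elastic_net_fit()] and counts a predictor as included
#' when its coefficient is nonzero (|coef| > 1e-12) at the CV-selected
#' penalty. The variable inclusion probability (VIP) of a predictor is its
#' inclusion count divided by B; predictors are selected when their VIP
#' strictly exceeds `threshold` ("more than 70%"). Resamples in which any
#' predictor loses all variance are refused and redrawn (counted in
#' `n_redraws`).
#'
#' @param x Predictor matrix or data frame (standardized internally).
#' @param y Numeric response (e.g. a PANSS subscale score).
#' @param alpha Elastic-net mixing (default 0.5).
#' @param B Number of bootstrap resamples (default 5000; 500 is a
#'   reasonable scaled-down setting for quick runs).
#' @param threshold VIP selection threshold (default 0.70).
#' @param seed Integer seed.
#' @param nfolds,nlambda,lambda_rule Passed to [elastic_net_fit()].
#' @param force_include Predictor names exempt from the penalty (always
#'   fitted, hence VIP 1), e.g. a co-predictor that must stay in every
#'   model. Default: none — every predictor competes for selection.
#' @return Object of class `vip_result`: list with `vip` (named vector),
#'   `selected` (character), `threshold`, `alpha`, `B`, `seed`,
#'   `n_redraws`.
#' @export
bootstrap_vip <- function(x, y, alpha = 0.5, B = 5000, threshold = 0.70,
                          seed = 1, nfolds = 10, nlambda = 100,
                          lambda_rule = "1se", force_include = character(0)) {
  if (B < 1) abort("`B` must be at least 1.")
  xs <- standardize_predictors(x)
  n <- nrow(xs)
  p <- ncol(xs)
  if (anyNA(xs) || anyNA(y)) abort("Missing values are not allowed here.")
  counts <- stats::setNames(numeric(p), colnames(xs))
  bad_force <- setdiff(force_include, colnames(xs))
  if (length(bad_force)) {
    abort(paste0("Unknown force_include predictor(s): ",
                 paste(bad_force, collapse = ", ")))
  }
  pen <- ifelse(colnames(xs) %in% force_include, 0, 1)
  n_redraws <- 0L
  for (b in seq_len(B)) {
    attempt <- 0L
    repeat {
      idx <- with_seed(derive_seed(seed, 8L, b, attempt),
                       sample.int(n, n, replace = TRUE))
      xb <- xs[idx, , drop = FALSE]
      if (all(matrixStats_colSds(xb) > 0)) break
      attempt <- attempt + 1L
      n_redraws <- n_redraws + 1L
      if (attempt > 100) abort("Could not draw a non-degenerate resample.")
    }
    fit <- elastic_net_fit(xb, y[idx], alpha = alpha,
                           seed = derive_seed(seed, 8L, b, 999L),
                           nfolds = nfolds, nlambda = nlambda,
                           lambda_rule = lambda_rule, penalty_factor = pen)
    counts <- counts + (abs(fit$coef) > 1e-12 | pen == 0)
  }
  vip <- counts / B
  structure(list(
    vip = vip, selected = names(vip)[vip > threshold],
    threshold = threshold, alpha = alpha, B = B, seed = seed,
    n_redraws = n_redraws
  ), class = "vip_result")
}

# column SDs without extra dependencies
matrixStats_colSds <- function(m) apply(m, 2, sd)

#' @export
print.vip_result <- function(x, ...) {
  cat(sprintf("Bootstrap VIP (alpha = %g, B = %d, threshold = %.2f)\n",
              x$alpha, x$B, x$threshold))
  v <- sort(x$vip, decreasing = TRUE)
  for (nm in names(v)) {
    cat(sprintf("  %-12s %.3f%s\n", nm, v[nm],
                if (nm %in% x$selected) "  *selected*" else ""))
  }
  invisible(x)
}

#' OLS refit of the selected predictors
#'
#' Refits the VIP-selected predictors (standardized) plus optional dummy
#' co-predictors (entered as 0/1, unstandardized) by ordinary least
#' squares, because penalized regression biases coefficient estimates.
#' Reported betas are standardized coefficients
#' (`beta * sd(x) / sd(y)`; for standardized predictors this is
#' `beta / sd(y)` times the raw coefficient).
#'
#' @param x Matrix or data frame of the selected predictors (raw scale;
#'   standardized internally).
#' @param y Numeric response.
#' @param co_predictors Optional data frame / matrix of dummy co-predictors
#'   (0/1 columns, e.g. medication use), left unstandardized.
#' @return Object of class `ols_refit`: list with `fit` (the `lm`),
#'   `beta_std` (standardized coefficients, no intercept), `r_squared`,
#'   `adj_r_squared`, `n`, `p`, `sd_y`, and the term names.
#' @export
ols_refit <- function(x, y, co_predictors = NULL) {
  xs <- standardize_predictors(x)
  d <- as.data.frame(xs)
  if (!is.null(co_predictors)) {
    cp <- as.data.frame(co_predictors)
    if (nrow(cp) != nrow(d)) abort("Co-predictor rows disagree with `x`.")
    d <- cbind(d, cp)
  }
  d$.y <- y
  fit <- lm(.y ~ ., data = d)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("Collinear column(s): ", paste(bad, collapse = ", ")))
  }
  sm <- summary(fit)
  sds <- vapply(d[setdiff(names(d), ".y")], sd, numeric(1))
  beta_std <- coef(fit)[-1] * sds / sd(y)
  structure(list(
    fit = fit, beta_std = beta_std,
    r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
    n = nrow(d), p = length(beta_std), sd_y = sd(y),
    terms = names(beta_std)
  ), class = "ols_refit")
}

#' @export
print.ols_refit <- function(x, ...) {
  cat(sprintf("OLS refit: n = %d, R^2 = %.3f, adjusted R^2 = %.3f\n",
              x$n, x$r_squared, x$adj_r_squared))
  print(round(x$beta_std, 3))
  invisible(x)
}

#' Hierarchical R-squared change for an added co-predictor
#'
#' Adds one column (e.g. a medication or group dummy) to a fitted
#' [ols_refit()] model and tests the R-squared increment with the
#' hierarchical F-test `F = (R2_full - R2_base) / ((1 - R2_full) /
#' (n - p_full - 1))`. A constant (zero-variance) added column yields a
#' change of exactly 0.
#'
#' @param base An [ols_refit()] model.
#' @param added Numeric vector (the new column), same length as the
#'   response.
#' @param name Column name for the added term.
#' @return One-row tibble: `r2_base`, `r2_full`, `r2_change`, `beta_std`
#'   (standardized coefficient of the added term), `f`, `df1`, `df2`, `p`.
#' @export
r2_change <- function(base, added, name = "added") {
  stopifnot(inherits(base, "ols_refit"))
  y <- base$fit$model$.y
  if (length(added) != length(y)) abort("`added` has the wrong length.")
  if (sd(added) == 0) {
    return(tibble::tibble(r2_base = base$r_squared, r2_full = base$r_squared,
                          r2_change = 0, beta_std = 0, f = 0,
                          df1 = 1, df2 = base$n - base$p - 2, p = 1))
  }
  d <- base$fit$model
  d[[name]] <- added
  full <- lm(.y ~ ., data = d)
  if (any(is.na(coef(full)))) {
    abort("The added column is collinear with the base model.")
  }
  r2_full <- summary(full)$r.squared
  change <- r2_full - base$r_squared
  df2 <- base$n - (base$p + 1) - 1
  f_stat <- change / ((1 - r2_full) / df2)
  tibble::tibble(
    r2_base = base$r_squared, r2_full = r2_full, r2_change = change,
    beta_std = unname(coef(full)[name] * sd(added) / base$sd_y),
    f = f_stat, df1 = 1, df2 = df2, p = pf(f_stat, 1, df2, lower.tail = FALSE)
  )
}
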