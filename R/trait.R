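TRAIT_OUTCOMES <- c("bis_total", "bis_motor", "bis_nonplanning", "bis_attention",
                    "upps_total", "upps_urgency", "upps_perseverance",
                    "upps_premeditation", "upps_sensation")

#' Feature-trait Pearson correlations
#'
#' Pairwise Pearson correlations, over complete cases, between every passive
#' feature column and every trait column, with two-sided p values. Constant
#' columns yield `NA` (undefined correlation).
#'
#' @param features Data frame or matrix of passive features (participants in
#'   rows); non-numeric columns such as `participant_id` are dropped.
#' @param traits Data frame of trait scores aligned to the same participants.
#' @return List of matrices `r`, `p`, and `n` (features in rows, traits in
#'   columns).
#' @export
correlate_traits <- function(features, traits) {
  fdf <- as.data.frame(features)
  tdf <- as.data.frame(traits)
  fx <- as.matrix(fdf[vapply(fdf, is.numeric, TRUE)])
  tx <- as.matrix(tdf[vapply(tdf, is.numeric, TRUE)])
  r <- p <- n <- matrix(NA_real_, ncol(fx), ncol(tx),
                        dimnames = list(colnames(fx), colnames(tx)))
  for (i in seq_len(ncol(fx))) {
    for (j in seq_len(ncol(tx))) {
      ok <- stats::complete.cases(fx[, i], tx[, j])
      n[i, j] <- sum(ok)
      if (n[i, j] < 3 || stats::sd(fx[ok, i]) == 0 || stats::sd(tx[ok, j]) == 0) next
      ct <- stats::cor.test(fx[ok, i], tx[ok, j])
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  list(r = r, p = p, n = n)
}

# Closed-form Lasso for a single predictor (soft thresholding), used when the
# design has one column and coordinate descent is overkill.
soft_threshold <- function(z, lambda) sign(z) * pmax(abs(z) - lambda, 0)

#' Lasso feature selection
#'
#' Fits the Lasso at a single fixed penalty and returns the indices of
#' features with nonzero coefficients. The penalty is on the scale of the
#' standard Lasso objective `(1/2n)||y - Xb||^2 + penalty * ||b||_1`, applied
#' to column-standardized predictors and a centered response (the caller's
#' responsibility; see [standardize_columns()]).
#'
#' @param X Numeric matrix of standardized predictors.
#' @param y Numeric response (centered).
#' @param penalty Regularization strength (default 0.05).
#' @return Integer vector of selected column indices (possibly empty, meaning
#'   "no model").
#' @export
lasso_select <- function(X, y, penalty = 0.05) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), penalty >= 0)
  if (stats::sd(y) == 0) return(integer())
  if (ncol(X) == 1L) {
    b <- soft_threshold(mean(X[, 1] * (y - mean(y))), penalty) /
      mean(X[, 1]^2)
    return(if (abs(b) > 0) 1L else integer())
  }
  fit <- glmnet::glmnet(X, y, alpha = 1, lambda = penalty,
                        standardize = FALSE, intercept = TRUE,
                        thresh = 1e-12)
  beta <- as.vector(fit$beta)
  sel <- which(beta != 0)
  attr(sel, "coefficients") <- beta[sel]
  sel
}

#' Column standardization
#'
#' Center and scale columns to mean 0, SD 1; constant columns become 0.
#' Optionally apply centering/scaling statistics learned elsewhere (e.g. a
#' training fold).
#'
#' @param X Matrix or data frame of numeric columns.
#' @param center,scale Optional vectors of precomputed statistics.
#' @return Matrix with attributes `center` and `scale`.
#' @export
standardize_columns <- function(X, center = NULL, scale = NULL) {
  X <- as.matrix(X)
  center <- center %||% colMeans(X)
  scale <- scale %||% apply(X, 2, stats::sd)
  scale[scale == 0 | is.na(scale)] <- 1
  out <- sweep(sweep(X, 2, center, "-"), 2, scale, "/")
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

#' OLS refit on Lasso-selected features
#'
#' Ordinary least squares on the selected columns, reported the way small-n
#' sensing studies summarise trait models: per-coefficient estimates with t
#' tests, the overall F statistic on (k, n - k - 1) degrees of freedom, and
#' adjusted R^2 = 1 - (1 - R^2)(n - 1)/(n - k - 1). The p values are naive
#' post-selection values (no selective-inference correction); a warning notes
#' that they are optimistic when selection was data-driven.
#'
#' @param X Matrix of predictor columns (already subset to the selection).
#' @param y Response vector.
#' @param outcome Label for the report.
#' @param warn_postselection Emit the optimism warning (default FALSE).
#' @return A `trait_model_report` list: `outcome`, `features`,
#'   `coefficients` (data frame), `F`, `df1`, `df2`, `p`, `r2`, `adj_r2`, `n`.
#' @export
ols_refit <- function(X, y, outcome = "trait", warn_postselection = FALSE) {
  X <- as.matrix(X)
  n <- length(y)
  k <- ncol(X)
  if (k < 1L) stop("no predictors selected: no model")
  if (n <= k + 1L) stop("need n > k + 1 observations for the OLS refit")
  if (qr(cbind(1, X))$rank < k + 1L) {
    qx <- qr(cbind(1, X))
    dropped <- colnames(X)[setdiff(seq_len(k), qx$pivot[seq_len(qx$rank)] - 1L)]
    stop("rank-deficient design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  if (warn_postselection) {
    warning("p values are not adjusted for feature selection and are optimistic")
  }
  df <- data.frame(y = y, X)
  fit <- stats::lm(y ~ ., data = df)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  coefs <- as.data.frame(sm$coefficients[-1, , drop = FALSE])
  names(coefs) <- c("beta", "se", "t", "p")
  coefs <- cbind(feature = colnames(X), coefs)
  rownames(coefs) <- NULL
  structure(list(
    outcome = outcome,
    features = colnames(X),
    coefficients = coefs,
    F = unname(fstat[1]), df1 = unname(fstat[2]), df2 = unname(fstat[3]),
    p = unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    r2 = sm$r.squared, adj_r2 = sm$adj.r.squared, n = n,
    fitted = stats::fitted(fit)
  ), class = "trait_model_report")
}

#' Leave-one-subject-out support vector regression
#'
#' For each participant in turn: standardize features and (optionally)
#' re-select them on the remaining n - 1 participants, fit a linear
#' epsilon-SVR (C = 1, epsilon = 0.1 by default), and predict the held-out
#' score. The held-out row never contributes to fold standardization,
#' selection, or fitting. Performance is summarised by the mean absolute
#' error and the Pearson correlation between predicted and true scores.
#'
#' @param X Participant x feature matrix (raw scale; fold standardization is
#'   internal).
#' @param y Trait scores.
#' @param selection `"per_fold"` (Lasso re-selection inside each training
#'   fold, the default) or `"all"` (all features every fold).
#' @param penalty Lasso penalty used when `selection = "per_fold"`.
#' @param cost,epsilon Linear SVR hyperparameters.
#' @param outcome Label for the report.
#' @return A `loso_prediction_report` list: `predicted`, `true`, `mae`, `r`,
#'   `p` (both `NA` when predictions are constant), `n`.
#' @export
loso_svr <- function(X, y, selection = c("per_fold", "all"), penalty = 0.05,
                     cost = 1, epsilon = 0.1, outcome = "trait") {
  selection <- match.arg(selection)
  X <- as.matrix(X)
  n <- length(y)
  if (n < 3L) stop("leave-one-subject-out needs at least 3 participants")
  pred <- numeric(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    Ztr <- standardize_columns(Xtr)
    Zte <- standardize_columns(X[i, , drop = FALSE],
                               center = attr(Ztr, "center"),
                               scale = attr(Ztr, "scale"))
    keep <- if (selection == "per_fold") {
      lasso_select(Ztr, ytr - mean(ytr), penalty = penalty)
    } else {
      seq_len(ncol(Ztr))
    }
    if (length(keep) == 0L) {
      pred[i] <- mean(ytr)
      next
    }
    fit <- e1071::svm(Ztr[, keep, drop = FALSE], ytr,
                      type = "eps-regression", kernel = "linear",
                      cost = cost, epsilon = epsilon, scale = FALSE)
    pred[i] <- as.numeric(stats::predict(fit, Zte[, keep, drop = FALSE]))
  }
  mae <- mean(abs(pred - y))
  if (stats::sd(pred) > 0 && stats::sd(y) > 0) {
    ct <- stats::cor.test(pred, y)
    r <- unname(ct$estimate); p <- ct$p.value
  } else {
    r <- NA_real_; p <- NA_real_
  }
  structure(list(outcome = outcome, predicted = pred, true = y,
                 mae = mae, r = r, p = p, n = n),
            class = "loso_prediction_report")
}

#' Run the full trait pipeline
#'
#' For each trait outcome (BIS-15 and UPPS totals and subscales):
#' standardize the 15 features across the sample, select features by Lasso,
#' refit by OLS, and evaluate out-of-sample predictive power by
#' leave-one-subject-out linear SVR. Complete-case per outcome.
#'
#' @param features Data frame with `participant_id` and the 15 feature
#'   columns (full-study windows).
#' @param traits Data frame with `participant_id` and the trait score
#'   columns.
#' @param penalty Lasso penalty (default 0.05).
#' @param outcomes Trait columns to model (defaults to the nine standard
#'   scores present in `traits`).
#' @param loso Also run the LOSO-SVR evaluation (default TRUE).
#' @return Named list per outcome with elements `selected`, `model` (a
#'   `trait_model_report` or `NULL` when nothing was selected) and `loso`.
#' @export
run_trait_battery <- function(features, traits, penalty = 0.05,
                              outcomes = NULL, loso = TRUE) {
  outcomes <- outcomes %||% intersect(TRAIT_OUTCOMES, names(traits))
  m <- merge(features, traits, by = "participant_id")
  fcols <- intersect(feature_names(), names(m))
  out <- list()
  for (oc in outcomes) {
    ok <- stats::complete.cases(m[, c(fcols, oc)])
    Xr <- as.matrix(m[ok, fcols])
    y <- m[[oc]][ok]
    Z <- standardize_columns(Xr)
    sel <- lasso_select(Z, y - mean(y), penalty = penalty)
    if (length(sel) > length(y) - 2) {
      # the refit needs n > k + 1; keep the largest Lasso coefficients
      keep <- order(abs(attr(sel, "coefficients")),
                    decreasing = TRUE)[seq_len(length(y) - 2)]
      warning("selection for ", oc, " capped at n - 2 features")
      sel <- sort(sel[keep])
    }
    model <- if (length(sel)) {
      ols_refit(Z[, sel, drop = FALSE], y, outcome = oc)
    } else NULL
    rep_loso <- if (loso) {
      loso_svr(Xr, y, penalty = penalty, outcome = oc)
    } else NULL
    out[[oc]] <- list(outcome = oc, selected = fcols[sel], model = model,
                      loso = rep_loso)
  }
  out
}
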