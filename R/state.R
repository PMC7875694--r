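STATE_OUTCOMES <- c(
  "am_distracted", "am_impulsive", "am_thrill", "am_bored", "am_aimless",
  "pm_distracted", "pm_impulsive", "pm_thrill", "pm_bored", "pm_aimless",
  "prev_negative", "prev_impulsive", "prev_unproductive", "prev_stressed",
  "prev_unhealthy",
  "pam_positive", "pam_negative",
  "bart_risk", "bart_gains",
  "gng_latency", "gng_commission", "gng_omission",
  "dd_present_bias"
)

#' Gaussian GEE with exchangeable working correlation
#'
#' Marginal linear regression for clustered daily data, estimated by
#' generalized estimating equations: coefficient updates by generalized
#' least squares under the working correlation, a moment estimator of the
#' exchangeable correlation from Pearson residual cross-products, and a
#' robust (sandwich) covariance for inference. With `corstr =
#' "independence"` the point estimates coincide with pooled OLS.
#'
#' Alongside the coefficient table the fit reports the estimated working
#' correlation (the "within-group correlation" of repeated-measures
#' summaries) and the in-sample Pearson correlation between marginal fitted
#' values and observations, with its two-sided p value.
#'
#' @param X Matrix or data frame of covariates (no intercept column; one is
#'   added).
#' @param y Numeric outcome, one value per row of `X`.
#' @param id Cluster (participant) identifier per row.
#' @param corstr Working correlation structure.
#' @param maxit,tol Iteration controls.
#' @return A `gee_fit` list: `coefficients` (data frame with robust SEs and
#'   Wald z/p), `alpha` (working correlation), `phi` (scale), `fitted`, `r`,
#'   `p`, `n_obs`, `n_clusters`, `converged`.
#' @export
fit_gee <- function(X, y, id, corstr = c("exchangeable", "independence"),
                    maxit = 100, tol = 1e-10) {
  corstr <- match.arg(corstr)
  X <- as.matrix(cbind("(Intercept)" = 1, as.matrix(X)))
  storage.mode(X) <- "double"
  n <- length(y)
  stopifnot(nrow(X) == n, length(id) == n)
  id <- as.character(id)
  if (length(unique(id)) < 2L) stop("need at least 2 clusters")
  p <- ncol(X)
  if (qr(X)$rank < p) stop("singular design matrix")
  idx <- split(seq_len(n), id)
  sizes <- lengths(idx)

  beta <- stats::lm.fit(X, y)$coefficients
  alpha <- 0
  converged <- FALSE
  phi <- NA_real_
  for (it in seq_len(maxit)) {
    e <- y - X %*% beta
    phi <- sum(e^2) / (n - p)
    if (corstr == "exchangeable") {
      num <- 0; den <- 0
      for (ix in idx) {
        ni <- length(ix)
        if (ni < 2L) next
        ei <- e[ix]
        num <- num + (sum(ei)^2 - sum(ei^2)) / 2
        den <- den + ni * (ni - 1) / 2
      }
      alpha <- num / ((den - p) * phi)
      amax <- max(sizes)
      alpha <- clamp(alpha, -1 / (amax - 1) + 1e-6, 1 - 1e-6)
    }
    A <- matrix(0, p, p)
    b <- numeric(p)
    for (ix in idx) {
      ni <- length(ix)
      Xi <- X[ix, , drop = FALSE]
      yi <- y[ix]
      # R^{-1} for exchangeable: (I - a/(1+(ni-1)a) J) / (1-a)
      if (alpha == 0 || ni == 1L) {
        WX <- Xi; Wy <- yi
      } else {
        f <- alpha / (1 + (ni - 1) * alpha)
        WX <- (Xi - f * matrix(colSums(Xi), ni, p, byrow = TRUE)) / (1 - alpha)
        Wy <- (yi - f * sum(yi)) / (1 - alpha)
      }
      A <- A + crossprod(Xi, WX)
      b <- b + crossprod(Xi, Wy)
    }
    beta_new <- solve(A, b)
    if (max(abs(beta_new - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  # Sandwich covariance: bread A^{-1}, meat from per-cluster score outer
  # products; the scale phi cancels between bread and meat.
  e <- as.vector(y - X %*% beta)
  A <- matrix(0, p, p)
  B <- matrix(0, p, p)
  for (ix in idx) {
    ni <- length(ix)
    Xi <- X[ix, , drop = FALSE]
    ei <- e[ix]
    if (alpha == 0 || ni == 1L) {
      WX <- Xi; We <- ei
    } else {
      f <- alpha / (1 + (ni - 1) * alpha)
      WX <- (Xi - f * matrix(colSums(Xi), ni, p, byrow = TRUE)) / (1 - alpha)
      We <- (ei - f * sum(ei)) / (1 - alpha)
    }
    A <- A + crossprod(Xi, WX)
    g <- crossprod(Xi, We)
    B <- B + tcrossprod(g)
  }
  Ainv <- solve(A)
  V <- Ainv %*% B %*% Ainv
  se <- sqrt(diag(V))
  z <- beta / se
  coefs <- data.frame(
    term = colnames(X), estimate = as.vector(beta), robust_se = se,
    z = as.vector(z), p = 2 * stats::pnorm(-abs(z))
  )
  fitted <- as.vector(X %*% beta)
  if (stats::sd(fitted) > 0 && stats::sd(y) > 0) {
    ct <- stats::cor.test(fitted, y)
    r <- unname(ct$estimate); rp <- ct$p.value
  } else {
    r <- NA_real_; rp <- NA_real_
  }
  structure(list(coefficients = coefs, alpha = alpha, phi = phi,
                 fitted = fitted, residuals = e, r = r, p = rp,
                 vcov = V, n_obs = n, n_clusters = length(idx),
                 converged = converged),
            class = "gee_fit")
}

#' Median-split binarization
#'
#' Labels each participant-day 1 when the outcome is strictly higher than
#' the pooled (all participant-days) median, else 0. With a strict "higher
#' than" rule the prevalence of 1 never exceeds one half.
#'
#' @param values Numeric outcome values.
#' @return Integer 0/1 labels.
#' @export
median_binarize <- function(values) {
  v <- values[!is.na(values)]
  if (length(unique(v)) < 2L) stop("degenerate outcome: fewer than 2 distinct values")
  as.integer(values > stats::median(values, na.rm = TRUE))
}

#' Leave-one-subject-out classification of daily labels
#'
#' For each participant: fit a logistic regression on all other
#' participants' days (features standardized with training-fold statistics),
#' predict the held-out participant's days at the 0.5 threshold, and score
#' the accuracy for that individual. A single-class training fold falls back
#' to majority-class prediction with a warning. Reports per-individual
#' accuracies with their mean and SD.
#'
#' @param X Participant-day x feature matrix.
#' @param labels 0/1 labels from [median_binarize()].
#' @param id Participant identifier per row.
#' @return A `loso_classification_report` list: `per_individual` (data
#'   frame: id, n_days, accuracy), `mean_accuracy`, `sd_accuracy`.
#' @export
loso_classify <- function(X, labels, id) {
  X <- as.matrix(X)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  id <- as.character(id)
  ids <- unique(id)
  if (length(ids) < 3L) stop("leave-one-subject-out needs at least 3 participants")
  acc <- numeric(length(ids))
  nd <- integer(length(ids))
  for (k in seq_along(ids)) {
    te <- id == ids[k]
    Ztr <- standardize_columns(X[!te, , drop = FALSE])
    Zte <- standardize_columns(X[te, , drop = FALSE],
                               center = attr(Ztr, "center"),
                               scale = attr(Ztr, "scale"))
    ytr <- labels[!te]
    if (length(unique(ytr)) < 2L) {
      warning("training fold for participant ", ids[k],
              " has a single class; predicting the majority class")
      pred <- rep(as.integer(mean(ytr) >= 0.5), sum(te))
    } else {
      df <- data.frame(y = ytr, Ztr)
      fit <- suppressWarnings(
        stats::glm(y ~ ., data = df, family = stats::binomial())
      )
      eta <- suppressWarnings(
        stats::predict(fit, newdata = as.data.frame(Zte), type = "response")
      )
      pred <- as.integer(eta > 0.5)
    }
    acc[k] <- mean(pred == labels[te])
    nd[k] <- sum(te)
  }
  structure(list(
    per_individual = data.frame(participant_id = ids, n_days = nd,
                                accuracy = acc),
    mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc)
  ), class = "loso_classification_report")
}

#' Run the daily state pipeline over every outcome
#'
#' For each daily outcome column (AM and PM semantic differentials,
#' previous-day differentials, affect scores, and the six active-task
#' metrics): fit the Gaussian exchangeable GEE of the outcome on the 15
#' prior-24-hour features, then median-binarize the outcome and evaluate
#' leave-one-subject-out logistic classification. Outcomes that are entirely
#' missing or degenerate are skipped with a warning. Complete-case per
#' outcome.
#'
#' @param features Data frame with `participant_id` and the 15 daily feature
#'   columns, one row per participant-day, row-aligned with `daily`.
#' @param daily Data frame of daily outcome columns (same row order).
#' @param outcomes Outcome columns to model; defaults to the standard 23.
#' @return Named list of `state_model_report`s: `outcome`, `gee`, `r`, `p`,
#'   `within_group_correlation`, `classification`.
#' @export
run_state_battery <- function(features, daily, outcomes = NULL) {
  outcomes <- outcomes %||% intersect(STATE_OUTCOMES, names(daily))
  fcols <- intersect(feature_names(), names(features))
  stopifnot(nrow(features) == nrow(daily))
  out <- list()
  for (oc in outcomes) {
    y <- daily[[oc]]
    ok <- stats::complete.cases(features[, fcols]) & !is.na(y)
    if (!any(ok)) {
      warning("outcome ", oc, " entirely missing; skipped")
      next
    }
    Xr <- as.matrix(features[ok, fcols])
    idv <- features$participant_id[ok]
    yv <- y[ok]
    if (length(unique(yv)) < 2L) {
      warning("outcome ", oc, " is degenerate; skipped")
      next
    }
    Z <- standardize_columns(Xr)
    gee <- fit_gee(Z, yv, idv)
    labels <- median_binarize(yv)
    cls <- loso_classify(Xr, labels, idv)
    out[[oc]] <- structure(list(
      outcome = oc, gee = gee, r = gee$r, p = gee$p,
      within_group_correlation = gee$alpha, classification = cls
    ), class = "state_model_report")
  }
  out
}
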