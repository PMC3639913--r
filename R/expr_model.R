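# Penalized stepwise linear-model selection with LMG relative-importance
# decomposition; the `expr_model` class and its methods.

#' Screen candidate predictors by marginal Spearman significance
#'
#' Reproduces the variable pre-selection used before stepwise model
#' selection: a feature becomes a candidate when its marginal Spearman
#' correlation with the response is significant. CAI is excluded by
#' default because tAI, the other codon-bias index, is the retained one.
#'
#' @param features Data frame of per-gene features.
#' @param response Numeric response (log mRNA level).
#' @param columns Columns to screen (default: all numeric columns).
#' @param alpha Significance level of the screen (default 0.05, no
#'   multiple-testing correction; set `bonferroni = TRUE` to divide alpha
#'   by the number of screened columns).
#' @param exclude Columns never admitted (default `"cai"` plus the
#'   composite ratio column).
#' @param bonferroni Apply a Bonferroni-corrected threshold.
#' @return Character vector of candidate column names.
#' @export
candidate_features <- function(features, response, columns = NULL,
                               alpha = 0.05, exclude = c("cai",
                                                         "tai_over_logLcds"),
                               bonferroni = FALSE) {
  features <- as.data.frame(features)
  if (is.null(columns)) {
    columns <- names(features)[vapply(features, is.numeric, logical(1))]
  }
  columns <- setdiff(columns, exclude)
  tab <- spearman_table(features, response, columns = columns)
  thr <- if (bonferroni) alpha / nrow(tab) else alpha
  tab$feature[!is.na(tab$p_value) & tab$p_value < thr]
}

#' Canonical candidate set for stepwise selection
#'
#' Builds the default candidate pool used throughout the package: the
#' structural features (log lengths, tAI, dG windows) that pass the
#' marginal Spearman screen of [candidate_features()], plus all 20
#' amino-acid frequency columns. The amino-acid frequencies enter
#' unscreened: their compositional constraint (they sum to 1) dilutes
#' marginal correlations even when conditional effects are real, so the
#' screen is left to the penalized selection itself. CAI is excluded as
#' the redundant codon-bias index.
#'
#' @inheritParams candidate_features
#' @return Character vector of candidate column names.
#' @export
model_candidates <- function(features, response, alpha = 0.05) {
  features <- as.data.frame(features)
  aa_cols <- grep("^aa_", names(features), value = TRUE)
  structural <- setdiff(
    names(features)[vapply(features, is.numeric, logical(1))],
    c(aa_cols, "gc_frac", "gc3_frac")
  )
  screened <- candidate_features(features, response, columns = structural,
                                 alpha = alpha)
  c(screened, aa_cols)
}

# ---- LMG relative importance -------------------------------------------

# R^2 of y on every subset of the columns of X, from moment matrices.
# Returns a numeric vector indexed by bitmask + 1.
subset_r2 <- function(X, y) {
  p <- ncol(X)
  Z <- cbind(X, y)
  Z <- sweep(Z, 2L, colMeans(Z))
  S <- crossprod(Z)
  Sxx <- S[seq_len(p), seq_len(p), drop = FALSE]
  Sxy <- S[seq_len(p), p + 1L]
  Syy <- S[p + 1L, p + 1L]
  r2 <- numeric(2^p)
  for (mask in seq_len(2^p - 1L)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, 0:(p - 1L))) != 0L)
    b <- tryCatch(solve(Sxx[idx, idx, drop = FALSE], Sxy[idx]),
                  error = function(e) NULL)
    r2[mask + 1L] <- if (is.null(b)) NA_real_ else sum(b * Sxy[idx]) / Syy
  }
  r2
}

# exact LMG shares (share of R^2, summing to 1) for p <= max_exact
lmg_exact <- function(X, y) {
  p <- ncol(X)
  r2 <- subset_r2(X, y)
  w <- vapply(0:(p - 1L), function(m) {
    exp(lfactorial(m) + lfactorial(p - m - 1L) - lfactorial(p))
  }, numeric(1))
  shares <- numeric(p)
  bits <- bitwShiftL(1L, 0:(p - 1L))
  masks <- 0:(2^p - 1L)
  sizes <- vapply(masks, function(m) sum(bitwAnd(m, bits) != 0L), numeric(1))
  for (j in seq_len(p)) {
    has_j <- bitwAnd(masks, bits[j]) != 0L
    s_masks <- masks[!has_j]
    inc <- r2[s_masks + bits[j] + 1L] - r2[s_masks + 1L]
    shares[j] <- sum(w[sizes[!has_j] + 1L] * inc)
  }
  total <- r2[2^p]
  if (total <= 0) stop("model has zero R^2; shares undefined", call. = FALSE)
  shares / total
}

# Monte-Carlo LMG over sampled orderings (used when p > max_exact)
lmg_mc <- function(X, y, n_orderings) {
  p <- ncol(X)
  Z <- sweep(cbind(X, y), 2L, colMeans(cbind(X, y)))
  S <- crossprod(Z)
  Syy <- S[p + 1L, p + 1L]
  r2_of <- function(idx) {
    if (!length(idx)) return(0)
    b <- solve(S[idx, idx, drop = FALSE], S[idx, p + 1L])
    sum(b * S[idx, p + 1L]) / Syy
  }
  shares <- numeric(p)
  for (o in seq_len(n_orderings)) {
    ord <- sample.int(p)
    prev <- 0
    for (step_i in seq_len(p)) {
      cur <- r2_of(ord[seq_len(step_i)])
      shares[ord[step_i]] <- shares[ord[step_i]] + (cur - prev)
      prev <- cur
    }
  }
  shares <- shares / n_orderings
  shares / r2_of(seq_len(p))
}

#' LMG contribution decomposition with bootstrap confidence intervals
#'
#' Decomposes a fitted linear model's R-squared into per-predictor shares
#' by averaging each predictor's sequential R-squared increment over all
#' predictor orderings (the LMG relative-importance measure), normalized
#' to sum to 1. With more than `max_exact` predictors, a seeded
#' Monte-Carlo sample of orderings is used (with a warning). Confidence
#' intervals come from a nonparametric case-resampling bootstrap.
#'
#' @param object An `expr_model`, an `lm`, or a numeric predictor matrix
#'   (then `y` must be given).
#' @param y Response vector when `object` is a matrix.
#' @param boot Number of bootstrap resamples for 95% CIs (0 = no CIs).
#' @param seed Seed for the bootstrap (and Monte-Carlo orderings).
#' @param max_exact Largest predictor count decomposed by exact
#'   enumeration (default 12).
#' @param n_orderings Monte-Carlo orderings when `p > max_exact`.
#' @return Data frame `predictor`, `share` and, when `boot > 0`,
#'   `ci_lower`, `ci_upper`; attribute `method = "LMG (assumed)"`.
#' @export
contribution_decomposition <- function(object, y = NULL, boot = 0L,
                                       seed = 1L, max_exact = 12L,
                                       n_orderings = 1000L) {
  if (inherits(object, "expr_model")) object <- object$fit
  if (inherits(object, "lm")) {
    mf <- model.frame(object)
    y <- model.response(mf)
    X <- model.matrix(object)
    X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  } else {
    X <- as.matrix(object)
    if (is.null(y)) stop("y is required when object is a matrix", call. = FALSE)
  }
  p <- ncol(X)
  if (p < 1L) stop("model has no predictors", call. = FALSE)
  exact <- p <= max_exact
  if (!exact) {
    warning("more than ", max_exact,
            " predictors: using Monte-Carlo ordering sample", call. = FALSE)
  }
  one_pass <- function(Xb, yb) {
    if (exact) lmg_exact(Xb, yb) else lmg_mc(Xb, yb, n_orderings)
  }
  shares <- with_seed(seed, one_pass(X, y))
  out <- data.frame(predictor = colnames(X), share = shares,
                    stringsAsFactors = FALSE)
  if (boot > 0L) {
    n <- nrow(X)
    draws <- with_seed(seed, {
      replicate(boot, {
        idx <- sample.int(n, n, replace = TRUE)
        tryCatch(one_pass(X[idx, , drop = FALSE], y[idx]),
                 error = function(e) rep(NA_real_, p))
      })
    })
    draws <- matrix(draws, nrow = p)
    out$ci_lower <- apply(draws, 1L, quantile, probs = 0.025, na.rm = TRUE)
    out$ci_upper <- apply(draws, 1L, quantile, probs = 0.975, na.rm = TRUE)
  }
  attr(out, "method") <- "LMG (assumed)"
  out
}

# ---- stepwise selection -------------------------------------------------

#' Stepwise linear-model selection with contribution decomposition
#'
#' Fits the full candidate model and performs bidirectional stepwise
#' selection minimizing the information criterion
#' `IC = n log(RSS/n) + k p`, with `k = log(n)` by default (the BIC-style
#' reading of a log penalty per parameter; `k = 2` gives AIC). The
#' selected model is returned as an `expr_model` with coefficients, 95%
#' CIs, p-values, LMG contribution shares, and R-squared statistics.
#' Rows with missing values in the response or any candidate are dropped
#' (listwise deletion). A rank-deficient candidate design triggers a
#' warning and the later-entering collinear columns are dropped before
#' selection.
#'
#' @param data Data frame holding the response and candidate columns.
#' @param response Name of the response column (log mRNA level).
#' @param candidates Character vector of candidate predictor columns,
#'   e.g. from [candidate_features()].
#' @param k Penalty per parameter (default `log(n)` after deletion).
#' @param direction Stepwise direction (default `"both"`, starting from
#'   the full candidate model).
#' @param boot Bootstrap resamples for contribution CIs (0 = point shares
#'   only; see [contribution_decomposition()]).
#' @param seed Seed for the contribution bootstrap.
#' @return An `expr_model` object.
#' @examples
#' set.seed(1)
#' d <- data.frame(x1 = rnorm(200), x2 = rnorm(200), x3 = rnorm(200))
#' d$y <- 2 * d$x1 + rnorm(200)
#' fit <- stepwise_select(d, "y", c("x1", "x2", "x3"))
#' fit$selected
#' @export
stepwise_select <- function(data, response, candidates, k = NULL,
                            direction = c("both", "backward", "forward"),
                            boot = 0L, seed = 1L) {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(data), response %in% names(data),
            all(candidates %in% names(data)))
  sub <- data[, c(response, candidates), drop = FALSE]
  sub <- sub[complete.cases(sub), , drop = FALSE]
  n <- nrow(sub)
  p <- length(candidates)
  if (n <= p + 2L) stop("need n > p + 2 complete observations", call. = FALSE)
  if (is.null(k)) k <- log(n)

  dropped <- character(0)
  if (p > 0L) {
    X <- scale(as.matrix(sub[, candidates, drop = FALSE]))
    qx <- qr(X)
    if (qx$rank < p) {
      keep_idx <- sort(qx$pivot[seq_len(qx$rank)])
      dropped <- candidates[-keep_idx]
      warning("collinear candidate design; dropping: ",
              paste(dropped, collapse = ", "), call. = FALSE)
      candidates <- candidates[keep_idx]
    }
  }

  fml <- if (length(candidates)) {
    as.formula(paste(response, "~", paste(candidates, collapse = " + ")))
  } else {
    as.formula(paste(response, "~ 1"))
  }
  start <- if (direction == "forward") {
    lm(as.formula(paste(response, "~ 1")), data = sub)
  } else {
    lm(fml, data = sub)
  }
  fit <- step(start, scope = list(lower = as.formula("~ 1"), upper = fml),
              direction = direction, k = k, trace = 0)

  new_expr_model(fit, candidates = candidates, k = k, dropped = dropped,
                 response = response, boot = boot, seed = seed)
}

#' Single-covariate ratio model: tAI / log(CDS length)
#'
#' Replaces the tAI and log CDS-length covariates by their ratio and fits
#' the response on that single composite covariate (optionally together
#' with further covariates). The ratio captures the concerted variation
#' of codon adaptation and coding-sequence length.
#'
#' @param data Data frame with `tai` and `log_cds_len` columns (names
#'   configurable) and the response.
#' @param response Response column name.
#' @param tai,log_cds Column names of the two components.
#' @param covariates Optional further predictor columns.
#' @return An `expr_model` fitted without selection.
#' @export
ratio_model <- function(data, response, tai = "tai",
                        log_cds = "log_cds_len", covariates = NULL) {
  stopifnot(all(c(response, tai, log_cds) %in% names(data)))
  if (any(data[[log_cds]] <= 0, na.rm = TRUE)) {
    stop("log CDS length must be positive", call. = FALSE)
  }
  sub <- data
  sub$tai_over_logLcds <- sub[[tai]] / sub[[log_cds]]
  preds <- c("tai_over_logLcds", covariates)
  sub <- sub[, c(response, preds), drop = FALSE]
  sub <- sub[complete.cases(sub), , drop = FALSE]
  fml <- as.formula(paste(response, "~", paste(preds, collapse = " + ")))
  fit <- lm(fml, data = sub)
  new_expr_model(fit, candidates = preds, k = NA_real_,
                 dropped = character(0), response = response)
}

# ---- the expr_model class ----------------------------------------------

new_expr_model <- function(fit, candidates, k, dropped, response,
                           boot = 0L, seed = 1L) {
  sm <- summary(fit)
  selected <- setdiff(names(coef(fit)), "(Intercept)")
  contributions <- if (length(selected) >= 1L) {
    contribution_decomposition(fit, boot = boot, seed = seed)
  } else {
    NULL
  }
  fstat <- sm$fstatistic
  model_p <- if (is.null(fstat)) NA_real_ else {
    unname(pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE))
  }
  structure(
    list(fit = fit, response = response, selected = selected,
         candidates = candidates, dropped = dropped, k = k,
         coefficients = coef(fit), conf_int = confint(fit),
         p_values = sm$coefficients[, 4L],
         contributions = contributions,
         r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
         model_p = model_p, n = length(residuals(fit)),
         call = sys.call(-1L)),
    class = "expr_model"
  )
}

#' @export
print.expr_model <- function(x, ...) {
  cat("Stepwise expression model (", x$response, " ~ ",
      if (length(x$selected)) paste(x$selected, collapse = " + ") else "1",
      ")\n", sep = "")
  cat(sprintf("  n = %d, R-squared = %.3f, adjusted R-squared = %.3f\n",
              x$n, x$r_squared, x$adj_r_squared))
  if (!is.na(x$model_p)) cat(sprintf("  model p = %.3g\n", x$model_p))
  invisible(x)
}

#' Summarize an expression model as a coefficient/contribution table
#'
#' @param object An `expr_model`.
#' @param ... Unused.
#' @return Data frame: predictor, coefficient, 95% CI bounds, p-value and
#'   LMG contribution share (with bootstrap CI columns when available).
#' @export
summary.expr_model <- function(object, ...) {
  terms_all <- names(object$coefficients)
  tab <- data.frame(
    predictor = terms_all,
    coefficient = unname(object$coefficients),
    ci_lower = object$conf_int[, 1L],
    ci_upper = object$conf_int[, 2L],
    p_value = unname(object$p_values[terms_all]),
    stringsAsFactors = FALSE
  )
  if (!is.null(object$contributions)) {
    m <- match(tab$predictor, object$contributions$predictor)
    tab$contribution <- object$contributions$share[m]
    if ("ci_lower" %in% names(object$contributions)) {
      tab$contribution_ci_lower <- object$contributions$ci_lower[m]
      tab$contribution_ci_upper <- object$contributions$ci_upper[m]
    }
  }
  rownames(tab) <- NULL
  structure(list(table = tab, r_squared = object$r_squared,
                 adj_r_squared = object$adj_r_squared,
                 model_p = object$model_p, n = object$n,
                 k = object$k),
            class = "summary.expr_model")
}

#' @export
print.summary.expr_model <- function(x, ...) {
  cat(sprintf("n = %d, R-squared = %.3f (adjusted %.3f), model p = %.3g\n",
              x$n, x$r_squared, x$adj_r_squared, x$model_p))
  df <- x$table
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
coef.expr_model <- function(object, ...) object$coefficients

#' @export
predict.expr_model <- function(object, newdata = NULL, ...) {
  if ("tai_over_logLcds" %in% object$selected && !is.null(newdata) &&
      !"tai_over_logLcds" %in% names(newdata) &&
      all(c("tai", "log_cds_len") %in% names(newdata))) {
    newdata$tai_over_logLcds <- newdata$tai / newdata$log_cds_len
  }
  if (is.null(newdata)) predict(object$fit, ...) else
    predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.expr_model <- function(object, ...) residuals(object$fit, ...)

#' @export
fitted.expr_model <- function(object, ...) fitted(object$fit, ...)

#' @export
simulate.expr_model <- function(object, nsim = 1, seed = NULL, ...) {
  simulate(object$fit, nsim = nsim, seed = seed, ...)
}

#' Observed-versus-fitted scatter plot of an expression model
#'
#' @param x An `expr_model`.
#' @param ... Further arguments passed to [graphics::plot()].
#' @export
plot.expr_model <- function(x, ...) {
  obs <- fitted(x$fit) + residuals(x$fit)
  plot(obs, fitted(x$fit),
       xlab = paste("observed", x$response),
       ylab = "fitted value",
       main = sprintf("adj. R-squared = %.2f, n = %d", x$adj_r_squared, x$n),
       ...)
  abline(0, 1, lty = 2)
  invisible(x)
}
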