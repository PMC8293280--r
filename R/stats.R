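# Statistical procedures: log transform / standardization, normality-gated
# correlations with FDR adjustment, exhaustive best-subset regression
# selected by repeated cross-validation with VIF screening, and Fisher
# exact tests on 2x2 count tables.

#' Log-transform and standardize columns
#'
#' Named columns are natural-log transformed (all values must be strictly
#' positive) and/or z-scored (sample SD, n - 1).
#'
#' @param table Data frame.
#' @param log_cols Columns to log transform.
#' @param z_cols Columns to standardize (after any log transform).
#' @return Transformed data frame.
#' @export
log_standardize <- function(table, log_cols = character(0),
                            z_cols = character(0)) {
  for (cl in log_cols) {
    bad <- which(table[[cl]] <= 0 | !is.finite(table[[cl]]))
    if (length(bad)) {
      stop("non-positive value in logged column '", cl, "' at row ", bad[1])
    }
    table[[cl]] <- log(table[[cl]])
  }
  for (cl in z_cols) {
    s <- stats::sd(table[[cl]])
    if (!is.finite(s) || s == 0) {
      stop("zero or undefined SD in column '", cl, "'")
    }
    table[[cl]] <- (table[[cl]] - mean(table[[cl]])) / s
  }
  table
}

#' Normality-gated correlation
#'
#' Fits `y ~ x`, runs a Shapiro-Wilk test on the residuals and reports a
#' Pearson correlation when the residuals are compatible with normality
#' (p >= `sw_threshold`), a Spearman correlation otherwise.
#'
#' @param x,y Numeric vectors, `n >= 5`, finite.
#' @param sw_threshold Shapiro-Wilk p-value threshold (default 0.05).
#' @return List: `method` ("pearson"/"spearman"), `estimate`, `p_value`,
#'   `shapiro_p`, `n`.
#' @export
correlate <- function(x, y, sw_threshold = 0.05) {
  stopifnot(length(x) == length(y), length(x) >= 5,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  res <- stats::resid(stats::lm(y ~ x))
  swp <- if (stats::sd(res) < .Machine$double.eps^0.5 * stats::sd(y) ||
             length(unique(round(res, 12))) < 3) {
    1  # (near-)exact fit: residuals carry no distributional signal
  } else stats::shapiro.test(res)$p.value
  method <- if (swp >= sw_threshold) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(method = method, estimate = unname(ct$estimate),
       p_value = ct$p.value, shapiro_p = swp, n = length(x))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment; monotone and bounded by 1.
#'
#' @param p P-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1 | !is.finite(p))) stop("p values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing predictor j on the others.
#' Perfect collinearity yields `Inf` with a flag.
#'
#' @param design Data frame or matrix of at least 2 predictors.
#' @return Named vector of VIFs (attribute `flagged` lists infinite ones).
#' @export
vif <- function(design) {
  x <- as.matrix(design)
  if (ncol(x) < 2) stop("need at least 2 predictors")
  out <- vapply(seq_len(ncol(x)), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    r2 <- 1 - sum(fit$residuals^2) /
      sum((x[, j] - mean(x[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 1)
  names(out) <- colnames(x)
  if (any(!is.finite(out))) {
    attr(out, "flagged") <- names(out)[!is.finite(out)]
  }
  out
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact p-value as the sum of hypergeometric probabilities of all tables
#' (with the observed margins) no more probable than the observed one.
#'
#' @param t 2x2 matrix of nonnegative integer counts `[[a, b], [c, d]]`
#'   (rows = groups, first column = positives), or a length-4 vector
#'   `c(a, b, c, d)`.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(t) {
  x <- if (is.matrix(t)) t else matrix(t, 2, 2, byrow = TRUE)
  if (any(x < 0) || any(x != round(x))) stop("counts must be nonnegative integers")
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    stop("all margins must be positive")
  }
  a <- x[1, 1]
  m <- sum(x[1, ]); n <- sum(x[2, ]); k <- sum(x[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

subset_fit_stats <- function(y, x) {
  n <- length(y); p <- ncol(x)
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, x), y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  k <- p + 2  # coefficients + intercept + sigma
  list(coef = fit$coefficients, r2 = r2, adj_r2 = adj_r2,
       aic = -2 * ll + 2 * k, bic = -2 * ll + log(n) * k, rss = rss)
}

cv_rmse <- function(y, x, folds, repeats, seed) {
  n <- length(y)
  x1 <- cbind(1, x)
  errs <- numeric(folds * repeats)
  k <- 0L
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      fold_id <- sample(rep(seq_len(folds), length.out = n))
      for (f in seq_len(folds)) {
        test <- fold_id == f
        ft <- stats::.lm.fit(x1[!test, , drop = FALSE], y[!test])
        cf <- numeric(ncol(x1))
        cf[ft$pivot] <- ft$coefficients  # undo QR column pivoting
        cf[is.na(cf)] <- 0
        pred <- x1[test, , drop = FALSE] %*% cf
        k <- k + 1L
        errs[k] <- sqrt(mean((y[test] - pred)^2))
      }
    }
  })
  mean(errs)
}

#' Best-subset regression selected by repeated cross-validation
#'
#' Exhaustive search over predictor subsets of each size; the best subset
#' per size is ranked by adjusted R^2 (AIC and BIC reported alongside).
#' Among the per-size winners, the final model minimizes the mean RMSE of a
#' repeated (default 20 x) 10-fold cross-validation with seeded fold
#' shuffling. The final fit reports coefficients, R^2 and per-variable
#' VIFs, flagged when any VIF reaches `vif_limit`.
#'
#' @param table Data frame of complete cases (transform/standardize first
#'   with [log_standardize()] as the procedure requires).
#' @param response Response column name.
#' @param predictors Candidate predictor column names (distinct).
#' @param sizes Subset sizes to search (default 1 to
#'   `min(5, length(predictors))`).
#' @param folds,repeats Cross-validation plan (defaults 10, 20).
#' @param seed Integer seed for fold shuffling.
#' @param vif_limit Collinearity screen (default 1.5).
#' @return List: `by_size` (per size: subset, adj R^2, AIC, BIC, mean CV
#'   RMSE), `chosen` (predictor names), `fit` (coefficients, r2, vif,
#'   vif_violation), `cv` metadata.
#' @export
best_subset_cv <- function(table, response, predictors,
                           sizes = seq_len(min(5, length(predictors))),
                           folds = 10, repeats = 20, seed = 1,
                           vif_limit = 1.5) {
  stopifnot(!anyDuplicated(predictors), response %in% names(table),
            all(predictors %in% names(table)))
  cc <- stats::complete.cases(table[c(response, predictors)])
  table <- table[cc, ]
  y <- table[[response]]
  n <- length(y)
  if (n < 3 * folds) stop("need n >= 3 * folds complete cases")
  xall <- as.matrix(table[predictors])
  by_size <- list()
  for (s in sizes) {
    combos <- utils::combn(predictors, s, simplify = FALSE)
    best <- NULL
    for (cmb in combos) {
      if (s >= n) next  # p >= n: skipped
      st <- subset_fit_stats(y, xall[, cmb, drop = FALSE])
      if (is.null(best) || st$adj_r2 > best$stats$adj_r2) {
        best <- list(subset = cmb, stats = st)
      }
    }
    if (is.null(best)) next
    best$cv_rmse <- cv_rmse(y, xall[, best$subset, drop = FALSE],
                            folds, repeats, seed)
    by_size[[as.character(s)]] <- best
  }
  if (!length(by_size)) stop("no fittable subset")
  cvs <- vapply(by_size, `[[`, 1, "cv_rmse")
  chosen <- by_size[[which.min(cvs)]]$subset
  xch <- xall[, chosen, drop = FALSE]
  st <- subset_fit_stats(y, xch)
  vifs <- if (length(chosen) >= 2) vif(xch) else
    stats::setNames(rep(1, length(chosen)), chosen)
  list(
    by_size = do.call(rbind, lapply(names(by_size), function(s) {
      b <- by_size[[s]]
      data.frame(size = as.integer(s),
                 subset = paste(b$subset, collapse = "+"),
                 adj_r2 = b$stats$adj_r2, aic = b$stats$aic,
                 bic = b$stats$bic, cv_rmse = b$cv_rmse)
    })),
    chosen = chosen,
    fit = list(coefficients = st$coef[-1], intercept = st$coef[1],
               r2 = st$r2, vif = vifs,
               vif_violation = any(vifs >= vif_limit)),
    cv = list(folds = folds, repeats = repeats, seed = seed)
  )
}

#' Full-model standardized sensitivity regression
#'
#' Multiple linear regression of a response on all supplied predictors
#' after z-scoring both, so coefficients are standardized sensitivities.
#' Used for the model database (predictors g_A, g_H, v50, tau against
#' log ISI or log rebound delay) and for synthetic per-neuron data.
#'
#' @param table Data frame.
#' @param response Response column name.
#' @param predictors Predictor column names.
#' @param log_response Natural-log the response before standardizing.
#' @return List: `coefficients` (standardized), `r2`, `vif`, `n`.
#' @export
sensitivity_regression <- function(table, response, predictors,
                                   log_response = FALSE) {
  cc <- stats::complete.cases(table[c(response, predictors)])
  table <- table[cc, ]
  y <- table[[response]]
  if (log_response) {
    if (any(y <= 0)) stop("non-positive response cannot be logged")
    y <- log(y)
  }
  y <- (y - mean(y)) / stats::sd(y)
  x <- scale(as.matrix(table[predictors]))
  st <- subset_fit_stats(y, x)
  vifs <- if (length(predictors) >= 2) vif(x) else
    stats::setNames(1, predictors)
  list(coefficients = st$coef[-1], r2 = st$r2, vif = vifs, n = length(y))
}
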