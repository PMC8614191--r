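# Stepwise-AIC multiple linear regression of the fitted thermal parameters
# on the 15 standardized environmental predictors, per spatial scale.

#' Canonical predictor order of the analysis table
#'
#' @return Character vector of the 15 predictor symbols.
#' @export
predictor_order <- function() {
  c("SHADE", "SINUO", "AGRI", "ARTI", "BROAD", "HERBA", "FORESTS",
    "NEEDLE", "OTHER", "WATER", "AREA", "SLOP", "LEVEL", "ELEV", "BFI")
}

#' Standardize columns to zero mean and unit variance
#'
#' @param table Data frame; all columns in `cols` must be numeric and
#'   non-constant.
#' @param cols Columns to standardize (default: all numeric columns).
#' @return The table with the selected columns z-scored (sample sd).
#' @export
standardize <- function(table, cols = NULL) {
  if (is.null(cols)) cols <- names(table)[vapply(table, is.numeric, TRUE)]
  if (nrow(table) < 3) stopf("standardize: need at least 3 rows")
  for (cl in cols) {
    v <- table[[cl]]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) stopf("standardize: column '%s' is constant", cl)
    table[[cl]] <- (v - mean(v)) / s
  }
  table
}

# Gaussian AIC of an lm (full likelihood, k = 2): matches stats::AIC.
# The residual sum of squares is floored at a sliver of the total sum of
# squares so that exact fits (RSS at floating-point zero) compare by the
# parameter penalty instead of by the noise in log(RSS).
gaussian_aic <- function(fit) {
  n <- length(stats::residuals(fit))
  rss <- sum(stats::residuals(fit)^2)
  y <- stats::fitted(fit) + stats::residuals(fit)
  tss <- sum((y - mean(y))^2)
  rss <- max(rss, 1e-12 * max(tss, .Machine$double.xmin))
  p <- length(stats::coef(fit))
  n * log(2 * pi * rss / n) + n + 2 * (p + 1)
}

#' Ordinary least squares with the report statistics
#'
#' @param response Response column name.
#' @param predictors Character vector of predictor names (possibly empty:
#'   intercept-only model).
#' @param data Data frame.
#' @return List with the `lm` fit, `estimates`, `p_values`, `adj_r2`
#'   (fraction), `aic`.
#' @export
ols_fit <- function(response, predictors, data) {
  n <- nrow(data)
  if (n <= length(predictors) + 1)
    stopf("ols_fit: n = %d rows cannot support %d predictors", n, length(predictors))
  rhs <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
  fml <- stats::as.formula(paste(response, "~", rhs))
  fit <- stats::lm(fml, data = data)
  if (any(is.na(stats::coef(fit)))) stopf("ols_fit: singular design")
  sm <- suppressWarnings(summary(fit))
  est <- stats::coef(fit)[-1]
  pv <- if (length(predictors)) sm$coefficients[-1, 4] else numeric(0)
  list(fit = fit, estimates = est, p_values = pv,
       adj_r2 = sm$adj.r.squared, aic = gaussian_aic(fit))
}

#' Significance star code for a p-value
#'
#' `"***"` for p <= 0.001, `"**"` for p <= 0.01, `"*"` for p <= 0.05,
#' `"#"` for p <= 0.1, otherwise the empty string.
#'
#' @param p_value Numeric vector in `[0, 1]`.
#' @return Character vector of codes.
#' @export
star_code <- function(p_value) {
  if (any(!is.finite(p_value)) || any(p_value < 0 | p_value > 1))
    stopf("star_code: p-values must lie in [0, 1]")
  vapply(p_value, function(p) {
    if (p <= 0.001) "***" else if (p <= 0.01) "**" else if (p <= 0.05) "*"
    else if (p <= 0.1) "#" else ""
  }, "")
}

#' Bidirectional stepwise-AIC selection
#'
#' Starts from the full model over `predictors` and repeatedly applies the
#' single add-or-drop move with the lowest Gaussian AIC (k = 2), stopping
#' when no move lowers the AIC.  Ties are broken in favour of the earliest
#' move in the fixed predictor order (drops before adds).  The endpoint is
#' refitted by OLS.
#'
#' @param response Response column name.
#' @param predictors Candidate predictors (default [predictor_order()]
#'   intersected with `data`).
#' @param data Data frame (standardized predictors).
#' @param scale_name Optional label stored in the report.
#' @return An object of class `stepwise_report`: `response`, `scale`,
#'   `selected`, `estimates`, `p_values`, `stars`, `adj_r2_pct`, `aic`,
#'   `trace` (data frame of moves, AIC non-increasing), `n`.
#' @export
stepwise_aic <- function(response, predictors = NULL, data, scale_name = NA_character_) {
  if (is.null(predictors)) predictors <- intersect(predictor_order(), names(data))
  if (!length(predictors)) stopf("stepwise_aic: no candidate predictors")
  current <- predictors
  # exact linear dependence (e.g. cover percentages summing to 100) makes
  # the literal full model singular; start from the maximal non-aliased
  # subset instead, dropping aliased predictors from the end of the fixed
  # order, as a rank-reduced full fit would
  X <- as.matrix(cbind(1, data[, current, drop = FALSE]))
  qrX <- qr(X)
  start_note <- "start (full model)"
  if (qrX$rank < ncol(X)) {
    keep_idx <- sort(qrX$pivot[seq_len(qrX$rank)])
    keep_idx <- setdiff(keep_idx, 1L) - 1L   # drop the intercept column index
    current <- current[keep_idx]
    start_note <- sprintf("start (full model; aliased: %s)",
                          paste(setdiff(predictors, current), collapse = ", "))
  }
  cur <- ols_fit(response, current, data)
  trace <- data.frame(move = start_note, aic = cur$aic,
                      stringsAsFactors = FALSE)
  repeat {
    candidates <- list()
    for (p in predictors) {        # fixed order: drop then add per predictor
      if (p %in% current) {
        candidates[[paste0("- ", p)]] <- setdiff(current, p)
      } else {
        candidates[[paste0("+ ", p)]] <- c(current, p)
      }
    }
    aics <- vapply(candidates, function(set) {
      tryCatch(ols_fit(response, set, data)$aic, error = function(e) Inf)
    }, 0)
    best <- which.min(aics)      # first minimum = earliest in fixed order
    if (!length(best) || aics[best] >= cur$aic - 1e-10) break
    current <- candidates[[best]]
    cur <- ols_fit(response, current, data)
    trace <- rbind(trace, data.frame(move = names(candidates)[best], aic = cur$aic))
  }
  selected <- predictors[predictors %in% current]   # canonical order
  final <- ols_fit(response, selected, data)
  structure(list(
    response = response, scale = scale_name,
    selected = selected,
    estimates = final$estimates,
    p_values = final$p_values,
    stars = if (length(selected)) star_code(final$p_values) else character(0),
    adj_r2_pct = 100 * final$adj_r2,
    aic = final$aic,
    trace = trace,
    n = nrow(data),
    fit = final$fit
  ), class = "stepwise_report")
}

#' @export
print.stepwise_report <- function(x, ...) {
  cat(sprintf("Stepwise-AIC MLR: %s ~ . (scale %s, n = %d)\n",
              x$response, x$scale %||% "?", x$n))
  if (!length(x$selected)) {
    cat("  no predictor retained\n")
  } else {
    for (i in seq_along(x$selected)) {
      cat(sprintf("  %-8s %8.3f%-3s  (p = %.3g)\n", x$selected[i],
                  x$estimates[[i]], x$stars[i], x$p_values[[i]]))
    }
  }
  cat(sprintf("  Adj. R2 = %.1f%%, AIC = %.2f, %d step(s)\n",
              x$adj_r2_pct, x$aic, nrow(x$trace) - 1))
  invisible(x)
}

#' Build the scale-by-response coefficient matrix
#'
#' Assembles the stepwise reports of every (response, scale) model into the
#' standard presentation: one row per scale within each response block,
#' columns the 15 predictors (estimate and star where selected, blank
#' otherwise) plus the adjusted R-squared in percent.  p-values are not
#' multiplicity-adjusted.
#'
#' @param reports List of `stepwise_report` objects.
#' @return Data frame with columns `response`, `scale`, one per predictor,
#'   and `Adj_R2_pct`.
#' @export
build_report <- function(reports) {
  rows <- lapply(reports, function(r) {
    row <- as.list(setNames(rep("", length(predictor_order())), predictor_order()))
    for (i in seq_along(r$selected)) {
      row[[r$selected[i]]] <- sprintf("%.3g%s", r$estimates[[i]], r$stars[i])
    }
    c(list(response = r$response, scale = r$scale), row,
      list(Adj_R2_pct = round(r$adj_r2_pct, 1)))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  df
}
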