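# Agreement between clinician ratings and objective scores: contingency
# table, concordance, Cohen's weighted kappa with large-sample CI, RMSE and
# MAE, and orthogonal-polynomial trend regression of (log) measures on
# scores.

#' Contingency table of clinician versus objective scores
#'
#' 5 x 5 table of paired 0-4 ratings: rows are clinician scores, columns
#' objective (accelerometry) scores. Pairs with a missing value on either
#' side are dropped, with a message reporting the count.
#'
#' @param clinician,objective Integer vectors of scores 0-4, equal length.
#' @return A 5 x 5 integer matrix of class `contingency_table` with the
#'   total attached as attribute `n`.
#' @export
build_contingency <- function(clinician, objective) {
  if (length(clinician) != length(objective)) {
    stop("score vectors must have equal length", call. = FALSE)
  }
  if (length(clinician) < 1) stop("need at least one pair", call. = FALSE)
  keep <- !(is.na(clinician) | is.na(objective))
  if (any(!keep)) {
    message(sum(!keep), " pair(s) dropped for missing scores")
    clinician <- clinician[keep]
    objective <- objective[keep]
  }
  if (!all(clinician %in% 0:4) || !all(objective %in% 0:4)) {
    stop("scores must be integers in 0..4", call. = FALSE)
  }
  tab <- table(factor(clinician, levels = 0:4),
               factor(objective, levels = 0:4))
  m <- matrix(as.integer(tab), 5, 5,
              dimnames = list(clinician = 0:4, objective = 0:4))
  structure(m, class = c("contingency_table", "matrix"), n = sum(m))
}

#' Concordance of a contingency table
#'
#' Percentage of exactly matching ratings: `100 * trace / n`.
#'
#' @param table A `contingency_table` (or any square count matrix).
#' @return Concordance in percent.
#' @export
concordance <- function(table) {
  n <- sum(table)
  if (n < 1) stop("empty contingency table", call. = FALSE)
  100 * sum(diag(as.matrix(table))) / n
}

#' Cohen's weighted kappa with large-sample confidence interval
#'
#' Chance-corrected agreement for ordinal ratings. With disagreement
#' weights `d_ij = |i - j|` (linear, default) or `(i - j)^2` (quadratic),
#' kappa is `1 - sum(d * p_obs) / sum(d * p_exp)`, where expected cell
#' probabilities are the marginal products. The 95% CI uses the
#' Fleiss-Cohen-Everitt large-sample standard error of weighted kappa.
#'
#' @param table A `contingency_table` or square count matrix.
#' @param weighting `"linear"` or `"quadratic"`.
#' @param conf_level Confidence level (default 0.95).
#' @return A list of class `kappa_result`: `kappa`, `se`, `ci` (length-2),
#'   `weighting`, `n`.
#' @export
weighted_kappa <- function(table, weighting = c("linear", "quadratic"),
                           conf_level = 0.95) {
  weighting <- match.arg(weighting)
  m <- as.matrix(table)
  k <- nrow(m)
  if (k != ncol(m)) stop("table must be square", call. = FALSE)
  n <- sum(m)
  if (n < 2) stop("need at least 2 rated pairs", call. = FALSE)
  p <- m / n
  pr <- rowSums(p)
  pc <- colSums(p)
  idx <- seq_len(k) - 1
  dmat <- abs(outer(idx, idx, "-"))
  if (weighting == "quadratic") dmat <- dmat^2
  # agreement weights, 1 on the diagonal
  w <- 1 - dmat / max(dmat)
  pe <- sum(w * outer(pr, pc))
  if (1 - pe < .Machine$double.eps) {
    stop("degenerate marginals: chance agreement is 1, kappa undefined",
         call. = FALSE)
  }
  po <- sum(w * p)
  kap <- (po - pe) / (1 - pe)
  # Fleiss-Cohen-Everitt (1969) large-sample variance of weighted kappa
  wbar_r <- as.vector(w %*% pc)   # row-wise expected weight
  wbar_c <- as.vector(pr %*% w)   # column-wise expected weight
  term <- (w * (1 - pe) -
             outer(wbar_r, wbar_c, "+") * (1 - po))^2
  var_k <- (sum(p * term) - (po * pe - 2 * pe + po)^2) /
    (n * (1 - pe)^4)
  se <- sqrt(max(var_k, 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(kappa = kap, se = se,
                 ci = c(kap - z * se, kap + z * se),
                 weighting = weighting, n = n),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("<kappa_result> kappa = %.3f (%s weights), 95%% CI %.3f..%.3f, n = %d\n",
              x$kappa, x$weighting, x$ci[1], x$ci[2], x$n))
  invisible(x)
}

#' RMSE and MAE between two rating sequences
#'
#' How far the objective scores deviate from the clinician ratings, in
#' score points. Missing pairs are dropped pairwise.
#'
#' @param clinician,objective Numeric vectors, equal length.
#' @return Named list with `rmse` and `mae`.
#' @export
error_metrics <- function(clinician, objective) {
  if (length(clinician) != length(objective)) {
    stop("score vectors must have equal length", call. = FALSE)
  }
  keep <- !(is.na(clinician) | is.na(objective))
  d <- clinician[keep] - objective[keep]
  if (length(d) < 1) stop("no complete pairs", call. = FALSE)
  list(rmse = sqrt(mean(d^2)), mae = mean(abs(d)))
}

#' Full agreement report for one test item
#'
#' Bundles the contingency table, concordance, weighted kappa with CI, and
#' RMSE/MAE for a pair of rating sequences.
#'
#' @param clinician,objective Integer score vectors 0-4.
#' @param weighting Kappa weighting, `"linear"` or `"quadratic"`.
#' @return A list of class `agreement_report`.
#' @export
agreement_report <- function(clinician, objective,
                             weighting = c("linear", "quadratic")) {
  weighting <- match.arg(weighting)
  tab <- build_contingency(clinician, objective)
  kap <- weighted_kappa(tab, weighting)
  err <- error_metrics(clinician, objective)
  structure(list(
    table = tab,
    concordance_pct = concordance(tab),
    kappa = kap$kappa, kappa_ci_95 = kap$ci, kappa_se = kap$se,
    rmse = err$rmse, mae = err$mae,
    weighting = weighting, n = attr(tab, "n")
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d\n", x$n))
  cat(sprintf("  concordance %.1f%% | kappa %.3f (%s) CI %.3f..%.3f\n",
              x$concordance_pct, x$kappa, x$weighting,
              x$kappa_ci_95[1], x$kappa_ci_95[2]))
  cat(sprintf("  RMSE %.3f | MAE %.3f score points\n", x$rmse, x$mae))
  invisible(x)
}

#' Linear-trend regression of a measure on ordinal scores
#'
#' Regresses a quantitative measure (log10-transformed unless
#' `log_transform = FALSE`; the time-fraction measure contains zeros and is
#' analyzed untransformed) on the score treated as an ordered factor coded
#' with orthogonal polynomial contrasts built on the observed levels. The
#' first contrast is the linear trend; its coefficient, 95% CI and p-value
#' are reported together with the overall correlation R and R^2.
#'
#' @param scores Integer scores 0-4.
#' @param measure Numeric measure, strictly positive if log-transformed.
#' @param log_transform Apply log10 to the measure first?
#' @return A list of class `trend_fit`: `r`, `r_squared`,
#'   `linear_contrast_coefficient`, `ci_95`, `p_value`, `outcome_name`,
#'   `n`, and the underlying `lm` fit.
#' @export
trend_regression <- function(scores, measure, log_transform = TRUE) {
  keep <- !(is.na(scores) | is.na(measure))
  scores <- scores[keep]
  measure <- measure[keep]
  if (!all(scores %in% 0:4)) stop("scores must be in 0..4", call. = FALSE)
  lv <- sort(unique(scores))
  if (length(lv) < 2) {
    stop("need at least 2 distinct score levels for a trend contrast",
         call. = FALSE)
  }
  if (log_transform) {
    if (any(measure <= 0)) {
      stop("measure must be strictly positive for the log10 transform",
           call. = FALSE)
    }
    y <- log10(measure)
    outcome <- "log10(measure)"
  } else {
    y <- measure
    outcome <- "measure"
  }
  f <- factor(scores, levels = lv)
  # orthonormal polynomial contrasts on the observed (possibly gappy) levels
  stats::contrasts(f) <- stats::contr.poly(length(lv), scores = lv)
  fit <- stats::lm(y ~ f)
  sm <- summary(fit)
  co <- sm$coefficients
  ci <- stats::confint(fit)[2, ]
  structure(list(
    r = sqrt(sm$r.squared),
    r_squared = sm$r.squared,
    linear_contrast_coefficient = unname(co[2, 1]),
    ci_95 = unname(ci),
    p_value = unname(co[2, 4]),
    outcome_name = outcome,
    n = length(y),
    fit = fit
  ), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> %s on score (n = %d)\n", x$outcome_name, x$n))
  cat(sprintf("  R = %.3f, R^2 = %.3f\n", x$r, x$r_squared))
  cat(sprintf("  linear contrast %.3f (95%% CI %.3f..%.3f), p = %.3g\n",
              x$linear_contrast_coefficient, x$ci_95[1], x$ci_95[2],
              x$p_value))
  invisible(x)
}
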