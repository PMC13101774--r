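# Group-level and brain-behavior statistics: Kruskal-Wallis omnibus,
# Dunn's post-hoc z tests with Benjamini-Hochberg correction, Cohen's d,
# Spearman rank correlation, and mode-wise linear models of clinical
# scores on modal weights. The pipeline is deliberately nonparametric for
# the AI group comparisons; Shapiro-Wilk / Levene checks are advisory.

#' Kruskal-Wallis omnibus test
#'
#' Tie-corrected rank-based H with a chi-square reference on
#' `(groups - 1)` degrees of freedom. All-identical data return H = 0,
#' p = 1 rather than NaN.
#'
#' @param values numeric vector.
#' @param groups group labels, same length.
#' @return list with `statistic` (H), `p_value`, `df`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need >= 2 non-empty groups")
  if (length(unique(values)) == 1L)
    return(list(statistic = 0, p_value = 1,
                df = nlevels(droplevels(groups)) - 1L))
  kt <- stats::kruskal.test(values, droplevels(groups))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

#' Dunn's post-hoc pairwise tests with BH correction
#'
#' Pairwise z statistics from the pooled-ranking of all groups with tie
#' correction: `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i +
#' 1/n_j))`, `T = sum(t^3 - t) / (12 (N - 1))`. Two-sided normal p-values
#' are Benjamini-Hochberg adjusted across all pairs; Cohen's d is reported
#' per pair as a descriptive effect size.
#'
#' @inheritParams kruskal_wallis
#' @return data.frame: `group1`, `group2`, `z`, `p`, `p_adj`, `cohens_d`.
#' @export
dunn_posthoc_bh <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  lev <- levels(groups)
  if (any(table(groups) == 0)) stop("empty group")
  if (length(lev) < 2) stop("need >= 2 groups")
  n_tot <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  rbar <- tapply(r, groups, mean)
  n <- tabulate(groups)
  pairs <- utils::combn(seq_along(lev), 2)
  rows <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt((n_tot * (n_tot + 1) / 12 - tie_corr) * (1 / n[i] + 1 / n[j]))
    z <- (rbar[i] - rbar[j]) / se
    d <- tryCatch(cohens_d(values[groups == lev[i]], values[groups == lev[j]]),
                  error = function(e) NA_real_)
    data.frame(group1 = lev[i], group2 = lev[j], z = unname(z),
               p = 2 * stats::pnorm(-abs(z)), cohens_d = d)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out[, c("group1", "group2", "z", "p", "p_adj", "cohens_d")]
}

#' Cohen's d with pooled standard deviation
#'
#' @param a,b numeric samples (each >= 2 values).
#' @return `(mean(a) - mean(b)) / s_pooled` with `n - 1` variances.
#' @export
cohens_d <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs >= 2 values")
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 < .Machine$double.eps) stop("undefined effect size: zero pooled sd")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of tie-averaged ranks; two-sided p from
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df. Incomplete pairs
#' are dropped with a logged count.
#'
#' @param x,y paired numeric vectors.
#' @return list with `rho`, `p_value`, `n_used`, `n_dropped`.
#' @export
spearman_correlation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) message(n_dropped, " incomplete pair(s) dropped")
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need >= 3 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("undefined correlation: constant vector")
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p_value = p, n_used = n, n_dropped = n_dropped)
}

#' Mode-wise linear model of a clinical outcome on modal weights
#'
#' Ordinary least-squares multiple regression with intercept; reports per
#' predictor the coefficient, t value and two-sided p on `n - p - 1` df.
#' Incomplete cases are dropped; near-collinear predictor matrices are
#' rejected with the offending columns named.
#'
#' @param outcome numeric response (clinical score).
#' @param predictors numeric matrix or data.frame of modal weights, one
#'   column per mode (column names kept in the report).
#' @param condition_max condition-number threshold for the collinearity
#'   check on the scaled predictor matrix.
#' @return data.frame: `term`, `estimate`, `t`, `p`; attributes
#'   `n_used`, `sigma`, `r_squared`.
#' @export
modewise_glm <- function(outcome, predictors, condition_max = 1e8) {
  predictors <- as.data.frame(predictors)
  if (is.null(names(predictors)) || any(!nzchar(names(predictors))))
    names(predictors) <- paste0("mode_", seq_along(predictors))
  ok <- stats::complete.cases(outcome, predictors)
  y <- outcome[ok]
  xd <- predictors[ok, , drop = FALSE]
  p <- ncol(xd)
  if (length(y) < p + 2)
    stop("need >= ", p + 2, " complete cases for ", p, " predictors")
  xs <- scale(as.matrix(xd))
  if (any(!is.finite(xs))) {
    bad <- names(xd)[apply(as.matrix(xd), 2, function(c) stats::sd(c) == 0)]
    stop("constant predictor column(s): ", paste(bad, collapse = ", "))
  }
  kap <- kappa(xs, exact = TRUE)
  if (kap > condition_max) {
    cc <- abs(stats::cor(as.matrix(xd)))
    diag(cc) <- 0
    worst <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    stop("collinear predictors (condition number ", format(kap, digits = 4),
         "): ", names(xd)[worst[1]], ", ", names(xd)[worst[2]])
  }
  fit <- stats::lm(y ~ ., data = cbind(y = y, xd))
  sm <- summary(fit)
  co <- sm$coefficients
  out <- data.frame(term = rownames(co), estimate = co[, 1],
                    t = co[, 3], p = co[, 4])
  rownames(out) <- NULL
  attr(out, "n_used") <- length(y)
  attr(out, "sigma") <- sm$sigma
  attr(out, "r_squared") <- sm$r.squared
  out
}

#' Advisory distributional diagnostics
#'
#' Shapiro-Wilk normality per group and a Brown-Forsythe (median-centered
#' Levene) variance-homogeneity test. Purely informational: downstream
#' group comparisons stay nonparametric regardless.
#'
#' @inheritParams kruskal_wallis
#' @return list with `shapiro` (data.frame group/W/p) and `levene`
#'   (list F/p).
#' @export
distribution_diagnostics <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  sh <- do.call(rbind, lapply(levels(groups), function(g) {
    v <- values[groups == g]
    if (length(v) < 3 || length(unique(v)) == 1)
      return(data.frame(group = g, W = NA_real_, p = NA_real_))
    s <- stats::shapiro.test(v)
    data.frame(group = g, W = unname(s$statistic), p = s$p.value)
  }))
  med <- tapply(values, groups, stats::median)
  z <- abs(values - med[groups])
  a <- stats::anova(stats::lm(z ~ groups))
  list(shapiro = sh, levene = list(F = a$`F value`[1], p = a$`Pr(>F)`[1]))
}
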