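#' Group comparison with automatic test dispatch
#'
#' Categorical variables are compared by the chi-square test (no continuity
#' correction by default). Continuous variables between two groups: each
#' group is tested for normality (Shapiro-Wilk at `alpha`); when both pass,
#' homogeneity of variances (Levene, median-centered) picks Student's t
#' versus Welch's t; otherwise the Mann-Whitney U test is used. Groups too
#' small for a normality test (n < 3) fall back to Mann-Whitney with a
#' warning. Group summaries follow the reporting convention mean (SD) for
#' normal variables and median [IQR] otherwise.
#'
#' @param values Variable values (factor/character for categorical, numeric
#'   for continuous).
#' @param group_labels Two-level grouping vector.
#' @param variable_kind `"continuous"` or `"categorical"`.
#' @param alpha Significance level for the normality and homogeneity checks.
#' @param correct Continuity correction for the chi-square test.
#' @return Object of class `group_comparison`: `test_name` (one of `chi2`,
#'   `t`, `welch_t`, `mann_whitney`), `statistic`, `p`, `group_summaries`.
#' @export
compare_groups <- function(values, group_labels,
                           variable_kind = c("continuous", "categorical"),
                           alpha = 0.05, correct = FALSE) {
  variable_kind <- match.arg(variable_kind)
  g <- factor(group_labels)
  if (variable_kind == "categorical") {
    tab <- table(values, g)
    ht <- suppressWarnings(chisq.test(tab, correct = correct))
    summ <- lapply(levels(g), function(lv) table(values[g == lv]))
    names(summ) <- levels(g)
    return(structure(list(test_name = "chi2",
                          statistic = unname(ht$statistic),
                          p = ht$p.value, group_summaries = summ),
                     class = "group_comparison"))
  }
  if (nlevels(g) != 2) stop("continuous comparison requires exactly 2 groups")
  values <- as.numeric(values)
  split_v <- split(values, g)
  too_small <- any(vapply(split_v, length, integer(1)) < 3)
  if (too_small) {
    warning("a group has n < 3; falling back to Mann-Whitney")
    normal <- FALSE
  } else {
    sw_p <- vapply(split_v, function(v) shapiro.test(v)$p.value, numeric(1))
    normal <- all(sw_p > alpha)
  }
  if (normal) {
    lev <- car::leveneTest(values ~ g, center = median)
    equal_var <- lev[1, "Pr(>F)"] > alpha
    ht <- t.test(split_v[[1]], split_v[[2]], var.equal = equal_var)
    test_name <- if (equal_var) "t" else "welch_t"
    summ <- lapply(split_v, function(v) {
      c(mean = mean(v), sd = sd(v), n = length(v))
    })
  } else {
    ht <- suppressWarnings(wilcox.test(split_v[[1]], split_v[[2]],
                                       exact = FALSE))
    test_name <- "mann_whitney"
    summ <- lapply(split_v, function(v) {
      c(median = median(v), iqr = unname(diff(quantile(v, c(0.25, 0.75)))),
        n = length(v))
    })
  }
  structure(list(test_name = test_name, statistic = unname(ht$statistic),
                 p = ht$p.value, group_summaries = summ),
            class = "group_comparison")
}

# Pearson correlation of two vectors with a two-sided t-approximation
# p-value on df degrees of freedom.
cor_t_test <- function(a, b, df) {
  r <- cor(a, b)
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * pt(-abs(tstat), df = df))
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties and a two-sided p-value from
#' the t approximation on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors (n >= 3).
#' @return Object of class `association_result`: `r`, `p`, `n`, `method`,
#'   `covariates`.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete observations")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input")
  res <- cor_t_test(rank(x), rank(y), df = n - 2)
  structure(list(r = res$r, p = res$p, n = n, method = "spearman",
                 covariates = character(0)),
            class = "association_result")
}

#' Covariate-adjusted (partial) Spearman correlation
#'
#' Rank-transforms `x`, `y` and every covariate, residualizes the ranked `x`
#' and `y` on the ranked covariates by least squares (with intercept), and
#' correlates the residuals; the p-value uses n - 2 - k degrees of freedom
#' for k covariates. With no covariates this reduces exactly to [spearman()].
#'
#' @param x,y Numeric vectors.
#' @param covariates Matrix or data.frame of numeric covariates (or `NULL`).
#' @return An `association_result` with `method = "partial_spearman"`.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0 ||
      (is.data.frame(covariates) && ncol(covariates) == 0)) {
    out <- spearman(x, y)
    out$method <- "partial_spearman"
    return(out)
  }
  Z <- as.matrix(covariates)
  stopifnot(length(x) == length(y), nrow(Z) == length(x))
  ok <- complete.cases(x, y, Z)
  x <- x[ok]; y <- y[ok]; Z <- Z[ok, , drop = FALSE]
  n <- length(x)
  k <- ncol(Z)
  if (n <= k + 3) stop("need n > #covariates + 3")
  Zr <- apply(Z, 2, rank)
  D <- cbind(1, Zr)
  qrd <- qr(D)
  if (qrd$rank < ncol(D)) {
    bad <- (colnames(Z) %||% paste0("cov", seq_len(k)))[qrd$rank]
    stop("collinear covariates (near '", bad, "')")
  }
  rx <- qr.resid(qrd, rank(x))
  ry <- qr.resid(qrd, rank(y))
  res <- cor_t_test(rx, ry, df = n - 2 - k)
  structure(list(r = res$r, p = res$p, n = n, method = "partial_spearman",
                 covariates = colnames(Z) %||% paste0("cov", seq_len(k))),
            class = "association_result")
}

#' Multiple linear regression coefficients
#'
#' Ordinary least squares of `y` on a named design; optionally with `y` and
#' all numeric predictors z-scored first so the coefficients are
#' standardized betas.
#'
#' @param y Response vector.
#' @param design data.frame of predictors (full rank required).
#' @param standardize Report standardized betas.
#' @return data.frame with one row per coefficient: `term`, `beta`, `se`,
#'   `p`, `n`, `method`.
#' @export
linear_model <- function(y, design, standardize = FALSE) {
  stopifnot(is.data.frame(design), nrow(design) == length(y))
  dat <- design
  yy <- y
  if (standardize) {
    yy <- (y - mean(y)) / sd(y)
    num <- vapply(dat, is.numeric, logical(1))
    dat[num] <- lapply(dat[num], function(v) (v - mean(v)) / sd(v))
  }
  if (ncol(dat) == 0) {
    fit <- lm(yy ~ 1)
  } else {
    mm <- stats::model.matrix(~ ., data = dat)
    if (qr(mm)$rank < ncol(mm)) stop("rank-deficient design matrix")
    fit <- lm(yy ~ ., data = dat)
  }
  sm <- summary(fit)$coefficients
  data.frame(term = rownames(sm), beta = sm[, "Estimate"],
             se = sm[, "Std. Error"], p = sm[, "Pr(>|t|)"],
             n = length(y), method = "ols_beta",
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment `q_(i) = min_{j >= i} m p_(j) / j`, mapped back to the
#' input order and capped at 1.
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}
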