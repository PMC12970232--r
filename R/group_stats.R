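# Group comparison framework: assumption-driven test selection
# (Shapiro-Wilk normality, Brown-Forsythe/Levene homoscedasticity ->
# Student's t, Welch's t, or Mann-Whitney U), Benjamini-Hochberg FDR
# across the six metrics, and Cliff's delta effect sizes.

#' Brown-Forsythe (median-centred Levene) test for equal variances
#'
#' One-way ANOVA F on absolute deviations from the group medians.
#'
#' @param x,y numeric samples.
#' @return list with `statistic` and `p.value`.
#' @export
levene_bf <- function(x, y) {
  zx <- abs(x - stats::median(x))
  zy <- abs(y - stats::median(y))
  nx <- length(zx); ny <- length(zy)
  zbar <- mean(c(zx, zy))
  ssb <- nx * (mean(zx) - zbar)^2 + ny * (mean(zy) - zbar)^2
  ssw <- sum((zx - mean(zx))^2) + sum((zy - mean(zy))^2)
  df2 <- nx + ny - 2
  f <- (ssb / 1) / (ssw / df2)
  list(statistic = f, p.value = stats::pf(f, 1, df2, lower.tail = FALSE))
}

#' Assumption-driven two-sample test selection
#'
#' Both groups normal by Shapiro-Wilk (p > alpha) and homoscedastic by the
#' Brown-Forsythe Levene test -> Student's t; normal but heteroscedastic
#' -> Welch's t; otherwise the two-sided Mann-Whitney U.
#'
#' @param x,y numeric samples, each of size >= 3.
#' @param alpha assumption-screening level (default 0.05).
#' @return one of `"student_t"`, `"welch_t"`, `"mann_whitney_u"`.
#' @export
choose_test <- function(x, y, alpha = 0.05) {
  if (length(x) < 3 || length(y) < 3) {
    stop("each sample needs at least 3 observations")
  }
  normal <- tryCatch(
    stats::shapiro.test(x)$p.value > alpha &&
      stats::shapiro.test(y)$p.value > alpha,
    error = function(e) FALSE)
  if (!normal) return("mann_whitney_u")
  if (levene_bf(x, y)$p.value > alpha) "student_t" else "welch_t"
}

#' Benjamini-Hochberg step-up adjusted values
#'
#' Step-up procedure: adjusted p for the i-th smallest p-value is
#' `min_{j >= i} (n * p_(j) / j)`, capped at 1; a hypothesis passes when
#' its adjusted value is below `q_level`.
#'
#' @param pvals p-values in `(0, 1]` (non-empty).
#' @param q_level FDR level (default 0.05).
#' @return list with `q` (adjusted values, input order) and `pass`.
#' @export
bh_fdr <- function(pvals, q_level = 0.05) {
  n <- length(pvals)
  if (n == 0) stop("empty p-value list")
  stopifnot(all(pvals > 0), all(pvals <= 1))
  o <- order(pvals)
  ranked <- pvals[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  q <- numeric(n)
  q[o] <- adj
  list(q = q, pass = q < q_level)
}

#' Cliff's delta effect size
#'
#' `delta = (#\{x_i > y_j\} - #\{x_i < y_j\}) / (n_x * n_y)`; ties
#' contribute zero.
#'
#' @param x,y numeric samples (non-empty).
#' @return delta in `[-1, 1]`.
#' @export
cliffs_delta <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  # rank-based O((n+m) log(n+m)) evaluation of the pair counts
  r <- rank(c(x, y))
  nx <- length(x); ny <- length(y)
  # sum of ranks of x among the pooled sample counts wins + 0.5*ties
  rx <- sum(r[seq_len(nx)])
  u <- rx - nx * (nx + 1) / 2          # wins + ties/2 of x over y
  (2 * u - nx * ny) / (nx * ny)
}

.run_test <- function(test, x, y) {
  switch(test,
         student_t = {
           h <- stats::t.test(x, y, var.equal = TRUE)
           list(stat = unname(h$statistic), p = h$p.value)
         },
         welch_t = {
           h <- stats::t.test(x, y, var.equal = FALSE)
           list(stat = unname(h$statistic), p = h$p.value)
         },
         mann_whitney_u = {
           exact <- min(length(x), length(y)) < 20 &&
             !any(duplicated(c(x, y)))
           h <- suppressWarnings(
             stats::wilcox.test(x, y, exact = exact, correct = TRUE))
           list(stat = unname(h$statistic), p = h$p.value)
         })
}

#' Compare tumor vs normal groups across the six texture metrics
#'
#' Spatial metrics (contrast, homogeneity) are tested on min-max
#' normalized values over the pooled groups; spectral metrics (ams, hfe,
#' sfc, sfv) on raw values. Each metric's test is selected by
#' [choose_test()]; the six p-values are BH-adjusted together
#' ([bh_fdr()]); effect sizes are Cliff's delta of tumor vs normal.
#'
#' @param table a `metric_table` from [feature_table()] with labels
#'   `"normal"` and `"tumor"`.
#' @param q_level FDR level (default 0.05).
#' @param alpha assumption-screening level (default 0.05).
#' @return data.frame, one row per metric:
#'   `metric,test,stat,p,q,significant,delta,direction,mean_normal,
#'   sd_normal,mean_tumor,sd_tumor`.
#' @export
compare_groups <- function(table, q_level = 0.05, alpha = 0.05) {
  labs <- unique(table$label)
  if (!all(c("normal", "tumor") %in% labs)) {
    stop("table must contain both 'normal' and 'tumor' labels")
  }
  spatial <- c("contrast", "homogeneity")
  spectral <- c("ams", "hfe", "sfc", "sfv")
  norm_tab <- minmax_normalize(table, columns = spatial)
  rows <- lapply(c(spatial, spectral), function(metric) {
    src <- if (metric %in% spatial) norm_tab else table
    x <- src[[metric]][src$label == "tumor"]
    y <- src[[metric]][src$label == "normal"]
    test <- choose_test(x, y, alpha)
    res <- .run_test(test, x, y)
    data.frame(metric = metric, test = test, stat = res$stat, p = res$p,
               delta = cliffs_delta(x, y),
               direction = sign(mean(x) - mean(y)),
               mean_normal = mean(y), sd_normal = stats::sd(y),
               mean_tumor = mean(x), sd_tumor = stats::sd(x),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  adj <- bh_fdr(out$p, q_level)
  out$q <- adj$q
  out$significant <- adj$pass
  out[, c("metric", "test", "stat", "p", "q", "significant", "delta",
          "direction", "mean_normal", "sd_normal", "mean_tumor",
          "sd_tumor")]
}
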