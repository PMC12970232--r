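# Seeded 2-D neighbor embedding for visualization only (no numeric
# contract beyond determinism). Compact exact t-SNE: Gaussian input
# affinities calibrated to a target perplexity by bisection, Student-t
# output kernel, momentum gradient descent with early exaggeration.

#' 2-D t-SNE embedding for visualization
#'
#' @param x feature matrix (rows = samples, >= 5).
#' @param seed seed for the random initialization.
#' @param perplexity target perplexity (effective neighbor count);
#'   capped at `(rows - 1) / 3`.
#' @param n_iter gradient-descent iterations (default 300).
#' @return numeric matrix `rows x 2`.
#' @export
embed_2d <- function(x, seed = 0L, perplexity = 30, n_iter = 300L) {
  x <- unclass(as.matrix(x))
  n <- nrow(x)
  if (n < 5) stop("need at least 5 rows to embed")
  perplexity <- min(perplexity, (n - 1) / 3)
  # pairwise squared distances
  ss <- rowSums(x^2)
  d2 <- pmax(outer(ss, ss, "+") - 2 * tcrossprod(x), 0)
  diag(d2) <- Inf
  logU <- log(perplexity)
  p <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta_lo <- 0; beta_hi <- Inf; beta <- 1
    di <- d2[i, ]
    for (it in 1:50) {
      w <- exp(-di * beta)
      w[i] <- 0
      sw <- sum(w)
      h <- log(sw) + beta * sum(di[is.finite(di)] * w[is.finite(di)]) / sw
      if (!is.finite(h)) h <- 0
      if (abs(h - logU) < 1e-5) break
      if (h > logU) {
        beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
      } else {
        beta_hi <- beta
        beta <- (beta + beta_lo) / 2
      }
    }
    p[i, ] <- w / sum(w)
  }
  p <- (p + t(p)) / (2 * n)
  p <- pmax(p, 1e-12)
  set.seed(as.integer(seed))
  y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  inc <- matrix(0, n, 2)
  momentum <- 0.5
  eta <- 200
  for (it in seq_len(n_iter)) {
    pe <- if (it <= 100) p * 4 else p      # early exaggeration
    sy <- rowSums(y^2)
    num <- 1 / (1 + pmax(outer(sy, sy, "+") - 2 * tcrossprod(y), 0))
    diag(num) <- 0
    q <- pmax(num / sum(num), 1e-12)
    g <- 4 * ((pe - q) * num)
    grad <- (diag(rowSums(g)) - g) %*% y
    if (it == 250) momentum <- 0.8
    inc <- momentum * inc - eta * grad
    y <- y + inc
    y <- sweep(y, 2, colMeans(y))
  }
  y
}
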