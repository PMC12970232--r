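# Independent brute-force oracles shared by the unit and acceptance tests.
# Deliberately written as plain loops / literal formula transcriptions,
# independent of the package implementation paths they check.

glcm_oracle_acc <- function(img, levels, offsets, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
  v <- img[mask]
  lo <- min(v); hi <- max(v)
  q <- matrix(NA_integer_, nrow(img), ncol(img))
  q[mask] <- if (hi > lo) {
    pmin(floor((img[mask] - lo) / (hi - lo) * levels), levels - 1)
  } else 0
  pm <- matrix(0, levels, levels)
  used <- 0
  for (off in offsets) {
    cnt <- matrix(0, levels, levels)
    for (r in seq_len(nrow(img))) for (cc in seq_len(ncol(img))) {
      r2 <- r + off[1]; c2 <- cc + off[2]
      if (r2 < 1 || r2 > nrow(img) || c2 < 1 || c2 > ncol(img)) next
      if (is.na(q[r, cc]) || is.na(q[r2, c2])) next
      i <- q[r, cc] + 1; j <- q[r2, c2] + 1
      cnt[i, j] <- cnt[i, j] + 1
      cnt[j, i] <- cnt[j, i] + 1
    }
    if (sum(cnt) > 0) {
      pm <- pm + cnt / sum(cnt)
      used <- used + 1
    }
  }
  p <- pm / used
  ii <- matrix(0:(levels - 1), levels, levels)
  jj <- t(ii)
  c(contrast = sum(p * (ii - jj)^2),
    homogeneity = sum(p / (1 + abs(ii - jj))))
}

bh_oracle_acc <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    cand <- vapply(i:n, function(j) n * p[o[j]] / j, numeric(1))
    adj[o[i]] <- min(1, min(cand))
  }
  adj
}

cliff_oracle_acc <- function(x, y) {
  s <- 0
  for (xi in x) for (yj in y) s <- s + sign(xi - yj)
  s / (length(x) * length(y))
}
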