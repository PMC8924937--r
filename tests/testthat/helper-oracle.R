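# Brute-force coordinate-descent elastic net, written independently of the
# package's fitting path. Mirrors the glmnet estimator convention: the
# response is scaled to unit (1/n)-variance and lambda with it, coordinates
# are cycled with soft-thresholding until the largest update falls below
# `tol`, and coefficients are rescaled to the original response units.
soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

enet_cd_oracle <- function(x, y, lambda, alpha, intercept = TRUE,
                           tol = 1e-13, max_iter = 100000L) {
  x <- as.matrix(x)
  p <- ncol(x)
  s <- sqrt(mean((y - mean(y))^2))
  ys <- y / s
  lam <- lambda / s
  xx <- colMeans(x^2)
  b <- rep(0, p)
  b0 <- if (intercept) mean(ys) else 0
  r <- ys - b0 - drop(x %*% b)
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      z <- mean(x[, j] * r) + xx[j] * b[j]
      bj <- soft_threshold(z, lam * alpha) / (xx[j] + lam * (1 - alpha))
      if (bj != b[j]) {
        r <- r + x[, j] * (b[j] - bj)
        delta <- max(delta, abs(bj - b[j]))
        b[j] <- bj
      }
    }
    if (intercept) {
      m <- mean(r)
      if (m != 0) {
        b0 <- b0 + m
        r <- r - m
        delta <- max(delta, abs(m))
      }
    }
    if (delta < tol) break
  }
  c(b0, b) * s
}
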