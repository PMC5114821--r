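# Radial-basis-function kernel base classifier.
#
# The base learner is a kernel logistic classifier: decision function
# f(x) = b + sum_j alpha_j K(x, c_j) with K(x, z) = exp(-gamma ||x - z||^2),
# fitted by penalized IRLS with ridge penalty (1/C) * alpha' K_cc alpha
# (intercept unpenalized).  For large training sets a random subset of rows
# serves as centers (Nystrom-style subset of regressors); below the cap the
# fit is the exact kernel machine.  Probabilities come straight from the
# logistic link, so no separate calibration step is needed.

rbf_kernel <- function(a, b, gamma) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

# sklearn-style "scale" default for the kernel width
default_gamma <- function(x) {
  v <- mean(apply(x, 2L, stats::var))
  if (!is.finite(v) || v <= 0) v <- 1
  1 / (ncol(x) * v)
}

klr_fit <- function(x, y, gamma = NULL, cost = 1, max_centers = 512L,
                    max_iter = 50L, tol = 1e-9) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (length(y) != n) stop_ligbind("x and y lengths differ")
  if (is.null(gamma)) gamma <- default_gamma(x)
  ci <- if (n > max_centers) sort(sample.int(n, max_centers)) else seq_len(n)
  centers <- x[ci, , drop = FALSE]
  K <- rbf_kernel(x, centers, gamma)
  Kmm <- rbf_kernel(centers, centers, gamma)
  m <- ncol(K)
  lambda <- 1 / cost
  P <- rbind(0, cbind(0, lambda * Kmm + 1e-8 * diag(m)))
  Z <- cbind(1, K)
  theta <- numeric(m + 1L)
  pen_dev <- function(th) {
    eta <- drop(Z %*% th)
    -2 * sum(y * eta - log1p(exp(eta))) + drop(t(th) %*% P %*% th)
  }
  dev <- pen_dev(theta)
  for (it in seq_len(max_iter)) {
    eta <- drop(Z %*% theta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(Z, y - mu)) - drop(P %*% theta)
    H <- crossprod(Z * w, Z) + P
    step <- tryCatch(solve(H, grad), error = function(e) {
      solve(H + 1e-6 * diag(nrow(H)), grad)
    })
    # step-halving line search on the penalized deviance
    shrink <- 1
    repeat {
      cand <- theta + shrink * step
      cand_dev <- pen_dev(cand)
      if (is.finite(cand_dev) && cand_dev <= dev + 1e-12) break
      shrink <- shrink / 2
      if (shrink < 1e-6) break
    }
    moved <- max(abs(shrink * step))
    theta <- theta + shrink * step
    dev <- pen_dev(theta)
    if (moved < tol) break
  }
  structure(list(centers = centers, gamma = gamma, cost = cost,
                 b = theta[1], alpha = theta[-1]),
            class = "ligbind_klr")
}

klr_prob <- function(fit, x) {
  x <- as.matrix(x)
  if (ncol(x) != ncol(fit$centers)) {
    stop_ligbind("feature dimension %d does not match training dimension %d",
                 ncol(x), ncol(fit$centers))
  }
  drop(stats::plogis(fit$b + rbf_kernel(x, fit$centers, fit$gamma) %*% fit$alpha))
}
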