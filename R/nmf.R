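# Non-negative matrix factorization: Frobenius objective, multiplicative
# updates, NNDSVD-based initialization. Written for small dense problems
# (thousands of spots by tens of cell states).

# NNDSVD initialization (Boutsidis & Gallopoulos). Zeros arising from the
# sign splits are filled with a small positive value (mean(A)/100) so that
# multiplicative updates do not lock entries at zero.
nndsvd_init <- function(A, k) {
  sv <- svd(A, nu = k, nv = k)
  n <- nrow(A); m <- ncol(A)
  W <- matrix(0, n, k); H <- matrix(0, k, m)
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (k >= 2) {
    for (j in 2:k) {
      x <- sv$u[, j]; y <- sv$v[, j]
      xp <- pmax(x, 0); xn <- pmax(-x, 0)
      yp <- pmax(y, 0); yn <- pmax(-y, 0)
      xpn <- sqrt(sum(xp^2)); xnn <- sqrt(sum(xn^2))
      ypn <- sqrt(sum(yp^2)); ynn <- sqrt(sum(yn^2))
      mp <- xpn * ypn; mn <- xnn * ynn
      if (mp >= mn) {
        u <- if (xpn > 0) xp / xpn else xp
        v <- if (ypn > 0) yp / ypn else yp
        sig <- mp
      } else {
        u <- if (xnn > 0) xn / xnn else xn
        v <- if (ynn > 0) yn / ynn else yn
        sig <- mn
      }
      W[, j] <- sqrt(sv$d[j] * sig) * u
      H[j, ] <- sqrt(sv$d[j] * sig) * v
    }
  }
  fill <- mean(A) / 100
  W[W < fill] <- fill
  H[H < fill] <- fill
  list(W = W, H = H)
}

#' Fit NMF by multiplicative updates
#'
#' Minimizes `0.5 * ||A - W H||_F^2` over nonnegative factors with the
#' classical multiplicative update rules, starting from an NNDSVD
#' initialization (deterministic: the `seed` only matters for the random
#' fallback used if the SVD rank is insufficient). The objective is
#' evaluated every `check_every` iterations; iteration stops when its
#' relative change falls below `tol` or `max_iter` is reached.
#'
#' @param A nonnegative matrix (spots x features).
#' @param k number of components.
#' @param seed RNG seed (rarely consumed, see above).
#' @param max_iter,tol,check_every convergence controls.
#' @return list with `W` (n x k), `H` (k x m), `objective` (trace of
#'   recorded objective values), `iterations`.
#' @export
nmf_fit <- function(A, k, seed = 0L, max_iter = 2000L, tol = 1e-6,
                    check_every = 10L) {
  A <- as.matrix(A)
  stopifnot(all(A >= 0), k >= 1, k <= min(dim(A)))
  set.seed(seed)
  init <- nndsvd_init(A, k)
  W <- init$W; H <- init$H
  eps <- 1e-12
  obj <- function() 0.5 * sum((A - W %*% H)^2)
  trace <- obj()
  last <- trace[1]
  it <- 0L
  while (it < max_iter) {
    for (step in seq_len(check_every)) {
      it <- it + 1L
      H <- H * (crossprod(W, A)) / (crossprod(W) %*% H + eps)
      W <- W * (A %*% t(H)) / (W %*% tcrossprod(H) + eps)
      if (it >= max_iter) break
    }
    cur <- obj()
    trace <- c(trace, cur)
    if (last - cur <= tol * max(last, eps)) break
    last <- cur
  }
  list(W = W, H = H, objective = trace, iterations = it)
}
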