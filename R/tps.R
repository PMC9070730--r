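## Thin-plate-spline machinery shared by the forward and inverse warps.
## Standard formulation: radial kernel U(r) = r^2 log(r^2) plus an
## affine part, solved as one bordered linear system; lambda on the
## kernel diagonal gives the smoothing (approximating) spline.

.tpsKernel <- function(d2) {
  k <- matrix(0, nrow(d2), ncol(d2))
  pos <- d2 > 0
  k[pos] <- d2[pos] * log(d2[pos])
  k
}

.tpsDist2 <- function(a, b) {
  ## squared distances between rows of a (m x 2) and b (n x 2)
  outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
}

.tpsFit <- function(src, dst, lambda = 0) {
  n <- nrow(src)
  if (n < 4) stop("thin-plate-spline fit needs at least 4 control pairs")
  if (anyDuplicated(src))
    stop("duplicated control points make the spline system singular")
  P <- cbind(1, src)
  if (qr(P)$rank < 3)
    stop("collinear control points make the spline system singular")
  K <- .tpsKernel(.tpsDist2(src, src)) + diag(lambda, n)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(dst, matrix(0, 3, 2))
  coef <- tryCatch(solve(L, rhs), error = function(e)
    stop(sprintf("singular thin-plate-spline system: %s", conditionMessage(e))))
  list(src = src, coef = coef)
}

.tpsEval <- function(fit, pts) {
  if (!nrow(pts)) return(pts)
  U <- .tpsKernel(.tpsDist2(pts, fit$src))
  n <- nrow(fit$src)
  w <- fit$coef[seq_len(n), , drop = FALSE]
  a <- fit$coef[n + 1:3, , drop = FALSE]
  U %*% w + cbind(1, pts) %*% a
}

.tpsBendingEnergy <- function(fit) {
  n <- nrow(fit$src)
  w <- fit$coef[seq_len(n), , drop = FALSE]
  K <- .tpsKernel(.tpsDist2(fit$src, fit$src))
  sum(diag(t(w) %*% K %*% w))
}
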