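## Exact non-negative least squares on the normal equations.
##
## Each ALS mode update solves rows of min ||Z u - w||^2, u >= 0 where the
## R x R Gram AtA = Z'Z (Hadamard product of the other modes' Grams) and the
## R-vector Atb come from the matricised-tensor-times-Khatri-Rao product, so
## the Lawson-Hanson active-set iteration is run entirely in Gram form.  The
## solver is exact (KKT at termination), which is what makes the ALS sweep
## objective provably non-increasing.

solveSym <- function(A, B) {
  out <- tryCatch(solve(A, B), error = function(e) NULL)
  if (is.null(out)) out <- pinv(A) %*% B   # rank-deficient fallback
  out
}

## Single problem: min ||Zu - w||^2 s.t. u >= 0, given AtA = Z'Z, Atb = Z'w.
nnlsGram <- function(AtA, Atb, maxIter = 30L * length(Atb)) {
  R <- length(Atb)
  x <- numeric(R)
  P <- logical(R)
  w <- Atb                       # gradient of -0.5*objective at x = 0
  tolw <- 1e-12 * max(abs(Atb), 1)
  iter <- 0L
  while (any(!P) && max(w[!P]) > tolw && iter < maxIter) {
    iter <- iter + 1L
    j <- which(!P)[which.max(w[!P])]
    P[j] <- TRUE
    repeat {
      s <- numeric(R)
      s[P] <- drop(solveSym(AtA[P, P, drop = FALSE], Atb[P]))
      if (all(s[P] > 0)) { x <- s; break }
      viol <- P & (s <= 0)
      alpha <- min(x[viol] / (x[viol] - s[viol]))
      x <- x + alpha * (s - x)
      P[P & (x <= .Machine$double.eps * max(x, 1))] <- FALSE
      x[!P] <- 0
    }
    w <- Atb - drop(AtA %*% x)
  }
  x
}

## Batch of problems sharing one Gram: columns of AtB are right-hand sides.
## The unconstrained solution is computed for all problems in one solve; only
## columns with active constraints fall back to the per-problem active set.
nnlsGramBatch <- function(AtA, AtB) {
  X <- solveSym(AtA, AtB)
  bad <- which(apply(X, 2L, function(v) any(v < 0)))
  for (j in bad) X[, j] <- nnlsGram(AtA, AtB[, j])
  X
}
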