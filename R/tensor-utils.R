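## Multiway array primitives shared by the CP engine.

## Mode-m unfolding: rows index mode m, columns index the remaining modes in
## increasing order with the lowest mode varying fastest (column-major).
unfold <- function(W, mode) {
  dims <- dim(W)
  perm <- c(mode, setdiff(seq_along(dims), mode))
  dim(W) <- dims  # guard against dim-dropped vectors
  matrix(aperm(W, perm), nrow = dims[mode])
}

## Inverse of unfold.
refold <- function(M, mode, dims) {
  other <- setdiff(seq_along(dims), mode)
  arr <- array(M, c(nrow(M), dims[other]))
  aperm(arr, order(c(mode, other)))
}

## Khatri-Rao product of a list of factor matrices given in increasing mode
## order; the FIRST matrix's row index varies fastest, matching unfold().
krList <- function(mats) {
  Reduce(function(acc, m) {
    n1 <- nrow(acc); n2 <- nrow(m)
    acc[rep(seq_len(n1), times = n2), , drop = FALSE] *
      m[rep(seq_len(n2), each = n1), , drop = FALSE]
  }, mats)
}

## Mode-m product with a matrix A (newSize x oldSize).
ttm <- function(W, A, mode) {
  dims <- dim(W)
  Y <- A %*% unfold(W, mode)
  newdims <- dims; newdims[mode] <- nrow(A)
  refold(Y, mode, newdims)
}

## Reconstruct the full array from CP factors.
cpReconstruct <- function(factors) {
  dims <- vapply(factors, nrow, integer(1))
  M1 <- factors[[1]] %*% t(krList(factors[-1]))
  refold(M1, 1L, dims)
}

## Project the first three modes of a 5-way array onto unit-scaled component
## profiles: G[s, c, r] = sum_ijk W[i,j,k,s,c] A[i,r] B[j,r] C[k,r].
projectSlabLoadings <- function(W, A, B, C) {
  dims <- dim(W)
  stopifnot(length(dims) == 5L)
  R <- ncol(A)
  G <- array(0, c(dims[4], dims[5], R))
  for (r in seq_len(R)) {
    Y <- ttm(W, matrix(A[, r], 1L), 1L)
    Y <- ttm(Y, matrix(B[, r], 1L), 2L)
    Y <- ttm(Y, matrix(C[, r], 1L), 3L)
    G[, , r] <- Y[1, 1, 1, , ]
  }
  G
}

## Moore-Penrose pseudoinverse (thin wrapper, tolerance-scaled).
pinv <- function(M) MASS::ginv(M)

## All permutations of 1..n (n small; used for component matching).
allPermutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- vector("list", factorial(n))
  k <- 0L
  rec <- function(head, rest) {
    if (!length(rest)) { k <<- k + 1L; out[[k]] <<- head; return(invisible()) }
    for (i in seq_along(rest)) rec(c(head, rest[i]), rest[-i])
  }
  rec(integer(0), seq_len(n))
  out
}
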