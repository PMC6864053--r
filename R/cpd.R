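## Non-negative canonical polyadic (PARAFAC) decomposition by alternating
## exact NNLS, with explained variance, CORCONDIA, rank sweep and
## factor-matching diagnostics.

asArray <- function(x) {
  if (is(x, "Tensor5D")) x@values
  else if (is(x, "TFRTensor")) x@values
  else if (is.array(x)) x
  else stop("expected a Tensor5D, TFRTensor or numeric array")
}

modeNamesOf <- function(x) {
  if (is(x, "Tensor5D"))
    c("space", "frequency", "time", "subject", "condition")
  else paste0("mode", seq_along(dim(asArray(x))))
}

factorList <- function(x) {
  if (is(x, "CPModel")) x@factors
  else if (is(x, "GroundTruth"))
    list(x@spaceFactors, x@freqFactors, x@timeFactors, x@subjectLoadings,
         appliedConditionLoadings(x))
  else if (is.list(x) && all(vapply(x, is.matrix, logical(1)))) x
  else stop("expected a CPModel, GroundTruth or list of factor matrices")
}

## One ALS run from a given initialisation.
cpALSEngine <- function(W, U, maxIter, tol, nonneg, fixedModes) {
  dims <- dim(W)
  M <- length(dims)
  normW2 <- sum(W^2)
  Gram <- lapply(U, crossprod)
  free <- setdiff(seq_len(M), fixedModes)
  if (!length(free)) stop("at least one mode must be free")
  objTrace <- numeric(0)
  fit <- -Inf
  converged <- FALSE
  it <- 0L
  V <- NULL
  for (it in seq_len(maxIter)) {
    for (m in free) {
      Z <- krList(U[-m])
      V <- unfold(W, m) %*% Z
      H <- Reduce(`*`, Gram[-m])
      Um <- if (nonneg) t(nnlsGramBatch(H, t(V))) else t(solveSym(H, t(V)))
      U[[m]] <- Um
      Gram[[m]] <- crossprod(Um)
    }
    mLast <- free[length(free)]
    res2 <- max(0, normW2 - 2 * sum(U[[mLast]] * V) +
                    sum(Reduce(`*`, Gram[-mLast]) * Gram[[mLast]]))
    objTrace <- c(objTrace, res2)
    fitNew <- 100 * (1 - res2 / normW2)
    if (it > 1L && abs(fitNew - fit) / 100 < tol) {
      fit <- fitNew
      converged <- TRUE
      break
    }
    fit <- fitNew
  }
  list(U = U, fit = fit, iterations = it, converged = converged,
       objTrace = objTrace)
}

randomInit <- function(dims, R) lapply(dims, function(d) abs(matrix(rnorm(d * R), d, R)))

#' Non-negative CP decomposition by alternating least squares
#'
#' Fits the canonical polyadic model with per-mode exact non-negative
#' least-squares updates (Lawson--Hanson active set on the normal equations).
#' Modes listed in \code{fixedModes} of the configuration are never updated.
#' The Frobenius objective is non-increasing across sweeps; iteration stops
#' when the relative change in fit drops below \code{tol} or after
#' \code{maxIterations} sweeps.  With random initialisation the best of
#' \code{nRestarts} runs (by fit) is returned, deterministically for a given
#' seed.  The squared-residual trace of the winning run is attached as
#' attribute \code{"objTrace"}.
#'
#' @param tensor a \linkS4class{Tensor5D} or numeric array of order >= 3.
#' @param cfg a \linkS4class{DecomposeConfig}.
#' @return a \linkS4class{CPModel} (normalization "raw").
#' @examples
#' a <- abs(rnorm(4)); b <- abs(rnorm(3)); d <- abs(rnorm(3))
#' W <- array(outer(outer(a, b), d), c(4, 3, 3))
#' m <- nncpALS(W, decomposeConfig(rank = 1, seed = 2))
#' fitPercent(m)  # 100: the tensor is exactly rank one
#' @export
nncpALS <- function(tensor, cfg) {
  W <- asArray(tensor)
  dims <- dim(W)
  if (length(dims) < 3L) stop("tensor order must be >= 3")
  if (all(W == 0)) stop("all-zero tensor cannot be decomposed")
  R <- cfg@rank
  if (R > min(dims))
    warning("rank exceeds the smallest mode size; solution is not unique")
  if (length(cfg@fixedModes) && !is.list(cfg@init))
    stop("fixedModes requires a provided init holding the fixed factors")
  runs <- if (is.list(cfg@init)) 1L else cfg@nRestarts
  ## a restart can drive a component to all-zero (a local minimum of lower
  ## effective rank); such runs are kept only if no clean restart is found,
  ## drawing up to 2*nRestarts extra random starts first
  maxRuns <- if (is.list(cfg@init)) 1L else 3L * cfg@nRestarts
  hasDeadColumn <- function(U)
    any(vapply(U, function(m) any(colSums(m^2) == 0), logical(1)))
  best <- NULL
  bestClean <- NULL
  k <- 0L
  while (k < runs || (is.null(bestClean) && k < maxRuns)) {
    k <- k + 1L
    U0 <- if (is.list(cfg@init)) {
      stopifnot(length(cfg@init) == length(dims))
      lapply(cfg@init, function(m) {
        stopifnot(is.matrix(m), ncol(m) == R)
        m
      })
    } else {
      set.seed(cfg@seed + k - 1L)
      randomInit(dims, R)
    }
    run <- cpALSEngine(W, U0, cfg@maxIterations, cfg@tol, cfg@nonneg,
                       cfg@fixedModes)
    if (is.null(best) || run$fit > best$fit) best <- run
    if (!hasDeadColumn(run$U) &&
        (is.null(bestClean) || run$fit > bestClean$fit)) bestClean <- run
  }
  if (!is.null(bestClean)) best <- bestClean
  if (!cfg@nonneg) warnDegenerate(best$U)
  model <- new("CPModel", factors = best$U, rank = R,
               fitPercent = best$fit, iterations = best$iterations,
               converged = best$converged, normalization = "raw",
               modeNames = modeNamesOf(tensor))
  attr(model, "objTrace") <- best$objTrace
  model
}

## Classical CP degeneracy watch: two components whose product of per-mode
## congruences approaches -1 (only reachable without the sign constraint).
warnDegenerate <- function(U, threshold = -0.85) {
  R <- ncol(U[[1]])
  if (R < 2L) return(invisible())
  prodCong <- matrix(1, R, R)
  for (m in seq_along(U)) {
    nrm <- sqrt(colSums(U[[m]]^2))
    if (any(nrm == 0)) return(invisible())
    Un <- sweep(U[[m]], 2L, nrm, "/")
    prodCong <- prodCong * crossprod(Un)
  }
  low <- min(prodCong[upper.tri(prodCong)])
  if (low < threshold)
    warning(sprintf(
      "possible degenerate CP solution: component congruence product %.3f",
      low))
  invisible()
}

#' Explained variance of a CP model
#'
#' Recomputes \code{100 * (1 - ||W - What||_F^2 / ||W||_F^2)} from the full
#' reconstruction.
#'
#' @param model a \linkS4class{CPModel}.
#' @param tensor the tensor the model was fitted to.
#' @return percent explained variance (at most 100; can be negative for a
#'   model worse than the zero model).
#' @export
explainedVariance <- function(model, tensor) {
  W <- asArray(tensor)
  dims <- vapply(model@factors, nrow, integer(1))
  if (!identical(as.integer(dim(W)), as.integer(dims)))
    stop("model and tensor shapes do not match")
  normW2 <- sum(W^2)
  if (normW2 == 0) stop("zero-norm tensor")
  res2 <- sum((W - cpReconstruct(model@factors))^2)
  100 * (1 - res2 / normW2)
}

#' Core consistency diagnostic (CORCONDIA)
#'
#' Fits the least-squares Tucker core implied by the model's factor matrices
#' (computed by projecting the tensor with per-mode pseudoinverses, which is
#' the exact least-squares core whenever it is defined) and measures its
#' similarity to the ideal superdiagonal core:
#' \code{100 * (1 - sum((G - T)^2) / sum(T^2))} with T the unit superdiagonal.
#' Values near 100 indicate an adequately multilinear model; the value may be
#' negative.
#'
#' @param model a \linkS4class{CPModel} with full-column-rank factors.
#' @param tensor the tensor the model was fitted to.
#' @return percent core consistency.
#' @export
corcondia <- function(model, tensor) {
  W <- asArray(tensor)
  U <- model@factors
  dims <- vapply(U, nrow, integer(1))
  if (!identical(as.integer(dim(W)), as.integer(dims)))
    stop("model and tensor shapes do not match")
  R <- model@rank
  for (m in seq_along(U)) {
    d <- svd(U[[m]], nu = 0, nv = 0)$d
    if (d[R] / d[1] < 1e-10)
      stop("rank-deficient factor matrix in mode ", m,
           "; the model is over-factored, try a lower rank")
  }
  G <- W
  for (m in seq_along(U)) G <- ttm(G, pinv(U[[m]]), m)
  superdiag <- matrix(rep(seq_len(R), length(U)), nrow = R)
  Tcore <- array(0, dim(G))
  Tcore[superdiag] <- 1
  100 * (1 - sum((G - Tcore)^2) / R)
}

#' Canonical normalisation of a CP model
#'
#' Rescales every mode except the last to unit-Euclidean-norm columns and
#' absorbs all component scale into the last (condition) mode.  The
#' reconstruction is unchanged.
#'
#' @param model a \linkS4class{CPModel}.
#' @return the model in canonical form.
#' @export
normalizeModel <- function(model) {
  U <- model@factors
  M <- length(U)
  lambda <- rep(1, model@rank)
  for (m in seq_len(M - 1L)) {
    nrm <- sqrt(colSums(U[[m]]^2))
    zero <- which(nrm <= 0)
    if (length(zero))
      stop("zero column for component ", zero[1], " in mode ", m)
    U[[m]] <- sweep(U[[m]], 2L, nrm, "/")
    lambda <- lambda * nrm
  }
  U[[M]] <- sweep(U[[M]], 2L, lambda, "*")
  out <- new("CPModel", factors = U, rank = model@rank,
             fitPercent = model@fitPercent, iterations = model@iterations,
             converged = model@converged, normalization = "canonical",
             modeNames = model@modeNames)
  attr(out, "objTrace") <- attr(model, "objTrace")
  out
}

## Tolerant variant used inside the permutation loop: a component whose
## loading column dies under a permutation is reported with zero scale
## instead of aborting the null draw.
normalizeFactorsTolerant <- function(U) {
  M <- length(U)
  lambda <- rep(1, ncol(U[[1]]))
  for (m in seq_len(M - 1L)) {
    nrm <- sqrt(colSums(U[[m]]^2))
    dead <- nrm <= 0
    nrm[dead] <- 1
    U[[m]] <- sweep(U[[m]], 2L, nrm, "/")
    lambda <- lambda * ifelse(dead, 0, nrm)
  }
  U[[M]] <- sweep(U[[M]], 2L, lambda, "*")
  U
}

#' Rank sweep with fit diagnostics
#'
#' Decomposes the tensor once per candidate rank (identical seeds across
#' ranks for comparability) and tabulates explained variance and CORCONDIA.
#'
#' @param tensor a \linkS4class{Tensor5D} or numeric array.
#' @param ranks integer vector of candidate ranks (default 1:8).
#' @param cfg a \linkS4class{DecomposeConfig}; its rank slot is replaced by
#'   each candidate in turn.
#' @return data.frame with columns rank, explained_variance, corcondia
#'   (CORCONDIA is NA where the fitted factors are rank-deficient).
#' @export
sweepRank <- function(tensor, ranks = 1:8, cfg = decomposeConfig(rank = 1)) {
  stopifnot(length(ranks) >= 1L)
  rows <- lapply(as.integer(ranks), function(R) {
    cfgR <- cfg
    cfgR@rank <- R
    model <- nncpALS(tensor, cfgR)
    cc <- tryCatch(corcondia(model, tensor), error = function(e) NA_real_)
    data.frame(rank = R,
               explained_variance = explainedVariance(model, tensor),
               corcondia = cc)
  })
  do.call(rbind, rows)
}

#' Tucker congruence between component sets
#'
#' Computes the normalised inner product between component columns of two
#' factor sets, averaged over a mode subset, together with the optimal
#' one-to-one component matching (exhaustive over permutations; rank is
#' small).
#'
#' @param modelA,modelB \linkS4class{CPModel}, \linkS4class{GroundTruth} or
#'   lists of factor matrices with equal mode sizes.
#' @param modes integer subset of modes to average over (default: all).
#' @return list with elements \code{matrix} (R x R mean congruence),
#'   \code{matching} (permutation: component j of B matched to component
#'   \code{matching[j]} of A... index into A for each column of B),
#'   \code{matched} (per-pair congruence under the matching) and \code{mean}.
#' @export
congruence <- function(modelA, modelB, modes = NULL) {
  UA <- factorList(modelA)
  UB <- factorList(modelB)
  stopifnot(length(UA) == length(UB))
  if (is.null(modes)) modes <- seq_along(UA)
  R <- ncol(UA[[1]])
  phi <- matrix(0, R, R)
  for (m in modes) {
    if (nrow(UA[[m]]) != nrow(UB[[m]]))
      stop("mode ", m, " sizes differ")
    na <- sqrt(colSums(UA[[m]]^2))
    nb <- sqrt(colSums(UB[[m]]^2))
    if (any(na == 0) || any(nb == 0))
      stop("zero column in mode ", m)
    phi <- phi + crossprod(sweep(UA[[m]], 2L, na, "/"),
                           sweep(UB[[m]], 2L, nb, "/"))
  }
  phi <- phi / length(modes)
  perms <- allPermutations(R)
  scores <- vapply(perms, function(p) sum(phi[cbind(p, seq_len(R))]),
                   numeric(1))
  bestPerm <- perms[[which.max(scores)]]
  matched <- phi[cbind(bestPerm, seq_len(R))]
  list(matrix = phi, matching = bestPerm, matched = matched,
       mean = mean(matched))
}

#' Ground truth as a canonical CP model
#'
#' Packages the generating factors (with the drug effect applied to the
#' condition loadings) as a \linkS4class{CPModel} for congruence checks
#' against fitted models.
#'
#' @param gt a \linkS4class{GroundTruth}.
#' @return a canonical-form \linkS4class{CPModel}.
#' @export
groundTruthModel <- function(gt) {
  U <- factorList(gt)
  new("CPModel", factors = normalizeFactorsTolerant(U),
      rank = ncol(U[[1]]), fitPercent = NA_real_, iterations = 0L,
      converged = TRUE, normalization = "canonical",
      modeNames = c("space", "frequency", "time", "subject", "condition"))
}
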