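## Condition-contrast tensors, master decomposition and the fixed-factor
## permutation test on condition loadings.

#' Stack per-subject/condition tensors into a five-way tensor
#'
#' @param tfrStore either a nested list \code{store[[subject]][[condition]]}
#'   of \linkS4class{TFRTensor} objects, or a \linkS4class{StudyContainer}
#'   whose /tfr group holds them.
#' @param contrast a \linkS4class{ContrastModel}; its label order defines the
#'   condition axis.
#' @param subjects subject identifiers; default: all subjects in the store.
#' @return a \linkS4class{Tensor5D} ordered
#'   (space, frequency, time, subject, condition).
#' @export
buildModelTensor <- function(tfrStore, contrast, subjects = NULL) {
  if (is(tfrStore, "StudyContainer")) tfrStore <- readTFRStore(tfrStore)
  if (is.null(subjects)) subjects <- names(tfrStore)
  labs <- contrast@conditionLabels
  ref <- NULL
  slabs <- vector("list", length(subjects) * length(labs))
  k <- 0L
  for (ci in seq_along(labs)) for (si in seq_along(subjects)) {
    cell <- tfrStore[[subjects[si]]][[labs[ci]]]
    if (is.null(cell))
      stop("missing TFR tensor for subject ", subjects[si],
           ", condition ", labs[ci])
    if (is.null(ref)) ref <- cell
    if (!identical(dim(cell@values), dim(ref@values)) ||
        !isTRUE(all.equal(cell@freqs, ref@freqs)) ||
        !isTRUE(all.equal(cell@times, ref@times)) ||
        !identical(cell@channels, ref@channels))
      stop("axis mismatch for subject ", subjects[si],
           ", condition ", labs[ci])
    k <- k + 1L
    slabs[[k]] <- cell@values
  }
  d3 <- dim(ref@values)
  values <- array(unlist(slabs, use.names = FALSE),
                  c(d3, length(subjects), length(labs)))
  tensor5D(values, channels = ref@channels, freqs = ref@freqs,
           times = ref@times, subjects = subjects, conditionLabels = labs)
}

#' Master decomposition
#'
#' Non-negative CP fit of the five-way tensor (default rank 3) returned in
#' canonical normalisation, so the condition loadings carry all component
#' scale and are comparable across permutation refits.
#'
#' @param tensor a \linkS4class{Tensor5D}.
#' @param cfg a \linkS4class{DecomposeConfig} (default rank 3).
#' @return a canonical-form \linkS4class{CPModel}.
#' @export
masterDecomposition <- function(tensor, cfg = decomposeConfig(rank = 3)) {
  normalizeModel(nncpALS(tensor, cfg))
}

#' Permute subject/condition slabs
#'
#' Reassigns the S x C grid of 3-D (space, frequency, time) slabs by a
#' permutation of all S*C slab positions; each slab's internal structure is
#' untouched.  With \code{perm = NULL} a uniformly random permutation is
#' drawn from the current RNG state.
#'
#' @param tensor a \linkS4class{Tensor5D}.
#' @param perm permutation of \code{seq_len(S*C)} (position i receives the
#'   slab at linear index perm[i], subject index varying fastest), or NULL.
#' @return a \linkS4class{Tensor5D}.
#' @export
permuteTensor <- function(tensor, perm = NULL) {
  d <- dim(tensor@values)
  nSlab <- d[4] * d[5]
  if (is.null(perm)) perm <- sample.int(nSlab)
  stopifnot(length(perm) == nSlab, all(sort(perm) == seq_len(nSlab)))
  Wm <- matrix(tensor@values, prod(d[1:3]), nSlab)
  initialize(tensor, values = array(Wm[, perm], d))
}

## Permutation index for the within-subject scheme: condition labels are
## shuffled independently inside each subject's block.
withinSubjectPerm <- function(S, C) {
  idx <- matrix(seq_len(S * C), S, C)
  for (s in seq_len(S)) idx[s, ] <- idx[s, sample.int(C)]
  as.vector(idx)
}

## ALS refit of the subject/condition loadings given the projected array
## G[s,c,r] (see projectSlabLoadings) and the fixed-mode Gram product P.
refitFromG <- function(G, P, D, E, maxIter = 100L, tol = 1e-10,
                       normW2 = NULL) {
  R <- ncol(D)
  fit <- Inf
  it <- 0L
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    VD <- vapply(seq_len(R), function(r) G[, , r] %*% E[, r],
                 numeric(nrow(D)))
    D <- t(nnlsGramBatch(P * crossprod(E), t(VD)))
    VE <- vapply(seq_len(R), function(r) crossprod(G[, , r], D[, r]),
                 numeric(nrow(E)))
    E <- t(nnlsGramBatch(P * crossprod(D), t(VE)))
    ## objective up to the constant ||W||^2
    obj <- -2 * sum(E * VE) + sum((P * crossprod(D)) * crossprod(E))
    ref <- if (is.null(normW2)) abs(obj) + 1 else normW2
    if (it > 1L && abs(obj - fit) / ref < tol) {
      fit <- obj
      converged <- TRUE
      break
    }
    fit <- obj
  }
  list(D = D, E = E, iterations = it, converged = converged, obj = fit)
}

#' Refit subject and condition loadings with fixed component profiles
#'
#' Freezes the space, frequency and time factor matrices at the master's
#' values and re-estimates the subject and condition loadings by alternating
#' exact NNLS, warm-started at the master loadings.  The refit depends on the
#' tensor only through the projected array
#' \code{G[s,c,r] = sum_ijk W[i,j,k,s,c] A[i,r] B[j,r] C[k,r]}, which makes
#' the permutation loop cheap.  The result is returned in canonical form;
#' the frozen modes are bit-identical to the master's.
#'
#' @param tensor a \linkS4class{Tensor5D} (possibly permuted).
#' @param master canonical-form \linkS4class{CPModel} from
#'   \code{\link{masterDecomposition}}.
#' @param maxIter maximum alternating sweeps (default 100).
#' @param tol relative objective tolerance.
#' @return a canonical-form \linkS4class{CPModel}.
#' @export
refitLoadings <- function(tensor, master, maxIter = 100L, tol = 1e-10) {
  stopifnot(is(master, "CPModel"))
  if (master@normalization != "canonical")
    stop("master model must be in canonical form (see normalizeModel)")
  W <- asArray(tensor)
  U <- master@factors
  G <- projectSlabLoadings(W, U[[1]], U[[2]], U[[3]])
  P <- crossprod(U[[1]]) * crossprod(U[[2]]) * crossprod(U[[3]])
  normW2 <- sum(W^2)
  rf <- refitFromG(G, P, U[[4]], U[[5]], maxIter = maxIter, tol = tol,
                   normW2 = normW2)
  de <- normalizeDE(rf$D, rf$E)
  fac <- list(U[[1]], U[[2]], U[[3]], de$D, de$E)
  fit <- 100 * (1 - max(0, normW2 + rf$obj) / normW2)
  new("CPModel", factors = fac, rank = master@rank, fitPercent = fit,
      iterations = rf$iterations, converged = rf$converged,
      normalization = "canonical", modeNames = master@modeNames)
}

## Move all component scale from the (already refit) subject loadings onto
## the condition loadings without touching the frozen modes, so they stay
## bit-identical to the master's.  A component whose loadings die under a
## permutation gets scale zero instead of aborting the draw.
normalizeDE <- function(D, E) {
  nrm <- sqrt(colSums(D^2))
  dead <- nrm <= 0
  nrm[dead] <- 1
  D <- sweep(D, 2L, nrm, "/")
  E <- sweep(E, 2L, ifelse(dead, 0, nrm), "*")
  list(D = D, E = E)
}

## Compiled form of the tested statistics: one (post, pre) index pair per
## contrast plus an optional difference-of-differences, evaluated on a
## condition-loading matrix without data.frame overhead.
statDefs <- function(labels, contrast) {
  pairs <- lapply(contrast@contrasts, function(p) match(p, labels))
  names(pairs) <- vapply(contrast@contrasts,
                         function(p) sprintf("%s - %s", p[1], p[2]),
                         character(1))
  between <- NULL
  if (length(contrast@betweenDrug)) {
    p1 <- contrast@betweenDrug[[1]]
    p2 <- contrast@betweenDrug[[2]]
    between <- list(idx = c(match(p1, labels), match(p2, labels)),
                    label = sprintf("(%s - %s) - (%s - %s)",
                                    p1[1], p1[2], p2[1], p2[2]))
  }
  list(pairs = pairs, between = between)
}

evalStats <- function(E, defs) {
  out <- unlist(lapply(defs$pairs, function(ix) E[ix[1], ] - E[ix[2], ]),
                use.names = FALSE)
  if (!is.null(defs$between)) {
    ix <- defs$between$idx
    out <- c(out, (E[ix[1], ] - E[ix[2], ]) - (E[ix[3], ] - E[ix[4], ]))
  }
  out
}

contrastStatistics <- function(E, labels, contrast) {
  R <- ncol(E)
  rows <- list()
  for (p in contrast@contrasts) {
    d <- E[match(p[1], labels), ] - E[match(p[2], labels), ]
    rows[[length(rows) + 1L]] <- data.frame(
      component = seq_len(R),
      contrast = sprintf("%s - %s", p[1], p[2]),
      observed = as.numeric(d))
  }
  if (length(contrast@betweenDrug)) {
    p1 <- contrast@betweenDrug[[1]]
    p2 <- contrast@betweenDrug[[2]]
    d <- (E[match(p1[1], labels), ] - E[match(p1[2], labels), ]) -
         (E[match(p2[1], labels), ] - E[match(p2[2], labels), ])
    rows[[length(rows) + 1L]] <- data.frame(
      component = seq_len(R),
      contrast = sprintf("(%s - %s) - (%s - %s)", p1[1], p1[2], p2[1], p2[2]),
      observed = as.numeric(d))
  }
  do.call(rbind, rows)
}

#' Fixed-factor permutation test on condition loadings
#'
#' Tests pre-vs-post condition-loading differences of each component against
#' an empirical null built by permuting the subject/condition slabs and
#' refitting only the subject and condition loadings (the space, frequency
#' and time factors stay frozen at the master's values).  The observed
#' statistic per component r and contrast (post, pre) is
#' \code{E[post, r] - E[pre, r]} read from the canonical master; the
#' between-drug contrast is the difference of the two (post - pre)
#' differences.  Two-tailed p-values use the add-one permutation convention
#' \code{p = (1 + #(|null| >= |d|)) / (nPerm + 1)}; the decision flags values
#' outside the empirical 2.5\%/97.5\% null quantiles (ties resolved toward
#' non-rejection).
#'
#' The default scheme permutes condition labels within each subject, the
#' exchangeable-block scheme under the no-effect null; \code{scheme="joint"}
#' shuffles all S*C slab positions jointly (which mixes between-subject
#' variability into the null and is conservative when subjects differ).
#'
#' @param tensor a \linkS4class{Tensor5D}.
#' @param master canonical \linkS4class{CPModel} of \code{tensor}.
#' @param contrast a \linkS4class{ContrastModel} matching the tensor's
#'   condition labels.
#' @param nPerm number of permutations (default 1000; a warning is issued
#'   below 40, where 2.5\% tail quantiles are undefined).
#' @param seed integer seed; the test is fully reproducible given it.
#' @param scheme "within_subject" (default) or "joint".
#' @param maxRefitIter maximum refit sweeps per permutation (default 100).
#' @return a \linkS4class{PermutationResult}.
#' @export
permutationTest <- function(tensor, master, contrast, nPerm = 1000L,
                            seed = 1L, scheme = c("within_subject", "joint"),
                            maxRefitIter = 100L) {
  scheme <- match.arg(scheme)
  stopifnot(is(tensor, "Tensor5D"), is(contrast, "ContrastModel"))
  if (master@normalization != "canonical")
    stop("master model must be in canonical form")
  labs <- tensor@conditionLabels
  if (!setequal(labs, contrast@conditionLabels))
    stop("tensor condition labels do not match the contrast model")
  nPerm <- as.integer(nPerm)
  if (nPerm < 40L)
    warning("nPerm < 40: 2.5% tail quantiles are undefined at this resolution")
  W <- tensor@values
  d <- dim(W)
  S <- d[4]; C <- d[5]
  U <- master@factors
  obs <- contrastStatistics(U[[5]], labs, contrast)
  G <- projectSlabLoadings(W, U[[1]], U[[2]], U[[3]])
  P <- crossprod(U[[1]]) * crossprod(U[[2]]) * crossprod(U[[3]])
  R <- master@rank
  defs <- statDefs(labs, contrast)
  Gm <- matrix(G, S * C, R)                 # rows = slab positions
  nullMat <- matrix(NA_real_, nPerm, nrow(obs))
  set.seed(seed)
  for (b in seq_len(nPerm)) {
    idx <- if (scheme == "joint") sample.int(S * C)
           else withinSubjectPerm(S, C)
    Gp <- array(Gm[idx, ], c(S, C, R))
    rf <- refitFromG(Gp, P, U[[4]], U[[5]], maxIter = maxRefitIter)
    Eb <- normalizeDE(rf$D, rf$E)$E
    nullMat[b, ] <- evalStats(Eb, defs)
  }
  p <- vapply(seq_len(nrow(obs)), function(j)
    (1 + sum(abs(nullMat[, j]) >= abs(obs$observed[j]))) / (nPerm + 1),
    numeric(1))
  qlo <- apply(nullMat, 2L, quantile, probs = 0.025, type = 1, names = FALSE)
  qhi <- apply(nullMat, 2L, quantile, probs = 0.975, type = 1, names = FALSE)
  decision <- obs$observed < qlo | obs$observed > qhi
  tab <- cbind(obs, p = p, decision = decision)
  rownames(tab) <- NULL
  new("PermutationResult", table = tab, null = nullMat, nPerm = nPerm,
      seed = as.integer(seed), scheme = scheme)
}
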