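## Accessors and show methods.

#' @rdname accessors
#' @param object,x a tensoreeg object.
#' @export
setGeneric("tensorValues", function(x) standardGeneric("tensorValues"))

#' @rdname accessors
#' @export
setGeneric("factorMatrices", function(x) standardGeneric("factorMatrices"))

#' @rdname accessors
#' @export
setGeneric("modelRank", function(x) standardGeneric("modelRank"))

#' @rdname accessors
#' @export
setGeneric("fitPercent", function(x) standardGeneric("fitPercent"))

#' @rdname accessors
#' @export
setGeneric("conditionLabels", function(x) standardGeneric("conditionLabels"))

#' @rdname accessors
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))

#' @rdname accessors
#' @export
setGeneric("nullSamples", function(x) standardGeneric("nullSamples"))

#' Accessors
#'
#' Read the array of a tensor, the factor matrices, rank and fit of a CP
#' model, condition labels, and the summary table or null samples of a
#' permutation result.
#'
#' @return the corresponding slot value.
#' @name accessors
#' @aliases tensorValues factorMatrices modelRank fitPercent conditionLabels
#'   resultTable nullSamples
NULL

#' @rdname accessors
#' @export
setMethod("tensorValues", "Tensor5D", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("tensorValues", "TFRTensor", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("tensorValues", "TrialTFR", function(x) x@power)
#' @rdname accessors
#' @export
setMethod("tensorValues", "EpochSet", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("factorMatrices", "CPModel", function(x) x@factors)
#' @rdname accessors
#' @export
setMethod("factorMatrices", "GroundTruth", function(x)
  list(space = x@spaceFactors, freq = x@freqFactors, time = x@timeFactors,
       subject = x@subjectLoadings, condition = x@conditionLoadings))
#' @rdname accessors
#' @export
setMethod("modelRank", "CPModel", function(x) x@rank)
#' @rdname accessors
#' @export
setMethod("fitPercent", "CPModel", function(x) x@fitPercent)
#' @rdname accessors
#' @export
setMethod("conditionLabels", "Tensor5D", function(x) x@conditionLabels)
#' @rdname accessors
#' @export
setMethod("conditionLabels", "GroundTruth", function(x) x@conditionLabels)
#' @rdname accessors
#' @export
setMethod("conditionLabels", "ContrastModel", function(x) x@conditionLabels)
#' @rdname accessors
#' @export
setMethod("resultTable", "PermutationResult", function(x) x@table)
#' @rdname accessors
#' @export
setMethod("nullSamples", "PermutationResult", function(x) x@null)

#' Condition loadings with the drug effect applied
#'
#' Returns the condition-loading matrix of a ground truth after multiplying
#' post-drug rows (labels starting "post-", placebo excluded) by the
#' per-component effect.
#'
#' @param gt a \linkS4class{GroundTruth}.
#' @return conditions x R numeric matrix.
#' @export
appliedConditionLoadings <- function(gt) {
  stopifnot(is(gt, "GroundTruth"))
  E <- gt@conditionLoadings
  post <- isPostDrug(gt@conditionLabels)
  if (any(post))
    E[post, ] <- E[post, , drop = FALSE] *
      matrix(gt@effectSpec, sum(post), length(gt@effectSpec), byrow = TRUE)
  E
}

isPostDrug <- function(labels) {
  startsWith(labels, "post-") & !grepl("placebo|baseline", labels)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nChannels, "x", object@nFreqs, "x", object@nTimes,
      "x", object@nSubjects, "x", object@nConditions,
      "| rank", object@rank, "| seed", object@seed, "\n")
  cat("  noiseSigma", object@noiseSigma, "(x signal RMS), subjectSpread",
      object@subjectSpread, "\n")
  cat("  conditions:", paste(object@conditionLabels, collapse = ", "), "\n")
  cat("  post-drug effect:", paste(object@effectSpec, collapse = ", "), "\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth with", ncol(object@spaceFactors), "components:",
      nrow(object@spaceFactors), "channels x", nrow(object@freqFactors),
      "freqs x", nrow(object@timeFactors), "times x",
      nrow(object@subjectLoadings), "subjects x",
      nrow(object@conditionLoadings), "conditions\n")
  pk <- object@freqs[apply(object@freqFactors, 2, which.max)]
  cat("  spectral peaks (Hz):", paste(round(pk, 1), collapse = ", "), "\n")
  cat("  effect on post-drug conditions:",
      paste(object@effectSpec, collapse = ", "), "\n")
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat("EpochSet:", d[1], "trials x", d[2], "channels x", d[3], "samples @",
      object@samplingRate, "Hz,", sprintf("%.3f..%.3f s\n",
      min(object@times), max(object@times)))
})

setMethod("show", "TrialTFR", function(object) {
  d <- dim(object@power)
  cat("TrialTFR (", object@stage, "): ", d[1], " trials x ", d[2],
      " channels x ", d[3], " freqs x ", d[4], " times; ",
      sum(is.na(object@power)), " flagged entries\n", sep = "")
})

setMethod("show", "TFRTensor", function(object) {
  d <- dim(object@values)
  cat("TFRTensor", paste(d, collapse = " x "), "| subject", object@subject,
      "| condition", object@condition, "|", object@nTrials, "trials |",
      object@nUndefined, "undefined bins\n")
})

setMethod("show", "Tensor5D", function(object) {
  cat("Tensor5D:", paste(dim(object@values), collapse = " x "),
      sprintf("(%s entries)\n",
              format(prod(dim(object@values)), big.mark = ",")))
  cat("  conditions:", paste(object@conditionLabels, collapse = ", "), "\n")
})

setMethod("show", "CPModel", function(object) {
  cat("CPModel: rank", object@rank, "|",
      paste(vapply(object@factors, nrow, integer(1)), collapse = " x "),
      "| fit", sprintf("%.2f%%", object@fitPercent),
      "|", object@iterations, "sweeps |",
      if (object@converged) "converged" else "NOT converged",
      "|", object@normalization, "\n")
})

setMethod("show", "ContrastModel", function(object) {
  cat("ContrastModel", object@modelId, "- conditions:",
      paste(object@conditionLabels, collapse = ", "), "\n")
  for (p in object@contrasts)
    cat("  contrast:", p[1], "-", p[2], "\n")
  if (length(object@betweenDrug))
    cat("  between:", sprintf("(%s - %s) - (%s - %s)\n",
        object@betweenDrug[[1]][1], object@betweenDrug[[1]][2],
        object@betweenDrug[[2]][1], object@betweenDrug[[2]][2]))
})

setMethod("show", "PermutationResult", function(object) {
  cat("PermutationResult:", object@nPerm, "permutations, scheme",
      object@scheme, ", seed", object@seed, "\n")
  print(object@table, digits = 4)
})
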