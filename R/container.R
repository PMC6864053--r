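## HDF5 study container: one self-describing file holding epochs, TFR
## tensors, five-way tensors, CP models, permutation results and (for
## synthetic runs) the ground truth.  Axis labels are stored next to every
## dataset and every stochastic product records its seed.

SCHEMA_VERSION <- 1L

#' Study container handle
#'
#' Thin handle on the HDF5 file that stores all pipeline products under the
#' layout \code{/epochs/<subject>/<condition>}, \code{/tfr/<subject>/<condition>},
#' \code{/tensor5d/<name>}, \code{/models/<name>}, \code{/permtest/<name>},
#' \code{/ground_truth} and \code{/meta} (stage hashes, seeds).
#'
#' @slot path path of the HDF5 file.
#' @exportClass StudyContainer
setClass("StudyContainer", representation(path = "character"))

#' Open or create a study container
#'
#' @param path HDF5 file path.
#' @param create create the file (with the current schema version) if absent.
#' @return a \linkS4class{StudyContainer}.
#' @export
studyContainer <- function(path, create = !file.exists(path)) {
  if (create && !file.exists(path)) {
    rhdf5::h5createFile(path)
    fid <- rhdf5::H5Fopen(path)
    rhdf5::h5writeAttribute(SCHEMA_VERSION, fid, "schema_version")
    rhdf5::H5Fclose(fid)
  }
  x <- new("StudyContainer", path = path)
  validateContainer(x)
  x
}

#' Validate a container's schema
#'
#' Refuses files without the expected schema-version attribute.
#'
#' @param x a \linkS4class{StudyContainer}.
#' @return invisibly TRUE.
#' @export
validateContainer <- function(x) {
  if (!file.exists(x@path)) stop("no such container: ", x@path)
  at <- rhdf5::h5readAttributes(x@path, "/")
  v <- at[["schema_version"]]
  if (is.null(v) || as.integer(v) != SCHEMA_VERSION)
    stop("not a tensoreeg study container (schema_version ",
         if (is.null(v)) "missing" else v, ", expected ", SCHEMA_VERSION, ")")
  invisible(TRUE)
}

h5exists <- function(x, name) {
  ls <- rhdf5::h5ls(x@path)
  full <- file.path(ifelse(ls$group == "/", "", ls$group), ls$name)
  paste0("/", sub("^/+", "", name)) %in% paste0("/", sub("^/+", "", full))
}

## Overwrite-safe dataset write (HDF5 datasets cannot be resized in place).
h5overwrite <- function(x, name, value) {
  if (h5exists(x, name)) rhdf5::h5delete(x@path, name)
  rhdf5::h5write(value, x@path, name)
}

ensureGroup <- function(x, name) {
  parts <- strsplit(sub("^/", "", name), "/")[[1]]
  cur <- ""
  for (p in parts) {
    cur <- paste0(cur, "/", p)
    if (!h5exists(x, cur))
      rhdf5::h5createGroup(x@path, cur)
  }
  invisible(cur)
}

writeScalar <- function(x, name, value) h5overwrite(x, name, value)

readScalar <- function(x, name) {
  v <- rhdf5::h5read(x@path, name)
  if (is.array(v)) v <- as.vector(v)
  v
}

#' Write / read epochs
#'
#' @param x a \linkS4class{StudyContainer}.
#' @param epochs an \linkS4class{EpochSet}.
#' @param subject,condition cell identifiers.
#' @return \code{readEpochs} returns an \linkS4class{EpochSet}.
#' @rdname containerEpochs
#' @export
writeEpochs <- function(x, epochs, subject, condition) {
  g <- sprintf("/epochs/%s/%s", subject, condition)
  ensureGroup(x, g)
  h5overwrite(x, paste0(g, "/data"), epochs@data)
  writeScalar(x, paste0(g, "/sampling_rate"), epochs@samplingRate)
  writeScalar(x, paste0(g, "/times"), epochs@times)
  writeScalar(x, paste0(g, "/channels"), epochs@channels)
  invisible(x)
}

#' @rdname containerEpochs
#' @export
readEpochs <- function(x, subject, condition) {
  g <- sprintf("/epochs/%s/%s", subject, condition)
  if (!h5exists(x, g)) stop("no epochs for ", subject, "/", condition)
  epochSet(rhdf5::h5read(x@path, paste0(g, "/data")),
           samplingRate = readScalar(x, paste0(g, "/sampling_rate")),
           times = readScalar(x, paste0(g, "/times")),
           channels = readScalar(x, paste0(g, "/channels")))
}

#' Write / read per-cell TFR tensors
#'
#' @param x a \linkS4class{StudyContainer}.
#' @param tt a \linkS4class{TFRTensor}.
#' @return \code{readTFRTensor} returns a \linkS4class{TFRTensor};
#'   \code{readTFRStore} a nested list \code{store[[subject]][[condition]]}.
#' @rdname containerTFR
#' @export
writeTFRTensor <- function(x, tt) {
  g <- sprintf("/tfr/%s/%s", tt@subject, tt@condition)
  ensureGroup(x, g)
  vals <- tt@values
  vals[is.na(vals)] <- NA_real_
  h5overwrite(x, paste0(g, "/values"), vals)
  writeScalar(x, paste0(g, "/channels"), tt@channels)
  writeScalar(x, paste0(g, "/freqs"), tt@freqs)
  writeScalar(x, paste0(g, "/times"), tt@times)
  writeScalar(x, paste0(g, "/n_trials"), tt@nTrials)
  invisible(x)
}

#' @rdname containerTFR
#' @param subject,condition cell identifiers.
#' @export
readTFRTensor <- function(x, subject, condition) {
  g <- sprintf("/tfr/%s/%s", subject, condition)
  if (!h5exists(x, g)) stop("no TFR tensor for ", subject, "/", condition)
  vals <- rhdf5::h5read(x@path, paste0(g, "/values"))
  new("TFRTensor", values = vals,
      channels = readScalar(x, paste0(g, "/channels")),
      freqs = readScalar(x, paste0(g, "/freqs")),
      times = readScalar(x, paste0(g, "/times")),
      subject = subject, condition = condition,
      nTrials = as.integer(readScalar(x, paste0(g, "/n_trials"))),
      nUndefined = as.integer(sum(!is.finite(vals))))
}

#' @rdname containerTFR
#' @export
readTFRStore <- function(x) {
  ls <- rhdf5::h5ls(x@path)
  subj <- ls$name[ls$group == "/tfr"]
  if (!length(subj)) stop("container holds no /tfr group")
  out <- lapply(subj, function(s) {
    conds <- ls$name[ls$group == paste0("/tfr/", s)]
    cells <- lapply(conds, function(co) readTFRTensor(x, s, co))
    names(cells) <- conds
    cells
  })
  names(out) <- subj
  out
}

#' Write / read a five-way tensor
#'
#' @param x a \linkS4class{StudyContainer}.
#' @param tensor a \linkS4class{Tensor5D}.
#' @param name dataset name under /tensor5d.
#' @return \code{readTensor5D} returns a \linkS4class{Tensor5D}.
#' @rdname containerTensor5D
#' @export
writeTensor5D <- function(x, tensor, name) {
  g <- sprintf("/tensor5d/%s", name)
  ensureGroup(x, g)
  h5overwrite(x, paste0(g, "/values"), tensor@values)
  writeScalar(x, paste0(g, "/channels"), tensor@channels)
  writeScalar(x, paste0(g, "/freqs"), tensor@freqs)
  writeScalar(x, paste0(g, "/times"), tensor@times)
  writeScalar(x, paste0(g, "/subjects"), tensor@subjects)
  writeScalar(x, paste0(g, "/conditions"), tensor@conditionLabels)
  invisible(x)
}

#' @rdname containerTensor5D
#' @export
readTensor5D <- function(x, name) {
  g <- sprintf("/tensor5d/%s", name)
  if (!h5exists(x, g)) stop("no tensor5d dataset '", name, "'")
  tensor5D(rhdf5::h5read(x@path, paste0(g, "/values")),
           channels = readScalar(x, paste0(g, "/channels")),
           freqs = readScalar(x, paste0(g, "/freqs")),
           times = readScalar(x, paste0(g, "/times")),
           subjects = readScalar(x, paste0(g, "/subjects")),
           conditionLabels = readScalar(x, paste0(g, "/conditions")))
}

#' Write / read a CP model
#'
#' @param x a \linkS4class{StudyContainer}.
#' @param model a \linkS4class{CPModel}.
#' @param name model name under /models.
#' @param seed seed recorded with the model.
#' @return \code{readModel} returns a \linkS4class{CPModel}.
#' @rdname containerModel
#' @export
writeModel <- function(x, model, name, seed = NA_integer_) {
  g <- sprintf("/models/%s", name)
  ensureGroup(x, g)
  for (m in seq_along(model@factors))
    h5overwrite(x, sprintf("%s/mode%d", g, m), model@factors[[m]])
  writeScalar(x, paste0(g, "/rank"), model@rank)
  writeScalar(x, paste0(g, "/fit_percent"), model@fitPercent)
  writeScalar(x, paste0(g, "/iterations"), model@iterations)
  writeScalar(x, paste0(g, "/converged"), as.integer(model@converged))
  writeScalar(x, paste0(g, "/normalization"), model@normalization)
  writeScalar(x, paste0(g, "/mode_names"), model@modeNames)
  writeScalar(x, paste0(g, "/seed"), as.integer(seed))
  invisible(x)
}

#' @rdname containerModel
#' @export
readModel <- function(x, name) {
  g <- sprintf("/models/%s", name)
  if (!h5exists(x, g)) stop("no model '", name, "'")
  modeNames <- readScalar(x, paste0(g, "/mode_names"))
  factors <- lapply(seq_along(modeNames), function(m)
    rhdf5::h5read(x@path, sprintf("%s/mode%d", g, m)))
  new("CPModel", factors = factors,
      rank = as.integer(readScalar(x, paste0(g, "/rank"))),
      fitPercent = as.numeric(readScalar(x, paste0(g, "/fit_percent"))),
      iterations = as.integer(readScalar(x, paste0(g, "/iterations"))),
      converged = as.logical(readScalar(x, paste0(g, "/converged"))),
      normalization = readScalar(x, paste0(g, "/normalization")),
      modeNames = modeNames)
}

#' Write / read a permutation result
#'
#' @param x a \linkS4class{StudyContainer}.
#' @param res a \linkS4class{PermutationResult}.
#' @param name result name under /permtest.
#' @return \code{readPermResult} returns a \linkS4class{PermutationResult}.
#' @rdname containerPerm
#' @export
writePermResult <- function(x, res, name) {
  g <- sprintf("/permtest/%s", name)
  ensureGroup(x, g)
  tab <- res@table
  writeScalar(x, paste0(g, "/component"), tab$component)
  writeScalar(x, paste0(g, "/contrast"), tab$contrast)
  writeScalar(x, paste0(g, "/observed"), tab$observed)
  writeScalar(x, paste0(g, "/p"), tab$p)
  writeScalar(x, paste0(g, "/decision"), as.integer(tab$decision))
  h5overwrite(x, paste0(g, "/null"), res@null)
  writeScalar(x, paste0(g, "/n_perm"), res@nPerm)
  writeScalar(x, paste0(g, "/seed"), res@seed)
  writeScalar(x, paste0(g, "/scheme"), res@scheme)
  invisible(x)
}

#' @rdname containerPerm
#' @export
readPermResult <- function(x, name) {
  g <- sprintf("/permtest/%s", name)
  if (!h5exists(x, g)) stop("no permutation result '", name, "'")
  tab <- data.frame(
    component = as.integer(readScalar(x, paste0(g, "/component"))),
    contrast = readScalar(x, paste0(g, "/contrast")),
    observed = as.numeric(readScalar(x, paste0(g, "/observed"))),
    p = as.numeric(readScalar(x, paste0(g, "/p"))),
    decision = as.logical(readScalar(x, paste0(g, "/decision"))))
  new("PermutationResult", table = tab,
      null = as.matrix(rhdf5::h5read(x@path, paste0(g, "/null"))),
      nPerm = as.integer(readScalar(x, paste0(g, "/n_perm"))),
      seed = as.integer(readScalar(x, paste0(g, "/seed"))),
      scheme = readScalar(x, paste0(g, "/scheme")))
}

#' Write / read a ground truth
#'
#' @param x a \linkS4class{StudyContainer}.
#' @param gt a \linkS4class{GroundTruth}.
#' @return \code{readGroundTruth} returns a \linkS4class{GroundTruth}.
#' @rdname containerGT
#' @export
writeGroundTruth <- function(x, gt) {
  g <- "/ground_truth"
  ensureGroup(x, g)
  h5overwrite(x, paste0(g, "/space"), gt@spaceFactors)
  h5overwrite(x, paste0(g, "/freq"), gt@freqFactors)
  h5overwrite(x, paste0(g, "/time"), gt@timeFactors)
  h5overwrite(x, paste0(g, "/subject"), gt@subjectLoadings)
  h5overwrite(x, paste0(g, "/condition"), gt@conditionLoadings)
  writeScalar(x, paste0(g, "/condition_labels"), gt@conditionLabels)
  writeScalar(x, paste0(g, "/effect_spec"), gt@effectSpec)
  writeScalar(x, paste0(g, "/noise_sigma"), gt@noiseSigma)
  writeScalar(x, paste0(g, "/channels"), gt@channels)
  writeScalar(x, paste0(g, "/freqs"), gt@freqs)
  writeScalar(x, paste0(g, "/times"), gt@times)
  writeScalar(x, paste0(g, "/seed"),
              as.integer(gt@metadata$seed %||% NA_integer_))
  invisible(x)
}

#' @rdname containerGT
#' @export
readGroundTruth <- function(x) {
  g <- "/ground_truth"
  if (!h5exists(x, g)) stop("container holds no ground truth")
  new("GroundTruth",
      spaceFactors = rhdf5::h5read(x@path, paste0(g, "/space")),
      freqFactors = rhdf5::h5read(x@path, paste0(g, "/freq")),
      timeFactors = rhdf5::h5read(x@path, paste0(g, "/time")),
      subjectLoadings = rhdf5::h5read(x@path, paste0(g, "/subject")),
      conditionLoadings = rhdf5::h5read(x@path, paste0(g, "/condition")),
      conditionLabels = readScalar(x, paste0(g, "/condition_labels")),
      effectSpec = as.numeric(readScalar(x, paste0(g, "/effect_spec"))),
      noiseSigma = as.numeric(readScalar(x, paste0(g, "/noise_sigma"))),
      channels = readScalar(x, paste0(g, "/channels")),
      freqs = as.numeric(readScalar(x, paste0(g, "/freqs"))),
      times = as.numeric(readScalar(x, paste0(g, "/times"))),
      metadata = list(seed = as.integer(readScalar(x, paste0(g, "/seed")))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

setMethod("show", "StudyContainer", function(object) {
  cat("StudyContainer:", object@path, "\n")
  ls <- rhdf5::h5ls(object@path)
  groups <- unique(sub("^/([^/]+).*", "\\1", ls$group[ls$group != "/"]))
  cat("  groups:", paste(sort(unique(c(groups,
      ls$name[ls$group == "/" & ls$otype == "H5I_GROUP"]))),
      collapse = ", "), "\n")
})
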