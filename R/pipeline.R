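## Umbrella pipeline: simulate -> (epochs/tfr demo) -> decompose -> permtest,
## with per-stage config hashing so unchanged stages are not recomputed, and
## CSV export of human-facing tables.

configHash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(x, tmp, version = 2)  # version-stable serialisation
  unname(tools::md5sum(tmp))
}

stageUpToDate <- function(container, stage, hash) {
  key <- sprintf("/meta/hash_%s", stage)
  h5exists(container, key) && identical(readScalar(container, key), hash)
}

recordStage <- function(container, stage, hash) {
  ensureGroup(container, "/meta")
  key <- sprintf("/meta/hash_%s", stage)
  if (h5exists(container, key)) rhdf5::h5delete(container@path, key)
  writeScalar(container, key, hash)
}

knownKeys <- function(cfg, allowed, where) {
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config key(s) in ", where, ": ",
         paste(unknown, collapse = ", "))
}

#' Run the full pipeline
#'
#' Executes the requested stages in order — simulate (ground truth and
#' five-way tensor; optionally demo epochs and their TFR), decompose (master
#' model, optional rank sweep) and permtest — writing every product into the
#' study container.  A stage whose configuration hash matches the one stored
#' in the container is skipped.  A stage failure halts the run with the
#' failing stage named; earlier outputs are preserved.
#'
#' @param config either a YAML file path or a nested list with keys
#'   \code{out} (container path), \code{seed}, \code{sim} (arguments of
#'   \code{\link{simConfig}}), optional \code{epochs}
#'   (\code{enabled}, \code{nTrials}), \code{decompose} (\code{rank},
#'   \code{nRestarts}, \code{maxIterations}, \code{tol}), optional
#'   \code{sweep} (\code{enabled}, \code{ranks}) and \code{permtest}
#'   (\code{model}, \code{nPerm}, \code{scheme}).  Unknown keys are rejected.
#' @param quiet suppress progress messages.
#' @return the \linkS4class{StudyContainer}, invisibly.
#' @export
runPipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  knownKeys(config, c("out", "seed", "sim", "epochs", "decompose", "sweep",
                      "permtest"), "top level")
  if (is.null(config$out)) stop("config$out (container path) is required")
  seed <- as.integer(config$seed %||% 1L)
  container <- studyContainer(config$out)
  log <- function(stage, msg, t0) {
    if (!quiet)
      message(sprintf("[%s] %s (seed %d, %.2fs)", stage, msg, seed,
                      as.numeric(Sys.time()) - t0))
  }
  runStage <- function(stage, cfg, fun) {
    hash <- configHash(list(cfg = cfg, seed = seed))
    if (stageUpToDate(container, stage, hash)) {
      log(stage, "up to date, skipped", as.numeric(Sys.time()))
      return(invisible(NULL))
    }
    t0 <- as.numeric(Sys.time())
    tryCatch(fun(), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
    recordStage(container, stage, hash)
    log(stage, "done", t0)
  }

  simArgs <- config$sim %||% list()
  knownKeys(simArgs, names(formals(simConfig)), "sim")
  simArgs$seed <- simArgs$seed %||% seed
  scfg <- do.call(simConfig, simArgs)
  gt <- NULL
  runStage("simulate", simArgs, function() {
    gt <<- makeGroundTruth(scfg)
    writeGroundTruth(container, gt)
    writeTensor5D(container, synthTensor5D(gt, scfg), "sim")
  })

  epo <- config$epochs %||% list(enabled = FALSE)
  knownKeys(epo, c("enabled", "nTrials", "subject", "condition"), "epochs")
  if (isTRUE(epo$enabled)) {
    runStage("tfr", epo, function() {
      if (is.null(gt)) gt <<- readGroundTruth(container)
      ep <- synthEpochs(gt, nTrials = epo$nTrials %||% 10L, seed = seed,
                        subject = epo$subject %||% 1L,
                        condition = epo$condition %||% 1L)
      subjectId <- sprintf("S%02d", epo$subject %||% 1L)
      condId <- gt@conditionLabels[epo$condition %||% 1L]
      writeEpochs(container, ep, subjectId, condId)
      tt <- tfrPipeline(ep, tfrConfig(), subject = subjectId,
                        condition = condId, undefined = "keep")
      writeTFRTensor(container, tt)
    })
  }

  dec <- config$decompose %||% list()
  knownKeys(dec, c("rank", "nRestarts", "maxIterations", "tol"), "decompose")
  dcfg <- decomposeConfig(rank = dec$rank %||% 3L,
                          nRestarts = dec$nRestarts %||% 4L,
                          maxIterations = dec$maxIterations %||% 500L,
                          tol = dec$tol %||% 1e-8, seed = seed)
  runStage("decompose", dec, function() {
    tensor <- readTensor5D(container, "sim")
    writeModel(container, masterDecomposition(tensor, dcfg), "master",
               seed = seed)
  })

  sw <- config$sweep %||% list(enabled = FALSE)
  knownKeys(sw, c("enabled", "ranks"), "sweep")
  if (isTRUE(sw$enabled)) {
    runStage("sweep", sw, function() {
      tensor <- readTensor5D(container, "sim")
      tab <- sweepRank(tensor, ranks = sw$ranks %||% 1:8, cfg = dcfg)
      ensureGroup(container, "/sweep")
      for (cl in names(tab)) {
        key <- paste0("/sweep/", cl)
        if (h5exists(container, key)) rhdf5::h5delete(container@path, key)
        writeScalar(container, key, tab[[cl]])
      }
    })
  }

  pt <- config$permtest %||% list()
  knownKeys(pt, c("model", "nPerm", "scheme"), "permtest")
  runStage("permtest", pt, function() {
    tensor <- readTensor5D(container, "sim")
    master <- readModel(container, "master")
    cm <- contrastModel(pt$model %||% 2L,
                        conditionLabels = tensor@conditionLabels)
    res <- permutationTest(tensor, master, cm,
                           nPerm = pt$nPerm %||% 1000L, seed = seed,
                           scheme = pt$scheme %||% "within_subject")
    writePermResult(container, res, sprintf("model%d", cm@modelId))
  })

  invisible(container)
}

fullPrecision <- function(df) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- vapply(df[[j]], function(v)
        formatC(v, digits = 17, format = "g"), character(1))
  df
}

#' Export container tables as CSV
#'
#' Writes the rank-sweep table, the factor matrices of every stored model
#' (one file per mode, labelled rows) and the permutation summaries as CSV
#' files with full floating-point precision.
#'
#' @param container a \linkS4class{StudyContainer}.
#' @param outDir output directory (created if needed).
#' @param groups which container groups to export (default: all of sweep,
#'   models, permtest that exist).
#' @return character vector of files written, invisibly.
#' @export
exportTables <- function(container, outDir,
                         groups = c("sweep", "models", "permtest")) {
  validateContainer(container)
  ls <- rhdf5::h5ls(container@path)
  present <- unique(c(sub("^/([^/]*).*$", "\\1", ls$group[ls$group != "/"]),
                      ls$name[ls$group == "/" & ls$otype == "H5I_GROUP"]))
  missing <- setdiff(groups, present)
  requested <- intersect(groups, present)
  if (!length(requested))
    stop("none of the requested groups exist; available: ",
         paste(sort(present), collapse = ", "))
  if (length(missing) && !setequal(groups, c("sweep", "models", "permtest")))
    stop("group(s) ", paste(missing, collapse = ", "),
         " not in container; available: ", paste(sort(present), collapse = ", "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wr <- function(df, fname) {
    path <- file.path(outDir, fname)
    utils::write.csv(fullPrecision(df), path, row.names = FALSE, quote = TRUE)
    files <<- c(files, path)
  }
  if ("sweep" %in% requested) {
    cols <- ls$name[ls$group == "/sweep"]
    tab <- as.data.frame(lapply(cols, function(cl)
      readScalar(container, paste0("/sweep/", cl))))
    names(tab) <- cols
    wr(tab[c("rank", "explained_variance", "corcondia")], "rank_sweep.csv")
  }
  if ("models" %in% requested) {
    for (nm in ls$name[ls$group == "/models"]) {
      model <- readModel(container, nm)
      for (m in seq_along(model@factors)) {
        fm <- as.data.frame(model@factors[[m]])
        names(fm) <- paste0("component", seq_len(model@rank))
        fm <- cbind(index = seq_len(nrow(fm)), fm)
        wr(fm, sprintf("model_%s_%s.csv", nm, model@modeNames[m]))
      }
    }
  }
  if ("permtest" %in% requested) {
    for (nm in ls$name[ls$group == "/permtest"])
      wr(readPermResult(container, nm)@table, sprintf("permtest_%s.csv", nm))
  }
  invisible(files)
}
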