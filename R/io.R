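# Directory-per-class image tree reader/writer (PlantVillage layout:
# <root>/<class_name>/<image>.png). Class names are sorted
# lexicographically and mapped to contiguous 0-based integer ids.

#' Read a directory-per-class image tree
#'
#' @param root directory whose sub-directories are classes containing PNG
#'   images.
#' @return an [ImageSet-class]; labels follow the lexicographic order of
#'   the class directory names.
#' @export
readImageDirectory <- function(root) {
  if (!dir.exists(root)) stop(sprintf("dataset directory '%s' not found", root))
  classDirs <- sort(list.dirs(root, recursive = FALSE))
  if (!length(classDirs)) stop("no class sub-directories found")
  images <- list(); labels <- integer(0); ids <- character(0)
  for (ci in seq_along(classDirs)) {
    files <- sort(list.files(classDirs[ci], pattern = "\\.png$",
                             full.names = TRUE, ignore.case = TRUE))
    for (f in files) {
      im <- png::readPNG(f)
      if (length(dim(im)) == 2L)
        im <- array(rep(im, 3L), c(dim(im), 3L))
      if (dim(im)[3] == 4L) im <- im[, , 1:3, drop = FALSE]
      images[[length(images) + 1L]] <- im
      labels <- c(labels, ci - 1L)
      ids <- c(ids, f)
    }
  }
  new("ImageSet", images = images, labels = labels,
      classNames = basename(classDirs), sourceIds = ids)
}

#' Write an ImageSet as a directory-per-class PNG tree
#'
#' @param dataset an [ImageSet-class].
#' @param root output directory (created if missing).
#' @return \code{root}, invisibly.
#' @export
writeImageDirectory <- function(dataset, root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  counters <- integer(length(dataset@classNames))
  for (i in seq_along(dataset@images)) {
    cls <- dataset@labels[i] + 1L
    dir <- file.path(root, dataset@classNames[cls])
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    counters[cls] <- counters[cls] + 1L
    png::writePNG(dataset@images[[i]],
                  file.path(dir, sprintf("img_%05d.png", counters[cls])))
  }
  invisible(root)
}

#' Save an encoder checkpoint with a JSON sidecar
#'
#' Writes the serialized encoder weights plus a JSON sidecar recording the
#' training configuration, a dataset fingerprint, and the final training
#' loss. The projection head may be saved for inspection but is never
#' loaded in phase 2.
#'
#' @param encoder a [ConvEncoder-class].
#' @param path checkpoint file path (RDS).
#' @param config the [TrainConfig-class] used for training.
#' @param datasetFingerprint character id of the training data.
#' @param finalLoss last recorded mean training loss.
#' @param head optional [ProjectionHead-class], stored alongside.
#' @return \code{path}, invisibly.
#' @export
saveCheckpoint <- function(encoder, path, config = NULL,
                           datasetFingerprint = "", finalLoss = NA_real_,
                           head = NULL) {
  saveRDS(list(encoder = encoder, head = head), path)
  sidecar <- list(
    inputSize = encoder@inputSize,
    channels = encoder@channels,
    featureDim = encoder@featureDim,
    datasetFingerprint = datasetFingerprint,
    finalLoss = finalLoss
  )
  if (!is.null(config))
    sidecar$train <- list(
      batchSize = config@batchSize, tau = config@tau,
      epochs = config@epochs, baseLR = config@baseLR,
      lrDecay = config@lrDecay, momentum = config@momentum,
      weightDecay = config@weightDecay, warmupEpochs = config@warmupEpochs,
      schedule = config@schedule, seed = config@seed,
      augment = paste(config@augment@ops, collapse = ""))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load an encoder checkpoint
#'
#' @param path checkpoint file written by [saveCheckpoint()].
#' @return the frozen [ConvEncoder-class] (the projection head, even if
#'   stored, is not returned: phase 2 never uses it).
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) stop(sprintf("checkpoint '%s' not found", path))
  freezeEncoder(readRDS(path)$encoder)
}
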