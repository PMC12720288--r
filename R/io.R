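#' Save / load cohorts, cases and checkpoints
#'
#' Cohorts and model checkpoints are serialised as RDS with a versioned
#' metadata wrapper; magnitude images and masks can additionally be exported
#' as NIfTI for visualisation when the RNifti package is available. Run logs
#' are appended as JSON lines.
#'
#' @param object any package object (cohort, template, modulator, prior net)
#' @param path file path
#' @param meta named list merged into the stored metadata
#' @return `path`, invisibly
#' @export
save_checkpoint <- function(object, path, meta = list()) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  wrapper <- list(
    format_version = 1L,
    package_version = as.character(utils::packageVersion("kinr")),
    class = class(object)[1L],
    meta = meta,
    object = object
  )
  saveRDS(wrapper, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  wrapper <- readRDS(path)
  if (is.null(wrapper$format_version)) stop("not a kinr checkpoint: ", path)
  wrapper$object
}

#' Export a subject's magnitude volumes and masks as NIfTI
#'
#' @param subject one element of [generate_cohort()]
#' @param dir output directory
#' @return written file paths, invisibly
#' @export
write_subject_nifti <- function(subject, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("RNifti is required for NIfTI export")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (b in seq_along(subject$bins)) {
    p <- file.path(dir, sprintf("magnitude_bin%02d.nii", b - 1L))
    img <- RNifti::asNifti(magnitude(subject$bins[[b]]),
                           pixdim = subject$spacing_mm)
    RNifti::writeNifti(img, p)
    paths <- c(paths, p)
  }
  for (nm in names(subject$masks0)) {
    p <- file.path(dir, sprintf("mask_%s_bin00.nii", nm))
    RNifti::writeNifti(RNifti::asNifti(subject$masks0[[nm]] * 1,
                                       pixdim = subject$spacing_mm), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Append a record to a JSONL run log
#' @param path log file
#' @param record named list
#' @export
log_jsonl <- function(path, record) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  line <- jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA)
  cat(line, "\n", sep = "", file = path, append = TRUE)
  invisible(path)
}
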