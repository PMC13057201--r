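# Plain-text (CSV/JSON) and TIFF interchange for the pipeline's tables.

#' Write a synthetic experiment to disk
#'
#' Emits the tidy trace CSV (`session, roi_id, roi_kind, frame,
#' fluorescence, motion_flag`), the trial table, skeleton node/edge lists,
#' spine attachments, the presence table, the ground truth as JSON and —
#' when the tiff package is available — per-spine 16-bit label/intensity
#' TIFFs.
#'
#' @param experiment A `spine_experiment`.
#' @param dir Output directory (created if needed).
#' @param images Also write ROI TIFFs?
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir, images = FALSE) {
  stopifnot(inherits(experiment, "spine_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  wr(experiment_traces(experiment), "traces.csv")
  wr(experiment_trials(experiment), "trials.csv")
  wr(experiment$skeleton$nodes, "skeleton_nodes.csv")
  wr(experiment$skeleton$edges, "skeleton_edges.csv")
  wr(experiment$skeleton$attachments, "attachments.csv")
  wr(experiment$ground_truth$presence, "presence.csv")
  write_ground_truth(experiment$ground_truth, file.path(dir, "ground_truth.json"))
  if (images && !is.null(experiment$images)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      warn("tiff package unavailable; skipping ROI images")
    } else {
      for (id in names(experiment$images)) {
        write_roi_image_tiff(experiment$images[[id]],
                             file.path(dir, paste0(id, "_intensity.tif")),
                             file.path(dir, paste0(id, "_labels.tif")))
      }
    }
  }
  invisible(dir)
}

#' Ground-truth JSON round trip
#'
#' @param ground_truth A `spine_ground_truth`.
#' @param path JSON file path.
#' @return For the reader, the restored `spine_ground_truth`.
#' @export
write_ground_truth <- function(ground_truth, path) {
  stopifnot(inherits(ground_truth, "spine_ground_truth"))
  jsonlite::write_json(unclass(ground_truth), path, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::fromJSON(path)
  proto <- list(
    releases = tibble::tibble(session = integer(), spine_id = character(),
                              trial = integer(), pulse = integer(),
                              success = logical()))
  out <- lapply(names(raw), function(nm) {
    if (length(raw[[nm]]) == 0L && !is.null(proto[[nm]])) proto[[nm]]
    else tibble::as_tibble(raw[[nm]])
  })
  names(out) <- names(raw)
  structure(out, class = "spine_ground_truth")
}

#' Read tidy pipeline CSVs
#'
#' Readers for the trace, trial and presence CSV schemas written by
#' [write_experiment()] (or produced by an extraction pipeline following
#' the same layout).
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_traces_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path))
  df$motion_flag <- as.logical(df$motion_flag)
  df
}

#' @rdname read_traces_csv
#' @export
read_trials_csv <- function(path) tibble::as_tibble(utils::read.csv(path))

#' @rdname read_traces_csv
#' @export
read_presence_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path))
  df$present <- as.logical(df$present)
  df
}

#' 16-bit TIFF input/output for labelled ROI images
#'
#' Intensities are stored as 16-bit grey values (clamped at 65535), labels
#' as 16-bit integers.
#'
#' @param image A [roi_image()].
#' @param intensity_path,labels_path TIFF file paths.
#' @param roles Role table (`label`, `roi_id`, `roi_kind`) for the reader.
#' @param pixel_size Micrometres per pixel for the reader.
#' @return The reader returns a [roi_image()].
#' @export
write_roi_image_tiff <- function(image, intensity_path, labels_path) {
  if (!requireNamespace("tiff", quietly = TRUE)) abort("needs the tiff package")
  stopifnot(inherits(image, "roi_image"))
  tiff::writeTIFF(pmin(pmax(round(image$intensity), 0), 65535) / 65535,
                  intensity_path, bits.per.sample = 16L)
  tiff::writeTIFF(image$labels / 65535, labels_path, bits.per.sample = 16L)
  invisible(intensity_path)
}

#' @rdname write_roi_image_tiff
#' @export
read_roi_image_tiff <- function(intensity_path, labels_path, roles,
                                pixel_size = 0.1) {
  if (!requireNamespace("tiff", quietly = TRUE)) abort("needs the tiff package")
  intensity <- round(tiff::readTIFF(intensity_path) * 65535)
  labels <- matrix(as.integer(round(tiff::readTIFF(labels_path) * 65535)),
                   nrow = nrow(intensity))
  roi_image(intensity, labels, roles, pixel_size)
}
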