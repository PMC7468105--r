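# Reading and writing the pipeline's on-disk formats: single-channel 8-bit
# PNG/TIFF slide images, annotation CSVs (one row per annotator-label per
# object, polygons as JSON arrays of [x, y] pairs), cut-out PNGs with a
# manifest CSV, and the bundled reference composition/confusion tables.

#' Write a virtual slide as an 8-bit grayscale image
#'
#' @param slide a `virtual_slide`.
#' @param path output path ending in `.png` or `.tif`/`.tiff`.
#' @return the path, invisibly.
#' @export
write_slide <- function(slide, path) {
  img <- slide$image / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = 8L)
  } else {
    stop("unsupported slide format: .", ext)
  }
  invisible(path)
}

#' Read a virtual slide image
#'
#' @param path `.png` or `.tif`/`.tiff` file.
#' @param slide_id,cohort_id metadata to attach (defaults: file stem, NA).
#' @return a `virtual_slide` with integer grey levels 0-255.
#' @export
read_slide <- function(path, slide_id = tools::file_path_sans_ext(basename(path)),
                       cohort_id = NA_character_) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  new_virtual_slide(matrix(as.integer(round(img * 255)), nrow(img), ncol(img)),
                    slide_id, cohort_id)
}

#' Write annotation records to CSV
#'
#' One row per annotator-label per object, with the polygon serialised as
#' a JSON array of `[x, y]` pairs.
#'
#' @param records list of [annotation_record()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_annotations <- function(records, path) {
  rows <- do.call(rbind, lapply(records, function(r) {
    poly_json <- as.character(jsonlite::toJSON(unname(
      lapply(seq_len(nrow(r$polygon)), function(i) r$polygon[i, ])), digits = NA))
    data.frame(slide_id = r$slide_id, annotation_id = r$annotation_id,
               annotator_id = r$labels$annotator_id,
               is_senior = as.integer(r$labels$is_senior),
               label = r$labels$label,
               polygon = poly_json, skip_flag = as.integer(r$skip_flag),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read annotation records from CSV
#'
#' @param path CSV written by [write_annotations()] (or following the same
#'   schema).
#' @return list of [annotation_record()].
#' @export
read_annotations <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"skip_flag" %in% names(d)) d$skip_flag <- 0L
  keys <- paste(d$slide_id, d$annotation_id, sep = "\r")
  lapply(split(seq_len(nrow(d)), factor(keys, levels = unique(keys))), function(ix) {
    g <- d[ix, ]
    poly <- do.call(rbind, jsonlite::fromJSON(g$polygon[1], simplifyMatrix = FALSE))
    annotation_record(g$slide_id[1], g$annotation_id[1], poly,
                      labels = data.frame(annotator_id = g$annotator_id,
                                          label = g$label,
                                          is_senior = g$is_senior == 1L),
                      skip_flag = g$skip_flag[1] == 1L)
  })
}

#' Export cut-outs as PNGs with a manifest
#'
#' Writes each cut-out as `<slide>_<annotation>_<masked|raw>.png` and a
#' `manifest.csv` with columns `cutout_path`, `label`, `cohort`, `bbox`
#' (as `x0;y0;x1;y1`) and `masked`.
#'
#' @param cutouts list of `cutout` objects.
#' @param dir output directory (created if needed).
#' @return path of the manifest CSV, invisibly.
#' @export
write_cutouts <- function(cutouts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cutouts, function(co) {
    fn <- sprintf("%s_%s_%s.png", co$source$slide_id, co$source$annotation_id,
                  if (co$masked) "masked" else "raw")
    png::writePNG(co$image / 255, file.path(dir, fn))
    data.frame(cutout_path = fn, label = co$label,
               cohort = co$source$cohort_id,
               bbox = paste(co$bbox, collapse = ";"),
               masked = co$masked, stringsAsFactors = FALSE)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

#' Reference data-set composition bundled with the package
#'
#' Per-class specimen counts of the two-expedition Southern Ocean diatom
#' reference data set the synthetic generator is modelled on: ten taxa
#' kept by the at-least-40-per-expedition rule, the most abundant one
#' capped at 660 specimens.
#'
#' @return data frame with columns `class`, `n_total`, `n_cohort_A`
#'   (expedition ANT-XXVIII/2), `n_cohort_B` (expedition PS103).
#' @export
reference_composition <- function() {
  utils::read.csv(system.file("extdata", "reference_composition.csv",
                              package = "diatomslide"),
                  stringsAsFactors = FALSE)
}

#' Reference per-class confusion counts of the pooled initial run
#'
#' TP/FP/FN per class from a pooled-data reference run (both expeditions
#' merged, no masking, 72/18/10 split) of a diatom classifier, scored on
#' the held-out test set; the package's metrics reproduce the associated
#' per-class report from these counts.
#'
#' @return data frame with columns `class`, `tp`, `fp`, `fn`.
#' @export
reference_confusion <- function() {
  utils::read.csv(system.file("extdata", "reference_confusion.csv",
                              package = "diatomslide"),
                  stringsAsFactors = FALSE)
}
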