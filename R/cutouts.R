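# Cut-out extraction: gold-standard label resolution across annotators,
# rectangular extraction with a >= 10 px margin, optional soft background
# masking, and the class filter / cap used to assemble data sets.

#' Resolve the gold-standard label of a multi-annotator record
#'
#' If every attached label agrees, that label is returned. If labels
#' diverge, policy `"senior_wins"` returns the senior expert's label when
#' one exists and skips otherwise; policy `"unanimous_only"` skips any
#' divergent record. Records flagged for exclusion (`skip_flag`) are always
#' skipped.
#'
#' @param record an [annotation_record()] with at least one label.
#' @param policy `"senior_wins"` (default) or `"unanimous_only"`.
#' @return the resolved class label, or `NA_character_` for a skip decision.
#' @export
resolve_gold_label <- function(record, policy = c("senior_wins", "unanimous_only")) {
  policy <- match.arg(policy)
  if (nrow(record$labels) == 0) stop("record has no labels")
  if (isTRUE(record$skip_flag)) return(NA_character_)
  labs <- record$labels$label
  if (length(unique(labs)) == 1L) return(labs[[1]])
  if (policy == "unanimous_only") return(NA_character_)
  senior <- labs[as.logical(record$labels$is_senior)]
  if (length(unique(senior)) == 1L) return(senior[[1]])
  NA_character_
}

new_cutout <- function(image, mask, label, bbox, masked, source) {
  stopifnot(identical(dim(image), dim(mask)), sum(mask) >= 1)
  structure(list(image = image, mask = mask, label = label,
                 bbox = as.integer(bbox), masked = isTRUE(masked),
                 source = source),
            class = "cutout")
}

#' @export
print.cutout <- function(x, ...) {
  cat(sprintf("<cutout> %s/%s '%s': %d x %d px, %s, %d fg px\n",
              x$source$slide_id, x$source$annotation_id,
              if (is.na(x$label)) "?" else x$label,
              ncol(x$image), nrow(x$image),
              if (x$masked) "masked" else "raw", sum(x$mask)))
  invisible(x)
}

#' Extract an unmasked rectangular cut-out around an annotated object
#'
#' The cut-out bounding box is the polygon's integer bounding box expanded
#' by `margin_px` on every side and clipped to the canvas; boxes are
#' half-open, 0-based `[x0, x1) x [y0, y1)`. Image pixels are copied
#' verbatim, so neighbouring objects falling inside the box remain visible;
#' the mask covers only the focal polygon (even-odd fill rule).
#'
#' @param slide a virtual slide (or any object with an `$image` matrix and
#'   `slide_id`/`cohort_id` fields).
#' @param record an [annotation_record()].
#' @param margin_px margin in pixels (>= 0, default 10).
#' @param label optional resolved label to store; defaults to
#'   [resolve_gold_label()] with the senior-wins policy.
#' @return a `cutout` object with `masked = FALSE`.
#' @export
extract_cutout <- function(slide, record, margin_px = 10L, label = NULL) {
  stopifnot(margin_px >= 0)
  W <- ncol(slide$image); H <- nrow(slide$image)
  bb <- polygon_bbox(record$polygon)
  if (bb[3] <= 0 || bb[1] >= W || bb[4] <= 0 || bb[2] >= H) {
    stop("polygon lies fully outside the slide canvas")
  }
  ext <- c(bb[1] - margin_px, bb[2] - margin_px, bb[3] + margin_px, bb[4] + margin_px)
  ext <- c(pmax(ext[1:2], 0L), pmin(ext[3:4], c(W, H)))
  img <- slide$image[(ext[2] + 1):ext[4], (ext[1] + 1):ext[3], drop = FALSE]
  mask <- rasterize_polygon(record$polygon, ext)
  if (sum(mask) == 0) {
    # degenerate, very thin polygon: mark the pixel nearest the centroid
    cx <- min(max(round(mean(record$polygon[, 1])), ext[1]), ext[3] - 1)
    cy <- min(max(round(mean(record$polygon[, 2])), ext[2]), ext[4] - 1)
    mask[cy - ext[2] + 1, cx - ext[1] + 1] <- 1L
  }
  if (is.null(label)) label <- resolve_gold_label(record)
  new_cutout(img, mask, label, ext, masked = FALSE,
             source = list(slide_id = record$slide_id,
                           annotation_id = record$annotation_id,
                           cohort_id = slide$cohort_id %||% NA_character_))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Soft background masking of a cut-out
#'
#' Replaces the area outside the annotated object by the cut-out's
#' background grey level, with a smooth transition close to the object
#' boundary. Let `b` be the median grey over background pixels outside the
#' transition band (all background pixels if none lie farther away; the
#' median is robust against darker neighbour objects in the window) and
#' `f` the hard-masked field: the object's pixels over a constant-`b`
#' background. The output copies the object verbatim and replaces every
#' background pixel by `f` smoothed with a truncated Gaussian (sigma =
#' `transition_width_px / 2`, support truncated at two sigma). The object's
#' rim thus blends smoothly into the homogenised background, pixels farther
#' than the transition width outside the object equal `b` exactly,
#' neighbouring objects are suppressed entirely, and re-applying the
#' operator moves no pixel by more than one grey level (the transition is
#' always rebuilt from the untouched object pixels and `b`).
#'
#' @param cutout an unmasked `cutout`.
#' @param transition_width_px transition width in pixels (> 0, default 5).
#' @return the masked `cutout` (`masked = TRUE`).
#' @export
mask_background <- function(cutout, transition_width_px = 5) {
  stopifnot(inherits(cutout, "cutout"), transition_width_px > 0)
  if (isTRUE(cutout$masked)) stop("cut-out is already masked")
  bgpix <- cutout$image[cutout$mask == 0L]
  if (!length(bgpix)) {
    cutout$masked <- TRUE
    return(cutout)
  }
  sigma <- transition_width_px / 2
  ws <- smooth_matrix(cutout$mask + 0, sigma = sigma)
  far <- cutout$mask == 0L & ws <= 0
  # robust location estimate of the scene background: the median is not
  # dragged by darker neighbour objects or debris in the window
  b <- stats::median(cutout$image[if (any(far)) far else cutout$mask == 0L])
  field <- ifelse(cutout$mask == 1L, as.numeric(cutout$image), b)
  halo <- smooth_matrix(field, sigma = sigma)
  out <- ifelse(cutout$mask == 1L, as.numeric(cutout$image), halo)
  cutout$image <- matrix(as.integer(round(clip255(out))),
                         nrow = nrow(out), ncol = ncol(out))
  cutout$masked <- TRUE
  cutout
}

#' Keep classes sufficiently represented in every cohort
#'
#' @param counts matrix or data frame of per-class, per-cohort counts
#'   (rows = classes with row names, columns = cohorts).
#' @param min_per_cohort minimum count required in every cohort
#'   (default 40).
#' @return character vector of kept class names, in input order.
#' @export
filter_classes <- function(counts, min_per_cohort = 40L) {
  m <- as.matrix(counts)
  if (is.null(rownames(m))) stop("counts must have class row names")
  keep <- apply(m, 1, function(r) all(r >= min_per_cohort))
  rownames(m)[keep]
}

#' Cap one class by uniform subsampling
#'
#' Reduces the records of the named class to `min(cap, n)` by seeded uniform
#' sampling without replacement; other classes and the relative order of
#' survivors are untouched.
#'
#' @param records list of records (anything with a resolvable label).
#' @param class class label to cap.
#' @param cap maximum number of survivors (>= 0).
#' @param seed integer seed.
#' @param get_label function mapping a record to its class label; defaults
#'   to [resolve_gold_label()] for annotation records and `$label` otherwise.
#' @return the subsampled record list.
#' @export
cap_class <- function(records, class, cap, seed = 1L,
                      get_label = NULL) {
  stopifnot(cap >= 0)
  if (is.null(get_label)) {
    get_label <- function(r) {
      if (inherits(r, "annotation_record")) resolve_gold_label(r) else r$label
    }
  }
  labs <- vapply(records, function(r) {
    l <- get_label(r)
    if (is.na(l)) NA_character_ else as.character(l)
  }, "")
  in_class <- which(!is.na(labs) & labs == class)
  if (length(in_class) <= cap) return(records)
  survivors <- with_seed(seed, sort(sample(in_class, cap)))
  drop <- setdiff(in_class, survivors)
  records[-drop]
}

#' Tabulate resolved class labels per cohort
#'
#' Convenience for feeding [filter_classes()]: drops skip-flagged and
#' unresolvable records, then counts gold labels per cohort.
#'
#' @param records list of [annotation_record()].
#' @param cohorts character vector, same length, cohort of each record.
#' @param policy label-resolution policy, see [resolve_gold_label()].
#' @return class x cohort count matrix.
#' @export
count_by_cohort <- function(records, cohorts, policy = "senior_wins") {
  labs <- vapply(records, resolve_gold_label, "", policy = policy)
  ok <- !is.na(labs)
  table(factor(labs[ok]), factor(cohorts[ok]))
}
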