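# Synthetic virtual slides: a bright, noisy 8-bit background (0 = black,
# 255 = white) on which darker diatom-like objects and debris are rendered,
# with polygon ground truth and a single senior-annotator label per object.

# Maximal cohort-drift offsets; a shift_strength s in [0, 1] scales these.
.SHIFT_MAX <- list(bg_offset = -20,   # grey levels added to background mean
                   contrast_scale = 0.30,  # contrast multiplied by (1 - 0.30 s)
                   size_scale = 0.25)      # sizes multiplied by (1 + 0.25 s)

#' Cohort drift parameters for a given shift strength
#'
#' The generator models "expedition"-level concept drift as a deterministic
#' offset of three appearance parameters. This helper exposes the applied
#' values so that drift is measurable from the outside.
#'
#' @param shift_strength drift magnitude in \[0, 1\].
#' @return list with `bg_offset` (grey levels, added to the background mean),
#'   `contrast_scale` and `size_scale` (multipliers).
#' @export
cohort_shift_params <- function(shift_strength) {
  stopifnot(shift_strength >= 0, shift_strength <= 1)
  list(bg_offset = .SHIFT_MAX$bg_offset * shift_strength,
       contrast_scale = 1 - .SHIFT_MAX$contrast_scale * shift_strength,
       size_scale = 1 + .SHIFT_MAX$size_scale * shift_strength)
}

#' Specify a synthetic virtual slide
#'
#' @param width_px,height_px canvas size in pixels (positive integers).
#' @param background_mean background grey level in \[0, 255\] (bright, since
#'   objects are darker; default 200).
#' @param background_sd grey-level noise standard deviation (>= 0).
#' @param debris_density expected debris blobs per megapixel (>= 0).
#' @param class_counts named integer vector/list, objects to render per class.
#' @param overlap_prob probability in \[0, 1\] that an object is deliberately
#'   placed adjacent to / overlapping an already placed object.
#' @param cohort_id cohort ("expedition") tag recorded in the slide metadata.
#' @param shift_strength cohort appearance drift magnitude in \[0, 1\]; see
#'   [cohort_shift_params()].
#' @param seed integer seed; identical specs give bit-identical slides.
#' @return an object of class `slide_spec`.
#' @export
slide_spec <- function(width_px, height_px, background_mean = 200,
                       background_sd = 6, debris_density = 5,
                       class_counts = integer(), overlap_prob = 0.1,
                       cohort_id = "A", shift_strength = 0, seed = 1L) {
  class_counts <- unlist(class_counts)
  stopifnot(width_px >= 1, height_px >= 1,
            background_mean >= 0, background_mean <= 255,
            background_sd >= 0, debris_density >= 0,
            overlap_prob >= 0, overlap_prob <= 1,
            shift_strength >= 0, shift_strength <= 1,
            all(class_counts >= 0))
  if (length(class_counts) && is.null(names(class_counts))) {
    stop("class_counts must be named by class")
  }
  structure(list(width_px = as.integer(width_px), height_px = as.integer(height_px),
                 background_mean = background_mean, background_sd = background_sd,
                 debris_density = debris_density,
                 class_counts = class_counts, overlap_prob = overlap_prob,
                 cohort_id = as.character(cohort_id),
                 shift_strength = shift_strength, seed = as.integer(seed)),
            class = "slide_spec")
}

new_virtual_slide <- function(image, slide_id, cohort_id, shift_strength = 0) {
  structure(list(image = image, slide_id = as.character(slide_id),
                 cohort_id = as.character(cohort_id),
                 shift_strength = shift_strength),
            class = "virtual_slide")
}

#' @export
print.virtual_slide <- function(x, ...) {
  cat(sprintf("<virtual_slide> %s (cohort %s): %d x %d px, grey %d-%d\n",
              x$slide_id, x$cohort_id, ncol(x$image), nrow(x$image),
              min(x$image), max(x$image)))
  invisible(x)
}

#' Construct an annotation record
#'
#' One object of interest: a polygon outline in 0-based slide pixel
#' coordinates plus one or more (annotator, label, seniority) label rows.
#'
#' @param slide_id,annotation_id identifiers.
#' @param polygon n x 2 matrix of (x, y) vertices, implicitly closed,
#'   n >= 3, non-zero area.
#' @param labels data frame with columns `annotator_id`, `label`,
#'   `is_senior` (logical); at most one distinct senior annotator.
#' @param skip_flag if `TRUE` the object is excluded from data sets
#'   (e.g. distorted by stitching).
#' @return object of class `annotation_record`.
#' @export
annotation_record <- function(slide_id, annotation_id, polygon, labels,
                              skip_flag = FALSE) {
  polygon <- as_polygon(polygon)
  if (polygon_area(polygon) <= 0) stop("polygon has zero area")
  labels <- as.data.frame(labels)
  stopifnot(all(c("annotator_id", "label", "is_senior") %in% names(labels)))
  senior <- unique(labels$annotator_id[as.logical(labels$is_senior)])
  if (length(senior) > 1) stop("at most one senior annotator per record")
  structure(list(slide_id = as.character(slide_id),
                 annotation_id = as.character(annotation_id),
                 polygon = polygon, labels = labels,
                 skip_flag = isTRUE(skip_flag)),
            class = "annotation_record")
}

# Render one polygon onto the canvas: interior set to a darker base level
# with periodic ornament along the object's major axis and pixel noise.
render_object <- function(canvas, poly, bbox, base_level, ornament_period,
                          ornament_amp, angle_rad, phase, noise_sd = 4) {
  m <- rasterize_polygon(poly, bbox)
  idx <- which(m == 1L)
  if (!length(idx)) return(canvas)
  h <- nrow(m); w <- ncol(m)
  rows <- ((idx - 1) %% h) + 1
  cols <- ((idx - 1) %/% h) + 1
  xs <- bbox[1] + cols - 1
  ys <- bbox[2] + rows - 1
  # coordinate along the major axis for stria ornament
  u <- xs * cos(angle_rad) + ys * sin(angle_rad)
  val <- base_level
  if (ornament_period > 0) {
    val <- val + ornament_amp * sin(2 * pi * u / ornament_period + phase)
  }
  val <- val + stats::rnorm(length(idx), 0, noise_sd)
  canvas[cbind(ys + 1, xs + 1)] <- clip255(val)
  canvas
}

bboxes_overlap <- function(a, b) {
  a[1] < b[3] && b[1] < a[3] && a[2] < b[4] && b[2] < a[4]
}

#' Generate one synthetic virtual slide with ground-truth annotations
#'
#' Renders `sum(spec$class_counts)` objects from the given shape families
#' onto a noisy bright background, plus unannotated debris. Each rendered
#' object yields one [annotation_record()] whose polygon is the exact
#' rendered outline and whose single label comes from a senior annotator.
#' Cohort drift (`spec$shift_strength`) offsets background level, contrast
#' and size as documented in [cohort_shift_params()].
#'
#' @param spec a [slide_spec()].
#' @param families named list of [shape_family()] covering every class in
#'   `spec$class_counts`.
#' @param slide_id identifier recorded on the slide and its records.
#' @return list with elements `slide` ([print.virtual_slide] object) and
#'   `annotations` (list of [annotation_record()]).
#' @export
generate_slide <- function(spec, families = default_shape_families(),
                           slide_id = paste0(spec$cohort_id, "-s", spec$seed)) {
  stopifnot(inherits(spec, "slide_spec"))
  unknown <- setdiff(names(spec$class_counts), names(families))
  if (length(unknown)) {
    stop("no shape family for class(es): ", paste(unknown, collapse = ", "))
  }
  drift <- cohort_shift_params(spec$shift_strength)
  W <- spec$width_px; H <- spec$height_px
  bg <- spec$background_mean + drift$bg_offset

  with_seed(spec$seed, {
    canvas <- matrix(clip255(round(bg + stats::rnorm(W * H, 0, spec$background_sd))),
                     nrow = H, ncol = W)

    # debris: small unannotated blobs
    n_debris <- stats::rpois(1, spec$debris_density * W * H / 1e6)
    for (d in seq_len(n_debris)) {
      r <- stats::runif(1, 2, 6)
      cx <- stats::runif(1, 0, W - 1); cy <- stats::runif(1, 0, H - 1)
      t <- seq(0, 2 * pi, length.out = 13)[-13]
      poly <- cbind(cx + r * cos(t) * stats::runif(1, 0.6, 1.4),
                    cy + r * sin(t))
      bb <- polygon_bbox(poly)
      bb <- pmax(pmin(bb, c(W, H, W, H)), 0)
      if (bb[3] > bb[1] && bb[4] > bb[2]) {
        canvas <- render_object(canvas, poly, bb, bg - stats::runif(1, 10, 60),
                                0, 0, 0, 0, noise_sd = 3)
      }
    }

    # objects, classes in listed order for reproducibility; an occupancy
    # mask guarantees rendered bodies never intersect, so every record's
    # polygon recovers its own rendered pixels even for adjacent placements
    annotations <- list()
    placed_bboxes <- list()
    occupancy <- matrix(FALSE, H, W)
    ann_i <- 0L
    body_clear <- function(poly, bb) {
      m <- rasterize_polygon(poly, bb)
      idx <- which(m == 1L)
      if (!length(idx)) return(list(ok = TRUE, cells = NULL))
      rows <- bb[2] + ((idx - 1) %% nrow(m)) + 1
      cols <- bb[1] + ((idx - 1) %/% nrow(m)) + 1
      cells <- cbind(rows, cols)
      list(ok = !any(occupancy[cells]), cells = cells)
    }
    for (cls in names(spec$class_counts)) {
      fam <- families[[cls]]
      for (k in seq_len(spec$class_counts[[cls]])) {
        inst <- draw_instance(fam, size_scale = drift$size_scale)
        poly0 <- inst$polygon
        bb0 <- polygon_bbox(poly0)
        ow <- bb0[3] - bb0[1]; oh <- bb0[4] - bb0[2]
        if (ow > W || oh > H) {
          stop(sprintf("canvas %dx%d too small for an object of class '%s' (%dx%d)",
                       W, H, cls, ow, oh))
        }
        want_overlap <- length(placed_bboxes) > 0 &&
          stats::runif(1) < spec$overlap_prob
        pos <- NULL; cells <- NULL
        if (want_overlap) {
          # adjacent placement: the neighbour's bounding box overlaps the
          # anchor's (so it shows up inside the anchor's cut-out window)
          # while the object bodies stay disjoint
          anchor <- placed_bboxes[[sample.int(length(placed_bboxes), 1)]]
          acx <- (anchor[1] + anchor[3]) / 2
          acy <- (anchor[2] + anchor[4]) / 2
          half_x <- (anchor[3] - anchor[1]) / 2 + (bb0[3] - bb0[1]) / 2
          half_y <- (anchor[4] - anchor[2]) / 2 + (bb0[4] - bb0[2]) / 2
          for (try in seq_len(25L)) {
            phi <- stats::runif(1, 0, 2 * pi)
            f <- stats::runif(1, 0.95, 1.1) + 0.02 * (try - 1)
            cx <- acx + f * half_x * cos(phi)
            cy <- acy + f * half_y * sin(phi)
            cx <- min(max(cx, -bb0[1]), W - 1 - bb0[3])
            cy <- min(max(cy, -bb0[2]), H - 1 - bb0[4])
            cand_poly <- cbind(poly0[, 1] + cx, poly0[, 2] + cy)
            cand_bb <- polygon_bbox(cand_poly)
            cand_bb <- c(pmax(cand_bb[1:2], 0), pmin(cand_bb[3:4], c(W, H)))
            chk <- body_clear(cand_poly, cand_bb)
            if (chk$ok) { pos <- c(cx, cy); cells <- chk$cells; break }
          }
        }
        if (is.null(pos)) {
          for (try in seq_len(200L)) {
            cx <- stats::runif(1, -bb0[1], W - 1 - bb0[3])
            cy <- stats::runif(1, -bb0[2], H - 1 - bb0[4])
            cand <- c(bb0[1] + cx, bb0[2] + cy, bb0[3] + cx, bb0[4] + cy)
            clash <- any(vapply(placed_bboxes, bboxes_overlap, TRUE, b = cand))
            if (!clash) { pos <- c(cx, cy); break }
          }
          if (is.null(pos)) {
            if (spec$overlap_prob == 0) {
              stop(sprintf(
                "could not place all objects without overlap on a %dx%d canvas",
                W, H))
            }
            # crowded canvas: fall back to any body-disjoint position
            for (try in seq_len(200L)) {
              cx <- stats::runif(1, -bb0[1], W - 1 - bb0[3])
              cy <- stats::runif(1, -bb0[2], H - 1 - bb0[4])
              cand_poly <- cbind(poly0[, 1] + cx, poly0[, 2] + cy)
              cand_bb <- polygon_bbox(cand_poly)
              cand_bb <- c(pmax(cand_bb[1:2], 0), pmin(cand_bb[3:4], c(W, H)))
              chk <- body_clear(cand_poly, cand_bb)
              if (chk$ok) { pos <- c(cx, cy); cells <- chk$cells; break }
            }
            if (is.null(pos)) {
              stop(sprintf(
                "could not place all objects on a %dx%d canvas", W, H))
            }
          }
        }
        poly <- cbind(poly0[, 1] + pos[1], poly0[, 2] + pos[2])
        bb <- polygon_bbox(poly)
        bb <- c(pmax(bb[1:2], 0), pmin(bb[3:4], c(W, H)))
        if (is.null(cells)) cells <- body_clear(poly, bb)$cells
        contrast <- fam$contrast * drift$contrast_scale
        canvas <- render_object(canvas, poly, bb,
                                base_level = bg - contrast,
                                ornament_period = fam$ornament_period,
                                ornament_amp = 0.35 * contrast,
                                angle_rad = inst$angle_rad, phase = inst$phase)
        placed_bboxes[[length(placed_bboxes) + 1L]] <- bb
        if (!is.null(cells)) occupancy[cells] <- TRUE
        ann_i <- ann_i + 1L
        annotations[[ann_i]] <- annotation_record(
          slide_id = slide_id,
          annotation_id = sprintf("a%04d", ann_i),
          polygon = poly,
          labels = data.frame(annotator_id = "senior_1", label = cls,
                              is_senior = TRUE))
      }
    }
    canvas <- matrix(as.integer(round(canvas)), nrow = H, ncol = W)
    list(slide = new_virtual_slide(canvas, slide_id, spec$cohort_id,
                                   spec$shift_strength),
         annotations = annotations)
  })
}

#' Add simulated annotator disagreement
#'
#' Each record gains `n_annotators - 1` additional labels drawn from the
#' confusion row of its true (senior) class; the senior label is never
#' altered. This emulates multiple users agreeing or disagreeing on
#' previously attached labels.
#'
#' @param records list of [annotation_record()], each with exactly one
#'   senior label.
#' @param confusion square numeric matrix with row/column names equal to the
#'   class set; each row a probability vector (sums to 1 within 1e-6).
#' @param n_annotators total number of annotators (>= 2).
#' @param seed integer seed.
#' @return the records with extended label tables.
#' @export
add_annotator_disagreement <- function(records, confusion, n_annotators = 2L,
                                       seed = 1L) {
  stopifnot(n_annotators >= 2, is.matrix(confusion),
            nrow(confusion) == ncol(confusion))
  if (any(abs(rowSums(confusion) - 1) > 1e-6)) {
    stop("every confusion row must sum to 1")
  }
  classes <- colnames(confusion)
  with_seed(seed, {
    lapply(records, function(r) {
      senior <- r$labels$label[as.logical(r$labels$is_senior)]
      if (length(senior) != 1) stop("record must have exactly one senior label")
      if (!senior %in% rownames(confusion)) {
        stop("class not in confusion matrix: ", senior)
      }
      extra <- sample(classes, n_annotators - 1L, replace = TRUE,
                      prob = confusion[senior, ])
      r$labels <- rbind(r$labels,
                        data.frame(annotator_id = paste0("annot_", seq_along(extra) + 1L),
                                   label = extra, is_senior = FALSE))
      r
    })
  })
}

#' Generate a two-cohort ("expedition") slide collection
#'
#' Cohort A is rendered without drift, cohort B with the given
#' `shift_strength` applied to background level, contrast and size
#' distributions (see [cohort_shift_params()]). With `shift_strength = 0`
#' the two cohorts come from the same generating distribution and differ
#' only by their random draws.
#'
#' @param base_spec a [slide_spec()]; its `cohort_id`/`shift_strength` are
#'   overridden per cohort, its `seed` seeds the whole collection.
#' @param n_slides_per_cohort number of slides per cohort (>= 1).
#' @param shift_strength drift applied to cohort B, in \[0, 1\].
#' @param families shape families passed to [generate_slide()].
#' @param cohort_ids length-2 character, ids of the two cohorts.
#' @return list with elements `A` and `B`, each a list of
#'   `list(slide, annotations)` as returned by [generate_slide()].
#' @export
generate_cohort_pair <- function(base_spec, n_slides_per_cohort = 1L,
                                 shift_strength = 0,
                                 families = default_shape_families(),
                                 cohort_ids = c("A", "B")) {
  stopifnot(n_slides_per_cohort >= 1)
  gen <- function(cohort, shift, stream0) {
    lapply(seq_len(n_slides_per_cohort), function(i) {
      sp <- base_spec
      sp$cohort_id <- cohort
      sp$shift_strength <- shift
      sp$seed <- as.integer(child_seed(base_spec$seed, stream0 + i))
      generate_slide(sp, families,
                     slide_id = sprintf("%s-s%02d", cohort, i))
    })
  }
  out <- list(gen(cohort_ids[1], 0, 0L),
              gen(cohort_ids[2], shift_strength, 1000L))
  names(out) <- cohort_ids
  out
}
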