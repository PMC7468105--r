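test_that("slide generation honours class counts, labels and determinism", {
  fams <- default_shape_families(c("Nitzschia", "Thalassiosira gracilis"))
  spec <- slide_spec(600, 500,
                     class_counts = c("Nitzschia" = 7,
                                      "Thalassiosira gracilis" = 5),
                     seed = 11)
  g <- generate_slide(spec, fams)
  expect_length(g$annotations, 12)
  labs <- vapply(g$annotations, resolve_gold_label, "")
  expect_equal(sum(labs == "Nitzschia"), 7)
  expect_equal(sum(labs == "Thalassiosira gracilis"), 5)
  expect_true(all(vapply(g$annotations, function(r)
    sum(as.logical(r$labels$is_senior)), 0L) == 1L))

  expect_identical(generate_slide(spec, fams), g)

  # all polygons lie inside the canvas
  for (r in g$annotations) {
    expect_true(all(r$polygon[, 1] >= -0.51 & r$polygon[, 1] <= 600))
    expect_true(all(r$polygon[, 2] >= -0.51 & r$polygon[, 2] <= 500))
  }
})

test_that("empty class counts give a background-only slide", {
  spec <- slide_spec(200, 150, debris_density = 0, class_counts = integer(),
                     background_mean = 200, background_sd = 6, seed = 2)
  g <- generate_slide(spec)
  expect_length(g$annotations, 0)
  expect_equal(dim(g$slide$image), c(150L, 200L))
  expect_equal(mean(g$slide$image), 200, tolerance = 0.5)
  expect_equal(sd(g$slide$image), 6, tolerance = 0.5)
})

test_that("generation fails cleanly on unknown classes and impossible placements", {
  expect_error(generate_slide(slide_spec(300, 300, class_counts = c(Zz = 1))),
               "no shape family")
  crowded <- slide_spec(150, 150, overlap_prob = 0,
                        class_counts = c("Thalassiosira gracilis" = 40), seed = 1)
  expect_error(generate_slide(crowded), "without overlap")
  expect_error(generate_slide(slide_spec(40, 40,
                                         class_counts = c("Rhizosolenia" = 1))),
               "too small")
})

test_that("rendered objects are recovered by their ground-truth polygons", {
  fams <- default_shape_families(c("Thalassiosira lentiginosa", "Rhizosolenia",
                                   "Silicoflagellate", "Fragilariopsis rhombica"))
  spec <- slide_spec(1500, 1500, debris_density = 0, overlap_prob = 0,
                     background_sd = 2,
                     class_counts = stats::setNames(rep(13, 4), names(fams)),
                     seed = 33)
  g <- generate_slide(spec, fams)
  set.seed(1)
  picks <- sample(length(g$annotations), 50)
  for (i in picks) {
    co <- extract_cutout(g$slide, g$annotations[[i]], margin_px = 5)
    fam <- fams[[co$label]]
    # rendered foreground: pixels darker than halfway between background
    # and the family's nominal object level
    thresh <- 200 - 0.35 * fam$contrast
    dark <- co$image < thresh
    recovered <- sum(dark & co$mask == 1L) / max(1, sum(dark))
    expect_gte(recovered, 0.95)
  }
})

test_that("annotator disagreement sampling follows the confusion matrix", {
  recs <- lapply(1:3, function(i)
    make_record(label_rows(c("senior_1", "A", TRUE)), annotation_id = paste0("a", i)))

  ident <- diag(2); dimnames(ident) <- list(c("A", "B"), c("A", "B"))
  out <- add_annotator_disagreement(recs, ident, n_annotators = 3, seed = 1)
  for (r in out) {
    expect_equal(nrow(r$labels), 3)
    expect_true(all(r$labels$label == "A"))
    expect_equal(sum(as.logical(r$labels$is_senior)), 1)
  }

  out2 <- add_annotator_disagreement(recs[1], ident, n_annotators = 2, seed = 1)
  expect_equal(nrow(out2[[1]]$labels), 2)

  bad <- matrix(c(0.6, 0.6, 0.5, 0.5), 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(add_annotator_disagreement(recs, bad), "sum to 1")
})

test_that("disagreement fraction matches its binomial expectation", {
  n <- 10000
  recs <- lapply(seq_len(n), function(i)
    make_record(label_rows(c("senior_1", "A", TRUE)),
                annotation_id = paste0("a", i)))
  conf <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, byrow = TRUE,
                 dimnames = list(c("A", "B"), c("A", "B")))
  out <- add_annotator_disagreement(recs, conf, n_annotators = 2, seed = 42)
  extra <- vapply(out, function(r) r$labels$label[2], "")
  frac <- mean(extra != "A")
  se <- sqrt(0.25 / n)
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("cohort pairs expose the documented drift and none without it", {
  fams <- default_shape_families(c("Thalassiosira gracilis", "Nitzschia"))
  base <- slide_spec(600, 600, debris_density = 0,
                     class_counts = c("Thalassiosira gracilis" = 5,
                                      "Nitzschia" = 5),
                     seed = 13)
  # shift 0: same generating distribution; per-class mean object area within 3 SE
  pair0 <- generate_cohort_pair(base, n_slides_per_cohort = 10,
                                shift_strength = 0, families = fams)
  areas <- function(coh, cls) {
    unlist(lapply(coh, function(s) {
      keep <- vapply(s$annotations, resolve_gold_label, "") == cls
      vapply(s$annotations[keep], function(r)
        diatomslide:::polygon_area(r$polygon), 0)
    }))
  }
  for (cls in names(fams)) {
    aA <- areas(pair0$A, cls); aB <- areas(pair0$B, cls)
    se <- sqrt(var(aA) / length(aA) + var(aB) / length(aB))
    expect_lt(abs(mean(aA) - mean(aB)), 3 * se)
  }

  # full shift: background means differ by the documented maximal offset
  bg_spec <- slide_spec(300, 300, debris_density = 0, class_counts = integer(),
                        seed = 19)
  pairs <- generate_cohort_pair(bg_spec, n_slides_per_cohort = 3,
                                shift_strength = 1)
  bgA <- mean(vapply(pairs$A, function(s) mean(s$slide$image), 0))
  bgB <- mean(vapply(pairs$B, function(s) mean(s$slide$image), 0))
  expect_equal(bgB - bgA, cohort_shift_params(1)$bg_offset, tolerance = 0.5)

  single <- generate_cohort_pair(bg_spec, n_slides_per_cohort = 1)
  expect_length(single$A, 1)
  expect_length(single$B, 1)
})

test_that("slides and annotations survive a file round-trip", {
  dir <- withr::local_tempdir()
  pair <- tiny_cohort_pair()
  sl <- pair$A[[1]]$slide
  for (ext in c("png", "tif")) {
    path <- file.path(dir, paste0("s.", ext))
    write_slide(sl, path)
    back <- read_slide(path, slide_id = sl$slide_id, cohort_id = sl$cohort_id)
    expect_identical(back$image, sl$image)
  }
  recs <- add_annotator_disagreement(
    pair$A[[1]]$annotations,
    {
      cls <- c("Thalassiosira gracilis", "Rhizosolenia")
      m <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE,
                  dimnames = list(cls, cls))
      m
    }, n_annotators = 3, seed = 2)
  csv <- file.path(dir, "ann.csv")
  write_annotations(recs, csv)
  back <- read_annotations(csv)
  expect_length(back, length(recs))
  for (i in seq_along(recs)) {
    expect_equal(back[[i]]$polygon, recs[[i]]$polygon)
    expect_equal(back[[i]]$labels$label, recs[[i]]$labels$label)
    expect_equal(back[[i]]$labels$is_senior, recs[[i]]$labels$is_senior)
  }
})

test_that("cut-out export writes images and a manifest", {
  dir <- withr::local_tempdir()
  ds <- tiny_dataset()
  cuts <- ds$A$raw[1:3]
  manifest <- write_cutouts(cuts, dir)
  m <- read.csv(manifest)
  expect_equal(nrow(m), 3)
  expect_true(all(file.exists(file.path(dir, m$cutout_path))))
  expect_true(all(grepl("_raw\\.png$", m$cutout_path)))
})
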