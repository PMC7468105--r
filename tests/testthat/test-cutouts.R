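test_that("gold-standard resolution follows the seniority policy table", {
  r1 <- make_record(label_rows(c("u1", "Nitzschia", TRUE)))
  expect_equal(resolve_gold_label(r1), "Nitzschia")

  r2 <- make_record(label_rows(c("u1", "Chaetoceros", FALSE),
                               c("u2", "Nitzschia", TRUE)))
  expect_equal(resolve_gold_label(r2), "Nitzschia")

  r3 <- make_record(label_rows(c("u1", "A", FALSE), c("u2", "B", FALSE)))
  expect_true(is.na(resolve_gold_label(r3, policy = "senior_wins")))
  expect_true(is.na(resolve_gold_label(r3, policy = "unanimous_only")))

  # unanimous_only skips any divergence, even with a senior label present
  expect_true(is.na(resolve_gold_label(r2, policy = "unanimous_only")))
  # agreement needs no senior
  r4 <- make_record(label_rows(c("u1", "A", FALSE), c("u2", "A", FALSE)))
  expect_equal(resolve_gold_label(r4, policy = "unanimous_only"), "A")
  # skip-flagged records are always skipped
  r5 <- make_record(label_rows(c("u1", "A", TRUE)), skip_flag = TRUE)
  expect_true(is.na(resolve_gold_label(r5)))

  r6 <- make_record(label_rows(c("u1", "A", TRUE)))
  r6$labels <- r6$labels[0, ]
  expect_error(resolve_gold_label(r6), "no label")
})

flat_slide <- function(w = 1000, h = 1000, value = 200) {
  diatomslide:::new_virtual_slide(matrix(as.integer(value), h, w), "s", "A")
}

test_that("cut-out boxes follow the half-open margin arithmetic", {
  rec <- make_record(label_rows(c("u1", "A", TRUE)),
                     polygon = rbind(c(20, 30), c(40, 30), c(40, 50), c(20, 50)))
  co <- extract_cutout(flat_slide(), rec, margin_px = 10)
  expect_equal(co$bbox, c(10L, 20L, 50L, 60L))
  expect_equal(dim(co$image), c(40L, 40L))

  co0 <- extract_cutout(flat_slide(), rec, margin_px = 0)
  expect_equal(co0$bbox, c(20L, 30L, 40L, 50L))

  corner <- make_record(label_rows(c("u1", "A", TRUE)),
                        polygon = rbind(c(0, 0), c(8, 0), c(8, 8), c(0, 8)))
  coc <- extract_cutout(flat_slide(), corner, margin_px = 10)
  expect_equal(coc$bbox[1:2], c(0L, 0L))

  outside <- make_record(label_rows(c("u1", "A", TRUE)),
                         polygon = rbind(c(2000, 2000), c(2010, 2000),
                                         c(2010, 2010), c(2000, 2010)))
  expect_error(extract_cutout(flat_slide(), outside), "outside")
})

test_that("cut-out extraction commutes with slide translation", {
  set.seed(8)
  img <- matrix(as.integer(sample(0:255, 300 * 300, TRUE)), 300, 300)
  poly <- rbind(c(40, 60), c(80, 55), c(95, 90), c(50, 100))
  dx <- 37; dy <- 21
  img2 <- matrix(0L, 300, 300)
  img2[dy + (1:(300 - dy)), dx + (1:(300 - dx))] <- img[1:(300 - dy), 1:(300 - dx)]
  s1 <- diatomslide:::new_virtual_slide(img, "s1", "A")
  s2 <- diatomslide:::new_virtual_slide(img2, "s1", "A")
  rec1 <- make_record(label_rows(c("u1", "A", TRUE)), polygon = poly)
  rec2 <- make_record(label_rows(c("u1", "A", TRUE)),
                      polygon = cbind(poly[, 1] + dx, poly[, 2] + dy))
  c1 <- extract_cutout(s1, rec1)
  c2 <- extract_cutout(s2, rec2)
  expect_identical(c1$image, c2$image)
  expect_identical(c1$mask, c2$mask)
  expect_identical(mask_background(c1)$image, mask_background(c2)$image)
})

test_that("mask foreground agrees exactly with a point-in-polygon oracle", {
  skip_if_not_installed("mgcv")
  set.seed(19)
  for (rep in 1:20) {
    pts <- cbind(runif(10, 30, 90), runif(10, 30, 90))
    poly <- pts[chull(pts), ]
    rec <- make_record(label_rows(c("u1", "A", TRUE)), polygon = poly)
    co <- extract_cutout(flat_slide(200, 200), rec)
    bb <- co$bbox
    xs <- (bb[1]:(bb[3] - 1)) + 0.5
    ys <- (bb[2]:(bb[4] - 1)) + 0.5
    grid <- cbind(rep(xs, each = length(ys)), rep(ys, times = length(xs)))
    oracle <- mgcv::in.out(rbind(poly, poly[1, ]), grid)
    expect_equal(as.vector(co$mask) == 1L, oracle)
  }
})

noisy_cutout <- function(obj_grey = 60, bg_grey = 200, seed = 2) {
  set.seed(seed)
  img <- matrix(as.integer(round(bg_grey + rnorm(60 * 60, 0, 3))), 60, 60)
  sl <- diatomslide:::new_virtual_slide(img, "s", "A")
  rec <- make_record(label_rows(c("u1", "A", TRUE)),
                     polygon = rbind(c(20, 20), c(40, 20), c(40, 40), c(20, 40)))
  co <- extract_cutout(sl, rec, margin_px = 15)
  co$image[co$mask == 1L] <- as.integer(obj_grey)
  co
}

test_that("soft background masking drives far background to the mean and leaves the object", {
  co <- noisy_cutout()
  b <- mean(co$image[co$mask == 0L])
  masked <- mask_background(co, transition_width_px = 5)
  # pixels >= 6 px outside the polygon equal the background mean within one
  # grey level (plus integer rounding of the stored image)
  expect_lt(abs(masked$image[1, 1] - b), 1.5)
  expect_true(all(abs(masked$image[1:9, ] - b) <= 1.5))
  # object pixels are untouched
  expect_true(all(masked$image[masked$mask == 1L] == 60L))
  expect_true(masked$masked)
  expect_error(mask_background(masked), "already masked")
})

test_that("masking is a no-op on constant patches and full-cover polygons", {
  co <- noisy_cutout()
  co$image[] <- 128L
  expect_equal(mask_background(co)$image, co$image)

  full <- noisy_cutout()
  full$mask[] <- 1L
  out <- mask_background(full)
  expect_identical(out$image, full$image)
})

test_that("masking is idempotent within one grey level", {
  co <- noisy_cutout(obj_grey = 60, seed = 7)
  m1 <- mask_background(co, 5)
  m2 <- m1
  m2$masked <- FALSE
  m2 <- mask_background(m2, 5)
  expect_true(max(abs(m2$image - m1$image)) <= 1)
})

test_that("class filtering keeps classes meeting the per-cohort minimum", {
  counts <- matrix(c(76, 42, 39, 100, 40, 40), ncol = 2, byrow = TRUE,
                   dimnames = list(c("N", "X", "Y"), c("A", "B")))
  expect_equal(filter_classes(counts, 40), c("N", "Y"))
  expect_equal(filter_classes(counts, 0), c("N", "X", "Y"))
  expect_equal(filter_classes(counts, 101), character())
})

test_that("class capping subsamples only the named class, preserving order", {
  recs <- lapply(1:30, function(i) {
    list(label = if (i <= 20) "big" else "small", id = i)
  })
  capped <- cap_class(recs, "big", cap = 8, seed = 3)
  labs <- vapply(capped, `[[`, "", "label")
  expect_equal(sum(labs == "big"), 8)
  expect_equal(sum(labs == "small"), 10)
  ids <- vapply(capped, `[[`, 0, "id")
  expect_true(all(diff(ids[labs == "big"]) > 0))  # survivor order preserved
  expect_identical(cap_class(recs, "big", 8, seed = 3), capped)
  expect_identical(cap_class(recs, "big", 25, seed = 3), recs)
  # content of surviving records is untouched
  expect_identical(capped[[1]], recs[[ids[1]]])
})
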