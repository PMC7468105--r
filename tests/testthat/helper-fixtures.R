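# Shared fixture builders. Everything is generated in code at test time;
# expensive fixtures are memoised for the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

memoise_fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A record with an arbitrary label table on a unit square polygon.
make_record <- function(labels, slide_id = "s1", annotation_id = "a1",
                        polygon = rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)),
                        skip_flag = FALSE) {
  annotation_record(slide_id, annotation_id, polygon, labels, skip_flag)
}

label_rows <- function(...) {
  # label_rows(c("u1", "A", TRUE), c("u2", "B", FALSE))
  rows <- list(...)
  data.frame(annotator_id = vapply(rows, `[[`, "", 1),
             label = vapply(rows, `[[`, "", 2),
             is_senior = vapply(rows, function(r) as.logical(r[[3]]), TRUE),
             stringsAsFactors = FALSE)
}

# Small two-class cohort pair used by split/experiment tests.
tiny_cohort_pair <- function() {
  memoise_fixture("tiny_pair", function() {
    fams <- default_shape_families(c("Thalassiosira gracilis", "Rhizosolenia"))
    spec <- slide_spec(700, 700, debris_density = 2,
                       class_counts = c("Thalassiosira gracilis" = 6,
                                        "Rhizosolenia" = 6),
                       overlap_prob = 0.1, seed = 21L)
    generate_cohort_pair(spec, n_slides_per_cohort = 2, shift_strength = 0.4,
                         families = fams)
  })
}

tiny_dataset <- function() {
  memoise_fixture("tiny_dataset", function() assemble_dataset(tiny_cohort_pair()))
}

# Flat cut-out list -> named class -> item-id list (mirrors the runner).
ids_by_class <- function(cutouts) {
  ids <- vapply(cutouts, function(co)
    paste(co$source$slide_id, co$source$annotation_id, sep = "/"), "")
  labs <- vapply(cutouts, function(co) as.character(co$label), "")
  split(ids, labs)
}

cutout_by_id <- function(cutouts) {
  stats::setNames(cutouts, vapply(cutouts, function(co)
    paste(co$source$slide_id, co$source$annotation_id, sep = "/"), ""))
}

# Trivially separable two-class image fixture: dark disc vs dark thin bar on
# a bright background, already preprocessed to tensors. A linear probe on
# mean intensity separates the two classes perfectly.
disc_bar_items <- function(n_per_class = 20, side = 32, seed = 5) {
  withr::with_seed(seed, {
    items <- list()
    for (i in seq_len(n_per_class)) {
      for (cls in c("disc", "bar")) {
        img <- matrix(200 + rnorm(side^2, 0, 5), side, side)
        cx <- runif(1, 12, side - 12); cy <- runif(1, 12, side - 12)
        xs <- matrix(rep(1:side, each = side), side)
        ys <- matrix(rep(1:side, side), side)
        if (cls == "disc") {
          r <- runif(1, 7, 9)
          img[(xs - cx)^2 + (ys - cy)^2 < r^2] <- 70
        } else {
          img[abs(ys - cy) < 2 & abs(xs - cx) < 9] <- 70
        }
        items[[length(items) + 1]] <-
          list(x = array(pmin(pmax(img / 255, 0), 1), c(side, side, 3)),
               label = cls)
      }
    }
    items
  })
}
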