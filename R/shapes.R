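# Procedural shape families emulating the morphological variety of Southern
# Ocean diatom taxa (and the silicoflagellate out-group) on brightfield
# virtual slides: analytic silhouettes plus periodic ornament ("striae")
# rendered darker than the bright background.

#' Define a shape family
#'
#' A shape family is the generative description of one taxon-like class:
#' a base silhouette, a size range, an ornament (stria) period, a contrast
#' against the background and an orientation distribution. Families used
#' together should differ in at least one parameter so that classes are
#' separable by a small classifier.
#'
#' @param name class name (string).
#' @param base one of `"lanceolate"` (pointed pennate outline),
#'   `"circular"` (centric disc), `"star"` (spiky rosette),
#'   `"chain"` (wavy colony band) or `"rod"` (capsule).
#' @param size_range length-2 numeric, min/max major-axis length in pixels
#'   (minimum allowed is 8).
#' @param ornament_period stria period in pixels (0 disables ornament).
#' @param contrast mean grey-level depression of the object below the
#'   background, in grey levels.
#' @param aspect width-to-length ratio of the silhouette (ignored for
#'   circular and star bases).
#' @param orientation `"uniform"` for random rotation or a fixed angle in
#'   degrees.
#' @return an object of class `shape_family`.
#' @export
shape_family <- function(name, base = c("lanceolate", "circular", "star", "chain", "rod"),
                         size_range = c(40, 80), ornament_period = 6,
                         contrast = 80, aspect = 0.3, orientation = "uniform") {
  base <- match.arg(base)
  stopifnot(length(size_range) == 2, size_range[1] >= 8, size_range[2] >= size_range[1],
            ornament_period >= 0, contrast > 0, aspect > 0, aspect <= 1)
  structure(list(name = as.character(name), base = base,
                 size_range = as.numeric(size_range),
                 ornament_period = as.numeric(ornament_period),
                 contrast = as.numeric(contrast), aspect = as.numeric(aspect),
                 orientation = orientation),
            class = "shape_family")
}

#' @export
print.shape_family <- function(x, ...) {
  cat(sprintf("<shape_family> %s: %s, %g-%g px, period %g px, contrast %g\n",
              x$name, x$base, x$size_range[1], x$size_range[2],
              x$ornament_period, x$contrast))
  invisible(x)
}

#' Registry of default shape families
#'
#' Returns named shape families mirroring the ten taxa of the reference
#' composition bundled with the package (four species-level diatoms, five
#' genus-level diatoms, one silicoflagellate). Each family is distinguishable
#' from every other by base silhouette, size, aspect or ornament period.
#'
#' @param classes optional character vector selecting a subset by name.
#' @return named list of `shape_family` objects.
#' @export
default_shape_families <- function(classes = NULL) {
  fams <- list(
    shape_family("Fragilariopsis kerguelensis", "lanceolate",
                 size_range = c(45, 90), ornament_period = 7, contrast = 95, aspect = 0.32),
    shape_family("Pseudonitzschia", "rod",
                 size_range = c(70, 130), ornament_period = 4, contrast = 55, aspect = 0.10),
    shape_family("Chaetoceros", "chain",
                 size_range = c(60, 110), ornament_period = 12, contrast = 60, aspect = 0.40),
    shape_family("Silicoflagellate", "star",
                 size_range = c(35, 65), ornament_period = 0, contrast = 110, aspect = 1),
    shape_family("Thalassiosira lentiginosa", "circular",
                 size_range = c(45, 75), ornament_period = 9, contrast = 70, aspect = 1),
    shape_family("Fragilariopsis rhombica", "lanceolate",
                 size_range = c(20, 40), ornament_period = 5, contrast = 85, aspect = 0.55),
    shape_family("Rhizosolenia", "rod",
                 size_range = c(110, 200), ornament_period = 0, contrast = 45, aspect = 0.13),
    shape_family("Asteromphalus", "circular",
                 size_range = c(40, 70), ornament_period = 16, contrast = 95, aspect = 1),
    shape_family("Thalassiosira gracilis", "circular",
                 size_range = c(18, 32), ornament_period = 5, contrast = 80, aspect = 1),
    shape_family("Nitzschia", "lanceolate",
                 size_range = c(35, 70), ornament_period = 3, contrast = 60, aspect = 0.15)
  )
  names(fams) <- vapply(fams, `[[`, "", "name")
  if (!is.null(classes)) {
    missing <- setdiff(classes, names(fams))
    if (length(missing)) stop("unknown class name(s): ", paste(missing, collapse = ", "))
    fams <- fams[classes]
  }
  fams
}

# Generate the outline polygon of one object of a family, centred at the
# origin, unrotated; `length_px` is the major-axis length. Returns an
# n x 2 (x, y) matrix.
family_outline <- function(family, length_px) {
  L <- length_px
  W <- max(4, L * family$aspect)
  switch(family$base,
    lanceolate = {
      x <- seq(-L / 2, L / 2, length.out = 32)
      half <- (W / 2) * (1 - (2 * x / L)^2)
      half <- pmax(half, 0)^0.75 * (W / 2)^0.25  # pointed tips
      rbind(cbind(x, half), cbind(rev(x), -rev(half)))
    },
    circular = {
      t <- seq(0, 2 * pi, length.out = 41)[-41]
      r <- L / 2 * (1 + 0.03 * sin(5 * t))
      cbind(r * cos(t), r * sin(t))
    },
    star = {
      t <- seq(0, 2 * pi, length.out = 61)[-61]
      r <- L / 2 * (0.45 + 0.55 * pmax(cos(6 * t), 0)^1.5 + 0.08 * sin(3 * t))
      cbind(r * cos(t), r * sin(t))
    },
    chain = {
      # a band whose half-width oscillates, evoking a colony of linked cells
      x <- seq(-L / 2, L / 2, length.out = 48)
      half <- (W / 2) * (0.55 + 0.45 * abs(cos(2 * pi * x / (L / 4))))
      rbind(cbind(x, half), cbind(rev(x), -rev(half)))
    },
    rod = {
      # capsule: rectangle with semicircular caps
      r <- W / 2
      xc <- L / 2 - r
      t1 <- seq(-pi / 2, pi / 2, length.out = 13)
      t2 <- seq(pi / 2, 3 * pi / 2, length.out = 13)
      rbind(cbind(xc + r * cos(t1), r * sin(t1)),
            cbind(-xc + r * cos(t2), r * sin(t2)))
    }
  )
}

# Draw one object instance: sampled length, orientation and ornament phase.
# Returns list(polygon, length_px, angle_rad, phase).
draw_instance <- function(family, size_scale = 1) {
  len <- stats::runif(1, family$size_range[1], family$size_range[2]) * size_scale
  ang <- if (identical(family$orientation, "uniform")) {
    stats::runif(1, 0, 2 * pi)
  } else {
    as.numeric(family$orientation) * pi / 180
  }
  poly <- family_outline(family, len)
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  list(polygon = poly %*% t(R), length_px = len, angle_rad = ang,
       phase = stats::runif(1, 0, 2 * pi))
}
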