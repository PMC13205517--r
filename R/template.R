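#' Canonical 68-point face template
#'
#' A fixed, documented face layout following the iBUG 68-landmark
#' convention (1-based indexing): jawline 1-17, brows 18-27, nose 28-36
#' (nose tip = landmark 34), right eye 37-42, left eye 43-48, mouth 49-68.
#' Coordinates are in pixels in image convention (y grows downwards), with
#' the face centred near (320, 240) and an inter-ocular distance (between
#' eye-landmark centroids) of 90 px. The template is the deterministic
#' starting point of the simulation generators and the coordinate frame for
#' facial topography plots.
#'
#' @return A tibble with columns `landmark` (integer 1-68), `x`, `y`
#'   (pixels) and `region` (character).
#' @examples
#' tpl <- face_template()
#' table(tpl$region)
#' @export
face_template <- function() {
  # jawline: lower-face elliptical arc, ear to ear through the chin
  ang <- seq(pi, 2 * pi, length.out = 17)
  jaw_x <- 320 + 95 * cos(ang)
  jaw_y <- 220 - 115 * sin(ang)

  brow_r_x <- seq(245, 300, length.out = 5)
  brow_l_x <- seq(340, 395, length.out = 5)
  brow_y <- 180 - c(0, 4, 6, 4, 0)

  nose_x <- c(rep(320, 4), c(300, 310, 320, 330, 340))
  nose_y <- c(200, 220, 240, 255, rep(270, 5))

  eye_hex_x <- c(-20, -10, 10, 20, 10, -10)
  eye_hex_y <- c(0, -8, -8, 0, 8, 8)
  eye_r_x <- 275 + eye_hex_x
  eye_r_y <- 205 + eye_hex_y
  eye_l_x <- 365 + eye_hex_x
  eye_l_y <- 205 + eye_hex_y

  outer_ang <- seq(0, 2 * pi, length.out = 13)[-13]
  mouth_out_x <- 320 + 38 * cos(outer_ang)
  mouth_out_y <- 300 + 18 * sin(outer_ang)
  inner_ang <- seq(0, 2 * pi, length.out = 9)[-9]
  mouth_in_x <- 320 + 22 * cos(inner_ang)
  mouth_in_y <- 300 + 8 * sin(inner_ang)

  x <- c(jaw_x, brow_r_x, brow_l_x, nose_x, eye_r_x, eye_l_x,
         mouth_out_x, mouth_in_x)
  y <- c(jaw_y, brow_y, brow_y, nose_y, eye_r_y, eye_l_y,
         mouth_out_y, mouth_in_y)
  region <- character(68)
  for (nm in names(face_regions())) region[face_regions()[[nm]]] <- nm

  tibble(landmark = 1:68, x = round(x, 3), y = round(y, 3), region = region)
}

#' Named landmark index sets for facial regions
#'
#' @return A named list of integer vectors of 1-based landmark ids:
#'   `jawline` 1-17, `brows` 18-27, `nose` 28-36, `right_eye` 37-42,
#'   `left_eye` 43-48, `mouth` 49-68. The sets are disjoint and cover all
#'   68 landmarks.
#' @export
face_regions <- function() {
  list(
    jawline   = landmark_index(1:17),
    brows     = landmark_index(18:27),
    nose      = landmark_index(28:36),
    right_eye = landmark_index(37:42),
    left_eye  = landmark_index(43:48),
    mouth     = landmark_index(49:68)
  )
}

#' Landmark id of the nose tip
#' @return The integer 34 (1-based iBUG convention).
#' @export
nose_tip_landmark <- function() landmark_index(34)
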