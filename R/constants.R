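#' Fixed size constants of the natural-history model
#'
#' The model anchors tumour volume trajectories to two fixed diameters: the
#' diameter of a single malignant cell, `d_cell` (the size at tumour onset and
#' at metastatic seeding), and the minimum diameter `d0` at which a tumour can
#' be detected at mammography screening. Both are conventions of the model, not
#' estimated parameters. Volumes follow the spherical convention
#' \eqn{v = \pi d^3 / 6} (mm^3).
#'
#' @param d_cell Diameter of a single tumour cell, mm. Default 0.01.
#' @param d0 Minimum screen-detectable tumour diameter, mm. Default 0.5.
#'
#' @return An object of class `nm_constants`: a list with `d_cell`, `d0` and
#'   the derived volumes `v_cell`, `v0` (mm^3).
#' @examples
#' size_constants()
#' @export
size_constants <- function(d_cell = 0.01, d0 = 0.5) {
  stopifnot(is.numeric(d_cell), length(d_cell) == 1L, d_cell > 0,
            is.numeric(d0), length(d0) == 1L, d0 > d_cell)
  structure(
    list(d_cell = d_cell, d0 = d0,
         v_cell = diameter_to_volume(d_cell),
         v0 = diameter_to_volume(d0)),
    class = "nm_constants")
}

#' Convert between tumour diameter and spherical volume
#'
#' @param d Diameter in mm (positive).
#' @param v Volume in mm^3 (positive).
#' @return Volume in mm^3, or diameter in mm.
#' @examples
#' diameter_to_volume(20)           # ~4188.79 mm^3
#' volume_to_diameter(diameter_to_volume(7)) # 7
#' @export
diameter_to_volume <- function(d) {
  if (any(d <= 0)) stop("diameter must be positive")
  pi * d^3 / 6
}

#' @rdname diameter_to_volume
#' @export
volume_to_diameter <- function(v) {
  if (any(v <= 0)) stop("volume must be positive")
  (6 * v / pi)^(1 / 3)
}
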