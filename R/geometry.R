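# Micropattern geometry utilities: how far apart can two points of an
# adhesive island be, and how does that distance scale with island area.

#' Maximum chord of a disc of given area
#'
#' The farthest two points of a circular ("O") micropattern are a
#' diameter apart: `2 * sqrt(area / pi)`. A 1100 um^2 disc gives 37.4 um
#' and a 700 um^2 disc 29.9 um (1 decimal).
#'
#' @param area Pattern area in um^2, `> 0`.
#' @return Maximum point-to-point distance in um.
#' @examples
#' round(disc_max_chord(1100), 1)  # 37.4
#' round(disc_max_chord(700), 1)   # 29.9
#' @export
disc_max_chord <- function(area) {
  if (any(area <= 0)) stop("'area' must be > 0", call. = FALSE)
  2 * sqrt(area / pi)
}

#' Linear-dimension growth between two areas of the same shape
#'
#' Under isotropic scaling every length of a fixed shape grows with the
#' square root of area, so the percent increase in any chord between an
#' `area_small` and an `area_large` pattern is
#' `(sqrt(area_large / area_small) - 1) * 100` - about 25% for
#' 1100 vs 700 um^2, whatever the shape.
#'
#' @param area_large,area_small Pattern areas in um^2, both `> 0`.
#' @return Percent increase of linear dimensions.
#' @examples
#' round(isotropic_scaling_percent(1100, 700))  # 25
#' @export
isotropic_scaling_percent <- function(area_large, area_small) {
  if (any(area_large <= 0) || any(area_small <= 0))
    stop("areas must be > 0", call. = FALSE)
  (sqrt(area_large / area_small) - 1) * 100
}
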