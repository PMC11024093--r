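# Downstream processing of high-content segmentation object tables:
# merge the four per-well data files on their region identifiers and
# apply the single-cell inclusion filters.

#' Circularity shape factor
#'
#' The standard circularity statistic `4 * pi * area / perimeter^2`: 1 for
#' a perfect circle, smaller for elongated outlines (a square gives
#' `pi/4`, a 3:1 rectangle `3*pi/16`).
#'
#' @param area Object area (um^2).
#' @param perimeter Object perimeter (um), `> 0`.
#' @return Dimensionless shape factor in `(0, 1]` for physical outlines.
#' @examples
#' shape_factor(pi * 25, 2 * pi * 5)  # circle of radius 5 -> 1
#' shape_factor(4, 8)                 # unit square -> pi/4
#' @export
shape_factor <- function(area, perimeter) {
  if (any(perimeter <= 0))
    stop("'perimeter' must be > 0", call. = FALSE)
  if (any(area < 0)) stop("'area' must be >= 0", call. = FALSE)
  4 * pi * area / perimeter^2
}

#' Merge the four per-well object tables
#'
#' Joins the calcium-object table (centroid, area, perimeter, shape
#' factor), the nucleus-cell association table (nucleus centroid, nucleus
#' area, nuclei per region), the nucleus-spacing table (minimum distance
#' to any other nucleus, pixels) and the post-stain calcium-object table
#' (centroid) on `region_id`. Regions missing from any file are kept with
#' `NA` in the absent fields and flagged `complete = FALSE`; downstream
#' filtering excludes them because their rules cannot be verified.
#'
#' @param calcium,nuclei,spacing,post Data frames as produced by
#'   [simulate_object_tables()] (or read from delimited text with the
#'   same columns). Each must have a unique `region_id` column.
#' @return Data frame of merged records, one row per region, with a
#'   logical `complete` column.
#' @export
merge_object_tables <- function(calcium, nuclei, spacing, post) {
  tabs <- list(calcium = calcium, nuclei = nuclei, spacing = spacing,
               post = post)
  for (nm in names(tabs)) {
    t <- tabs[[nm]]
    if (is.null(t$region_id))
      stop(sprintf("table '%s' has no region_id column", nm), call. = FALSE)
    if (anyDuplicated(t$region_id))
      stop(sprintf("table '%s' has duplicate region ids", nm),
           call. = FALSE)
  }
  m <- Reduce(function(a, b) merge(a, b, by = "region_id", all = TRUE),
              tabs)
  need <- c("shape_factor", "nucleus_area", "nuclei_in_region",
            "nucleus_min_distance", "calcium_centroid_x",
            "hoechst_centroid_x", "post_centroid_x")
  present <- intersect(need, names(m))
  m$complete <- stats::complete.cases(m[, present, drop = FALSE])
  m[order(m$region_id), , drop = FALSE]
}

# largest Euclidean distance among the three pairwise centroid
# combinations (calcium, Hoechst, post-stain)
max_centroid_diff <- function(rec) {
  pts <- rbind(c(rec$calcium_centroid_x, rec$calcium_centroid_y),
               c(rec$hoechst_centroid_x, rec$hoechst_centroid_y),
               c(rec$post_centroid_x, rec$post_centroid_y))
  max(stats::dist(pts))
}

#' Single-cell inclusion filters
#'
#' Applies the five inclusion rules to merged object records:
#' \describe{
#'   \item{shape_factor}{"O" regions need shape factor `>= 0.9`; "L"
#'     regions need `0.5 <= sf <= 0.85` (both ends inclusive).}
#'   \item{multi_nucleus}{exactly one nucleus in the region.}
#'   \item{nucleus_distance}{nucleus at least 20 pixels from every other
#'     nucleus (inclusive).}
#'   \item{nucleus_area}{nucleus smaller than 300 um^2 (strict; 300 is
#'     excluded).}
#'   \item{centroid_mismatch}{largest pairwise difference among the
#'     calcium, Hoechst and post-stain centroids at most 30 um
#'     (strictly greater than 30 um is excluded).}
#' }
#' A record with missing values in a rule's inputs fails that rule (the
#' rule cannot be verified). The rules are independent, so the inclusion
#' set does not depend on the order of application.
#'
#' @param records Merged records from [merge_object_tables()].
#' @param shape_group `"O"` or `"L"`; selects the shape-factor window.
#' @param um_per_pixel Optional calibration. Supply it when
#'   `nucleus_min_distance` is in micrometres instead of pixels
#'   (`spacing_unit = "um"`); the 20-pixel rule is then applied after
#'   conversion. There is no default calibration.
#' @param spacing_unit Unit of `nucleus_min_distance` in `records`.
#' @return `records` with logical per-rule pass columns
#'   (`pass_shape_factor`, `pass_multi_nucleus`, `pass_nucleus_distance`,
#'   `pass_nucleus_area`, `pass_centroid_mismatch`), a `failed_rules`
#'   comma-separated string and the final `included` flag.
#' @export
apply_filters <- function(records, shape_group = c("O", "L"),
                          um_per_pixel = NULL,
                          spacing_unit = c("pixel", "um")) {
  shape_group <- match.arg(shape_group)
  spacing_unit <- match.arg(spacing_unit)
  dist_px <- records$nucleus_min_distance
  if (spacing_unit == "um") {
    if (is.null(um_per_pixel) || um_per_pixel <= 0)
      stop("supply a positive 'um_per_pixel' to convert nucleus spacing",
           call. = FALSE)
    dist_px <- dist_px / um_per_pixel
  }
  sf <- records$shape_factor
  pass_sf <- if (shape_group == "O") sf >= 0.9 else sf >= 0.5 & sf <= 0.85
  pass_multi <- records$nuclei_in_region == 1
  pass_dist <- dist_px >= 20
  pass_area <- records$nucleus_area < 300
  cd <- vapply(seq_len(nrow(records)),
               function(i) {
                 r <- records[i, ]
                 if (anyNA(c(r$calcium_centroid_x, r$calcium_centroid_y,
                             r$hoechst_centroid_x, r$hoechst_centroid_y,
                             r$post_centroid_x, r$post_centroid_y)))
                   NA_real_
                 else max_centroid_diff(r)
               }, numeric(1))
  pass_cd <- cd <= 30

  # an unverifiable rule (NA inputs) counts as failed
  pass <- cbind(shape_factor = pass_sf %in% TRUE,
                multi_nucleus = pass_multi %in% TRUE,
                nucleus_distance = pass_dist %in% TRUE,
                nucleus_area = pass_area %in% TRUE,
                centroid_mismatch = pass_cd %in% TRUE)
  records$pass_shape_factor <- pass[, "shape_factor"]
  records$pass_multi_nucleus <- pass[, "multi_nucleus"]
  records$pass_nucleus_distance <- pass[, "nucleus_distance"]
  records$pass_nucleus_area <- pass[, "nucleus_area"]
  records$pass_centroid_mismatch <- pass[, "centroid_mismatch"]
  records$max_centroid_diff <- cd
  records$failed_rules <- apply(pass, 1, function(p)
    paste(colnames(pass)[!p], collapse = ","))
  records$included <- rowSums(!pass) == 0
  records
}
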