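#' Per-tract HOLC grade coverage from polygon overlay
#'
#' Computes, for every tract polygon, the percentage of tract area covered
#' by each HOLC grade: `pct_g = 100 * area(tract intersect dissolve(grade g
#' polygons)) / area(tract)`. Same-grade polygons are dissolved (unioned)
#' before intersection so overlapping pieces are never double counted. An
#' optional mask layer (typically water area) is subtracted from both the
#' tract and graded layers first, so percentages refer to land area. The
#' unrated share is the remainder, `pct_u = 100 - sum_g pct_g`.
#'
#' All layers must share one planar (projected) coordinate system;
#' geographic (lon-lat) layers are rejected. Invalid geometries are
#' repaired before overlay.
#'
#' @param tracts A [polygon_layer()] of tract polygons.
#' @param holc A [polygon_layer()] with a `grade` column (A--D).
#' @param mask Optional [polygon_layer()] to subtract (e.g. water).
#' @return A coverage table (see [as_coverage()]), one row per tract.
#' @export
compute_coverage <- function(tracts, holc, mask = NULL) {
  check_planar(tracts, holc)
  if (!is.null(mask)) check_planar(tracts, mask)
  if (!"grade" %in% names(holc)) {
    stop("holc layer must have a grade column", call. = FALSE)
  }

  tract_geoms <- lapply(tracts$geometry, poly_clean)
  mask_u <- if (is.null(mask)) {
    list()
  } else {
    poly_union_all(lapply(mask$geometry, poly_clean))
  }

  grade_geoms <- dissolve_by_grade(holc, mask_u)

  n <- nrow(tracts)
  p <- matrix(0, n, 4, dimnames = list(NULL, HOLC_GRADES))
  drowned <- character(0)
  for (i in seq_len(n)) {
    tg <- tract_geoms[[i]]
    if (length(mask_u) > 0) tg <- poly_op(tg, mask_u, "minus")
    at <- poly_area(tg)
    if (at <= 0) {
      drowned <- c(drowned, as.character(tracts$id[i]))
      next
    }
    for (g in HOLC_GRADES) {
      gg <- grade_geoms[[g]]
      if (length(gg) == 0) next
      p[i, g] <- 100 * poly_area(poly_op(tg, gg, "intersection")) / at
    }
  }
  if (length(drowned) > 0) {
    stop("tract(s) with zero area after mask subtraction: ",
         paste(drowned, collapse = ", "), call. = FALSE)
  }

  # clamp clipper quantization dust and close the composition
  p[p < 0] <- 0
  tot <- rowSums(p)
  over <- tot > 100
  if (any(over)) p[over, ] <- p[over, , drop = FALSE] * (100 / tot[over])
  out <- tibble::tibble(
    tract_id = as.character(tracts$id),
    pct_a = as.numeric(p[, "A"]), pct_b = as.numeric(p[, "B"]),
    pct_c = as.numeric(p[, "C"]), pct_d = as.numeric(p[, "D"]),
    pct_u = pmax(0, 100 - as.numeric(rowSums(p)))
  )
  as_coverage(out)
}

dissolve_by_grade <- function(holc, mask_u = list()) {
  out <- setNames(vector("list", 4), HOLC_GRADES)
  for (g in HOLC_GRADES) {
    polys <- holc$geometry[holc$grade == g]
    u <- poly_union_all(lapply(polys, poly_clean))
    if (length(mask_u) > 0 && length(u) > 0) u <- poly_op(u, mask_u, "minus")
    out[[g]] <- u
  }
  out
}

#' Centroid-based grade assignment (published baseline)
#'
#' Assigns each tract the grade of the HOLC area containing the tract's
#' representative interior point, the point-in-polygon approach used by
#' earlier redlining studies. A guaranteed-interior point is used rather
#' than the raw centroid, which can fall outside concave tracts. Because
#' one tract can intersect several differently graded areas, the grade at
#' the interior point is not necessarily the grade covering the largest
#' tract area.
#'
#' @inheritParams compute_coverage
#' @return A tibble `tract_id, grade`, with `NA` grade when the point
#'   falls in unrated space.
#' @export
centroid_grade <- function(tracts, holc, mask = NULL) {
  check_planar(tracts, holc)
  mask_u <- if (is.null(mask)) {
    list()
  } else {
    poly_union_all(lapply(mask$geometry, poly_clean))
  }
  grade_geoms <- dissolve_by_grade(holc, mask_u)
  grades <- vapply(seq_len(nrow(tracts)), function(i) {
    tg <- poly_clean(tracts$geometry[[i]])
    if (length(mask_u) > 0) tg <- poly_op(tg, mask_u, "minus")
    pt <- representative_point(tg)
    if (anyNA(pt)) return(NA_character_)
    # tie order: worst grade wins if graded areas overlap at the point
    for (g in intersect(TIE_ORDER, HOLC_GRADES)) {
      if (point_in_poly(pt[1], pt[2], grade_geoms[[g]])) return(g)
    }
    NA_character_
  }, character(1))
  tibble::tibble(tract_id = as.character(tracts$id), grade = grades)
}
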