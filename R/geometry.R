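# Low-level planar polygon helpers. Geometries use the polyclip
# representation: a polygon is a list of rings, each ring a list with
# numeric vectors x and y (no repeated closing vertex). Ring nesting uses
# even-odd semantics, so holes are simply additional rings.

#' Construct a polygon layer
#'
#' A polygon layer is a tibble with an `id` column, a `geometry`
#' list-column of planar polygons (lists of rings, each ring a list with
#' `x` and `y`), and optionally a `grade` column restricted to A--D. An
#' attribute `crs` records the coordinate system; overlay operations
#' require planar (projected) coordinates.
#'
#' @param id Character or numeric identifiers.
#' @param geometry List of polygons (each a list of rings).
#' @param grade Optional character vector of HOLC grades.
#' @param crs Coordinate system tag; `"planar"` (default) or a descriptive
#'   string. Tags containing `"4326"`, `"longlat"` or `"geographic"` mark
#'   geographic coordinates and are rejected by overlay operations.
#' @return A tibble of class `holc_polygon_layer`.
#' @export
polygon_layer <- function(id, geometry, grade = NULL, crs = "planar") {
  stopifnot(length(id) == length(geometry))
  out <- tibble::tibble(id = id, geometry = geometry)
  if (!is.null(grade)) {
    if (!all(grade %in% HOLC_GRADES)) {
      stop("grades must be one of ", paste(HOLC_GRADES, collapse = ", "),
           call. = FALSE)
    }
    out$grade <- grade
  }
  attr(out, "crs") <- crs
  class(out) <- c("holc_polygon_layer", class(out))
  out
}

rect_poly <- function(xmin, xmax, ymin, ymax) {
  list(list(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax)))
}

ring_signed_area <- function(r) {
  x <- r$x; y <- r$y
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

# Net area of a polygon (outer rings minus holes), orientation-consistent.
poly_area <- function(p) {
  if (length(p) == 0) return(0)
  abs(sum(vapply(p, ring_signed_area, numeric(1))))
}

# Repair self-intersections / inconsistent orientation.
poly_clean <- function(p) {
  if (length(p) == 0) return(p)
  out <- tryCatch(polyclip::polysimplify(p, filltype = "evenodd"),
                  error = function(e) NULL)
  if (is.null(out)) {
    stop("invalid polygon geometry could not be repaired", call. = FALSE)
  }
  out
}

poly_op <- function(a, b, op) {
  if (length(a) == 0) return(if (op == "union") b else list())
  if (length(b) == 0) {
    return(if (op == "intersection") list() else a)
  }
  polyclip::polyclip(a, b, op = op)
}

# Union of a list of polygons (dissolve).
poly_union_all <- function(polys) {
  polys <- polys[vapply(polys, length, 1L) > 0]
  if (length(polys) == 0) return(list())
  Reduce(function(a, b) poly_op(a, b, "union"), polys)
}

# Even-odd point-in-polygon over all rings; boundary counts as inside.
point_in_poly <- function(x, y, p) {
  if (length(p) == 0) return(FALSE)
  hits <- vapply(p, function(r) {
    polyclip::pointinpolygon(list(x = x, y = y), r)
  }, numeric(1))
  if (any(hits == -1)) return(TRUE)
  sum(hits) %% 2 == 1
}

# Guaranteed-interior representative point. The area centroid is used when
# it falls inside; otherwise the midpoint of the widest interior interval
# of a horizontal scanline through the polygon.
representative_point <- function(p) {
  if (length(p) == 0) return(c(NA_real_, NA_real_))
  a6 <- 0; cx <- 0; cy <- 0
  for (r in p) {
    x <- r$x; y <- r$y
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    cr <- x * yn - xn * y
    a6 <- a6 + sum(cr)
    cx <- cx + sum((x + xn) * cr)
    cy <- cy + sum((y + yn) * cr)
  }
  if (abs(a6) > 1e-12) {
    pt <- c(cx / (3 * a6), cy / (3 * a6))
    if (point_in_poly(pt[1], pt[2], p)) return(pt)
  }
  ys <- unlist(lapply(p, `[[`, "y"))
  y0 <- mean(range(ys))
  for (nudge in c(0, 1e-7, -1e-7, 1e-5, -1e-5)) {
    yl <- y0 + nudge * diff(range(ys))
    xs <- scanline_crossings(p, yl)
    if (length(xs) >= 2 && length(xs) %% 2 == 0) {
      widths <- xs[seq(2, length(xs), 2)] - xs[seq(1, length(xs), 2)]
      i <- which.max(widths)
      return(c((xs[2 * i - 1] + xs[2 * i]) / 2, yl))
    }
  }
  c(NA_real_, NA_real_)
}

scanline_crossings <- function(p, yl) {
  xs <- numeric(0)
  for (r in p) {
    x <- r$x; y <- r$y
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    cross <- (y <= yl & yn > yl) | (yn <= yl & y > yl)
    if (any(cross)) {
      t <- (yl - y[cross]) / (yn[cross] - y[cross])
      xs <- c(xs, x[cross] + t * (xn[cross] - x[cross]))
    }
  }
  sort(xs)
}

check_planar <- function(...) {
  layers <- list(...)
  crss <- unlist(lapply(layers, function(l) attr(l, "crs")))
  geo <- grepl("4326|longlat|geographic", crss, ignore.case = TRUE)
  if (any(geo)) {
    stop("layer uses geographic (lon-lat) coordinates; reproject to a ",
         "planar coordinate system before overlay", call. = FALSE)
  }
  crss <- crss[!is.na(crss)]
  if (length(unique(crss)) > 1) {
    stop("layers have mismatched coordinate systems (",
         paste(unique(crss), collapse = " vs "),
         "); reproject to a common planar system", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read and write polygon layers as GeoJSON
#'
#' Reads a GeoJSON FeatureCollection of Polygon / MultiPolygon features
#' into a [polygon_layer()]. Coordinates are taken as already planar
#' (projected); pass `crs` to tag them otherwise. Multi-ring geometries
#' use even-odd semantics (holes are additional rings).
#'
#' @param path File path.
#' @param grade_property Property name holding the HOLC grade (default
#'   `"holc_grade"`); ignored when absent.
#' @param id_property Property name holding the feature id; defaults to the
#'   feature `id` member or a running index.
#' @param crs Coordinate system tag to attach.
#' @return A [polygon_layer()].
#' @export
read_geojson_layer <- function(path, grade_property = "holc_grade",
                               id_property = NULL, crs = "planar") {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection",
                                 call. = FALSE)
  feats <- gj$features
  geoms <- vector("list", length(feats))
  ids <- character(length(feats))
  grades <- rep(NA_character_, length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    geoms[[i]] <- geojson_to_rings(f$geometry)
    props <- f$properties
    ids[i] <- if (!is.null(id_property) && !is.null(props[[id_property]])) {
      as.character(props[[id_property]])
    } else if (!is.null(f$id)) as.character(f$id) else as.character(i)
    if (!is.null(props[[grade_property]])) {
      grades[i] <- as.character(props[[grade_property]])
    }
  }
  grade <- if (all(is.na(grades))) NULL else grades
  polygon_layer(id = ids, geometry = geoms, grade = grade, crs = crs)
}

geojson_to_rings <- function(g) {
  ring_list <- function(rings) {
    lapply(rings, function(r) {
      m <- do.call(rbind, lapply(r, function(pt) c(pt[[1]], pt[[2]])))
      # drop repeated closing vertex
      if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), ]
      list(x = m[, 1], y = m[, 2])
    })
  }
  switch(g$type,
    Polygon = ring_list(g$coordinates),
    MultiPolygon = do.call(c, lapply(g$coordinates, ring_list)),
    stop("unsupported GeoJSON geometry type: ", g$type, call. = FALSE)
  )
}

#' @rdname read_geojson_layer
#' @param layer A [polygon_layer()].
#' @export
write_geojson_layer <- function(layer, path) {
  feats <- lapply(seq_len(nrow(layer)), function(i) {
    props <- list(id = layer$id[i])
    if ("grade" %in% names(layer)) props$holc_grade <- layer$grade[i]
    coords <- lapply(layer$geometry[[i]], function(r) {
      xs <- c(r$x, r$x[1]); ys <- c(r$y, r$y[1])
      lapply(seq_along(xs), function(j) c(xs[j], ys[j]))
    })
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
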