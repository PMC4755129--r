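#' Exact planar geometry on rectilinear polygons
#'
#' All coverage statistics in this package reduce to areas of unions and
#' intersections of axis-aligned rectilinear polygons in a planar,
#' equal-area coordinate system. A geometry is represented as a *rectset*:
#' a set of axis-aligned rectangles whose union is the region of interest
#' (rectangles may overlap; union semantics apply throughout). On this
#' class of geometries union, intersection and area are computed exactly by
#' a slab sweep over compressed coordinates -- no tolerance, no
#' approximation. Rectilinear GeoJSON polygons (all edges axis-parallel,
#' holes supported) are converted losslessly to rectsets on input.
#'
#' Real-world layers in projected equal-area coordinates whose boundaries
#' are not rectilinear are outside the scope of this engine; the pipeline's
#' geometric statistics are defined on the rectilinear class.
#'
#' @name geometry
#' @keywords internal
NULL

#' Build a rectset from rectangle corner coordinates
#'
#' Vectorized over the four corner arguments: n values build a rectset of n
#' rectangles. Inverted rectangles (min > max) are repaired by swapping;
#' degenerate (zero-area) rectangles are dropped.
#'
#' @param xmin,ymin,xmax,ymax numeric vectors of corner coordinates.
#' @return an object of class `rectset`.
#' @export
rectset <- function(xmin = numeric(), ymin = numeric(),
                    xmax = numeric(), ymax = numeric()) {
  df <- data.frame(xmin = as.numeric(xmin), ymin = as.numeric(ymin),
                   xmax = as.numeric(xmax), ymax = as.numeric(ymax))
  if (nrow(df) > 0) {
    if (!all(is.finite(as.matrix(df)))) {
      stop("rectset coordinates must be finite", call. = FALSE)
    }
    sw <- df$xmin > df$xmax
    df[sw, c("xmin", "xmax")] <- df[sw, c("xmax", "xmin")]
    sw <- df$ymin > df$ymax
    df[sw, c("ymin", "ymax")] <- df[sw, c("ymax", "ymin")]
    df <- df[df$xmax > df$xmin & df$ymax > df$ymin, , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("rectset", "data.frame")
  df
}

#' @rdname rectset
#' @export
is_rectset <- function(x) inherits(x, "rectset")

#' @export
print.rectset <- function(x, ...) {
  cat("rectset:", nrow(x), "rectangle(s), union area", rs_area(x), "\n")
  invisible(x)
}

rs_empty <- function() rectset()

#' Is a rectset empty (zero area)?
#' @param rs a `rectset`.
#' @return logical.
#' @export
rs_is_empty <- function(rs) nrow(rs) == 0

# merge a set of [lo, hi) intervals; returns total covered length and the
# merged intervals themselves
merge_intervals <- function(lo, hi) {
  if (length(lo) == 0) {
    return(list(length = 0, lo = numeric(), hi = numeric()))
  }
  o <- order(lo, hi)
  lo <- lo[o]; hi <- hi[o]
  mlo <- lo[1]; mhi <- hi[1]
  out_lo <- numeric(); out_hi <- numeric()
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= mhi) {
      mhi <- max(mhi, hi[i])
    } else {
      out_lo <- c(out_lo, mlo); out_hi <- c(out_hi, mhi)
      mlo <- lo[i]; mhi <- hi[i]
    }
  }
  out_lo <- c(out_lo, mlo); out_hi <- c(out_hi, mhi)
  list(length = sum(out_hi - out_lo), lo = out_lo, hi = out_hi)
}

#' Exact area of the union of a rectset
#'
#' Slab sweep: x-coordinates are compressed; within each vertical slab the
#' covered y-length is the merged length of the y-intervals of rectangles
#' spanning the slab.
#'
#' @param rs a `rectset`.
#' @return numeric area (0 for an empty set).
#' @export
rs_area <- function(rs) {
  stopifnot(is_rectset(rs))
  if (nrow(rs) == 0) return(0)
  xs <- sort(unique(c(rs$xmin, rs$xmax)))
  total <- 0
  for (i in seq_len(length(xs) - 1)) {
    x0 <- xs[i]; x1 <- xs[i + 1]
    span <- rs$xmin <= x0 & rs$xmax >= x1
    if (!any(span)) next
    m <- merge_intervals(rs$ymin[span], rs$ymax[span])
    total <- total + (x1 - x0) * m$length
  }
  total
}

#' Canonical disjoint form of a rectset
#'
#' Decomposes the union into disjoint slab rectangles in deterministic
#' order (left-to-right slabs, bottom-to-top intervals). Two rectsets with
#' equal union have identical normal forms.
#'
#' @param rs a `rectset`.
#' @return a `rectset` of pairwise-disjoint rectangles.
#' @export
rs_normalize <- function(rs) {
  stopifnot(is_rectset(rs))
  if (nrow(rs) == 0) return(rs)
  xs <- sort(unique(c(rs$xmin, rs$xmax)))
  out <- list()
  for (i in seq_len(length(xs) - 1)) {
    x0 <- xs[i]; x1 <- xs[i + 1]
    span <- rs$xmin <= x0 & rs$xmax >= x1
    if (!any(span)) next
    m <- merge_intervals(rs$ymin[span], rs$ymax[span])
    out[[length(out) + 1]] <- data.frame(xmin = x0, ymin = m$lo,
                                         xmax = x1, ymax = m$hi)
  }
  if (length(out) == 0) return(rs_empty())
  df <- do.call(rbind, out)
  rectset(df$xmin, df$ymin, df$xmax, df$ymax)
}

#' Dissolve (union) geometries into one layer
#'
#' Merges any number of rectsets (or a list of them) into a single union
#' geometry, so overlapping area is counted once. The union area never
#' exceeds the sum of the input areas.
#'
#' @param ... rectsets, or a single list of rectsets.
#' @return a normalized `rectset`.
#' @export
dissolve <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.list(args[[1]]) && !is_rectset(args[[1]])) {
    args <- args[[1]]
  }
  if (length(args) == 0) return(rs_empty())
  ok <- vapply(args, is_rectset, logical(1))
  if (!all(ok)) stop("dissolve() takes rectsets", call. = FALSE)
  df <- do.call(rbind, lapply(args, as.data.frame))
  rs_normalize(rectset(df$xmin, df$ymin, df$xmax, df$ymax))
}

#' @rdname dissolve
#' @export
rs_union <- dissolve

#' Intersection of two rectsets
#'
#' @param a,b rectsets.
#' @return a normalized `rectset` covering the common region.
#' @export
rs_intersect <- function(a, b) {
  stopifnot(is_rectset(a), is_rectset(b))
  if (nrow(a) == 0 || nrow(b) == 0) return(rs_empty())
  ia <- rep(seq_len(nrow(a)), each = nrow(b))
  ib <- rep(seq_len(nrow(b)), times = nrow(a))
  xmin <- pmax(a$xmin[ia], b$xmin[ib])
  xmax <- pmin(a$xmax[ia], b$xmax[ib])
  ymin <- pmax(a$ymin[ia], b$ymin[ib])
  ymax <- pmin(a$ymax[ia], b$ymax[ib])
  keep <- xmax > xmin & ymax > ymin
  rs_normalize(rectset(xmin[keep], ymin[keep], xmax[keep], ymax[keep]))
}

#' Does the union contain a point?
#'
#' Containment is closed on all rectangle edges.
#'
#' @param rs a `rectset`.
#' @param x,y point coordinates.
#' @return logical.
#' @export
rs_contains_point <- function(rs, x, y) {
  stopifnot(is_rectset(rs))
  if (nrow(rs) == 0) return(FALSE)
  any(rs$xmin <= x & x <= rs$xmax & rs$ymin <= y & y <= rs$ymax)
}

#' Representative interior point of a rectset
#'
#' The centre of the first rectangle of the normal form: a deterministic
#' point strictly inside the union. Used to assign a site to the single
#' unit that "holds" it for counting purposes.
#'
#' @param rs a non-empty `rectset`.
#' @return numeric vector `c(x, y)`.
#' @export
rs_rep_point <- function(rs) {
  stopifnot(is_rectset(rs))
  if (nrow(rs) == 0) stop("empty geometry has no interior", call. = FALSE)
  n <- rs_normalize(rs)
  c(x = (n$xmin[1] + n$xmax[1]) / 2, y = (n$ymin[1] + n$ymax[1]) / 2)
}

#' Translate a rectset
#' @param rs a `rectset`.
#' @param dx,dy offsets.
#' @return translated `rectset`.
#' @export
rs_translate <- function(rs, dx = 0, dy = 0) {
  stopifnot(is_rectset(rs))
  rectset(rs$xmin + dx, rs$ymin + dy, rs$xmax + dx, rs$ymax + dy)
}

#' Bounding box of a rectset
#' @param rs a `rectset`.
#' @return numeric vector `c(xmin, ymin, xmax, ymax)` or `NULL` when empty.
#' @export
rs_bbox <- function(rs) {
  stopifnot(is_rectset(rs))
  if (nrow(rs) == 0) return(NULL)
  c(xmin = min(rs$xmin), ymin = min(rs$ymin),
    xmax = max(rs$xmax), ymax = max(rs$ymax))
}

## ---- GeoJSON conversion -------------------------------------------------

# ray-crossing (even-odd) test of point (px, py) against a list of rings;
# exact when the point does not lie on any edge
point_in_rings <- function(px, py, rings) {
  crossings <- 0L
  for (ring in rings) {
    x <- ring[, 1]; y <- ring[, 2]
    n <- length(x)
    if (n < 2) next
    # ensure closure
    if (x[1] != x[n] || y[1] != y[n]) {
      x <- c(x, x[1]); y <- c(y, y[1]); n <- n + 1
    }
    for (i in seq_len(n - 1)) {
      y0 <- y[i]; y1 <- y[i + 1]
      if ((y0 > py) != (y1 > py)) {
        xcross <- x[i] + (py - y0) / (y1 - y0) * (x[i + 1] - x[i])
        if (xcross > px) crossings <- crossings + 1L
      }
    }
  }
  crossings %% 2L == 1L
}

rings_are_rectilinear <- function(rings) {
  for (ring in rings) {
    x <- ring[, 1]; y <- ring[, 2]
    n <- length(x)
    if (x[1] != x[n] || y[1] != y[n]) {
      x <- c(x, x[1]); y <- c(y, y[1]); n <- n + 1
    }
    dx <- diff(x); dy <- diff(y)
    if (any(dx != 0 & dy != 0)) return(FALSE)
  }
  TRUE
}

# convert one GeoJSON polygon (list of rings; first exterior, rest holes)
# to a rectset, exactly, via coordinate compression + even-odd cell test
polygon_to_rectset <- function(rings) {
  rings <- lapply(rings, function(r) {
    m <- if (is.matrix(r)) r else do.call(rbind, lapply(r, unlist))
    storage.mode(m) <- "double"
    m
  })
  if (!rings_are_rectilinear(rings)) {
    stop("polygon is not rectilinear (all edges must be axis-parallel)",
         call. = FALSE)
  }
  xs <- sort(unique(unlist(lapply(rings, function(r) r[, 1]))))
  ys <- sort(unique(unlist(lapply(rings, function(r) r[, 2]))))
  if (length(xs) < 2 || length(ys) < 2) return(rs_empty())
  out <- list()
  for (i in seq_len(length(xs) - 1)) {
    cx <- (xs[i] + xs[i + 1]) / 2
    for (j in seq_len(length(ys) - 1)) {
      cy <- (ys[j] + ys[j + 1]) / 2
      if (point_in_rings(cx, cy, rings)) {
        out[[length(out) + 1]] <- c(xs[i], ys[j], xs[i + 1], ys[j + 1])
      }
    }
  }
  if (length(out) == 0) return(rs_empty())
  m <- do.call(rbind, out)
  rs_normalize(rectset(m[, 1], m[, 2], m[, 3], m[, 4]))
}

geojson_geometry_to_rectset <- function(geom) {
  if (is.null(geom) || is.null(geom$type)) return(rs_empty())
  switch(geom$type,
    Polygon = polygon_to_rectset(geom$coordinates),
    MultiPolygon = {
      parts <- lapply(geom$coordinates, polygon_to_rectset)
      dissolve(parts)
    },
    stop("unsupported GeoJSON geometry type: ", geom$type, call. = FALSE)
  )
}

rectset_to_geojson_geometry <- function(rs) {
  n <- rs_normalize(rs)
  ring_of <- function(x0, y0, x1, y1) {
    list(matrix(c(x0, y0, x1, y0, x1, y1, x0, y1, x0, y0),
                ncol = 2, byrow = TRUE))
  }
  polys <- lapply(seq_len(nrow(n)), function(i) {
    ring_of(n$xmin[i], n$ymin[i], n$xmax[i], n$ymax[i])
  })
  if (length(polys) == 1) {
    list(type = "Polygon", coordinates = polys[[1]])
  } else {
    list(type = "MultiPolygon", coordinates = polys)
  }
}

#' Read a GeoJSON feature layer
#'
#' Reads a FeatureCollection of rectilinear Polygon/MultiPolygon features.
#' Feature properties become data-frame columns; geometries become a
#' `geometry` list-column of rectsets.
#'
#' @param path path to a GeoJSON file.
#' @return data frame with a `geometry` list-column.
#' @export
read_geojson_layer <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection: ", path, call. = FALSE)
  }
  feats <- gj$features
  props <- lapply(feats, function(f) {
    p <- f$properties
    lapply(p, function(v) if (is.null(v)) NA else v)
  })
  keys <- unique(unlist(lapply(props, names)))
  cols <- lapply(keys, function(k) {
    vals <- lapply(props, function(p) if (k %in% names(p)) p[[k]] else NA)
    unlist(lapply(vals, function(v) if (is.null(v)) NA else v))
  })
  names(cols) <- keys
  df <- if (length(cols) > 0) as.data.frame(cols, stringsAsFactors = FALSE)
        else data.frame(row.names = seq_along(feats))
  geoms <- lapply(feats, function(f) {
    g <- f$geometry
    if (!is.null(g$coordinates)) {
      g$coordinates <- simplify_coords(g$coordinates, g$type)
    }
    geojson_geometry_to_rectset(g)
  })
  df$geometry <- I(geoms)
  df
}

simplify_coords <- function(coords, type) {
  ring_to_matrix <- function(ring) {
    do.call(rbind, lapply(ring, function(pt) as.numeric(unlist(pt))))
  }
  if (type == "Polygon") {
    lapply(coords, ring_to_matrix)
  } else if (type == "MultiPolygon") {
    lapply(coords, function(poly) lapply(poly, ring_to_matrix))
  } else {
    coords
  }
}

#' Write a feature layer to GeoJSON
#'
#' @param df data frame with a `geometry` list-column of rectsets; all other
#'   columns are written as feature properties.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_geojson_layer <- function(df, path) {
  stopifnot(is.data.frame(df), "geometry" %in% names(df))
  prop_cols <- setdiff(names(df), "geometry")
  feats <- lapply(seq_len(nrow(df)), function(i) {
    props <- lapply(prop_cols, function(k) {
      v <- df[[k]][i]
      if (is.na(v)) NULL else v
    })
    names(props) <- prop_cols
    props <- props[!vapply(props, is.null, logical(1))]
    list(type = "Feature",
         properties = props,
         geometry = rectset_to_geojson_geometry(df$geometry[[i]]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA,
                       always_decimal = FALSE)
  invisible(path)
}
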