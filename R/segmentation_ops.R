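#' Contour of one labeled object
#'
#' Ordered outer boundary (8-connected tracing) of the largest connected
#' component of a label; holes are ignored. Coordinates are 1-based
#' (row, col) pixel positions.
#'
#' @param frame integer label matrix.
#' @param id label to trace.
#' @return numeric matrix with columns (row, col), one vertex per boundary
#'   pixel, in traversal order.
#' @export
object_contour <- function(frame, id) {
  mask <- frame == id
  if (!any(mask)) stop("label ", id, " not present in frame")
  comp <- label_components(mask)
  sizes <- tabulate(comp[comp > 0L])
  main <- which.max(sizes)
  m <- matrix(as.integer(comp == main), nrow(frame), ncol(frame))
  oc <- EBImage::ocontour(m)[[1L]]
  cbind(oc[, 1L] + 1, oc[, 2L] + 1)   # 0-based -> 1-based (row, col)
}

# Perpendicular distance of points (n x 2) from the line through a and b.
perp_dist <- function(pts, a, b) {
  d <- b - a
  len <- sqrt(sum(d^2))
  if (len == 0) return(sqrt(rowSums(sweep(pts, 2L, a)^2)))
  abs((pts[, 1L] - a[1L]) * d[2L] - (pts[, 2L] - a[2L]) * d[1L]) / len
}

# Douglas-Peucker on an open chain; keeps both endpoints.
dp_chain <- function(pts, eps) {
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  d <- perp_dist(pts[2:(n - 1L), , drop = FALSE], pts[1L, ], pts[n, ])
  i <- which.max(d)
  if (d[i] <= eps) return(pts[c(1L, n), , drop = FALSE])
  k <- i + 1L
  rbind(dp_chain(pts[1:k, , drop = FALSE], eps),
        dp_chain(pts[k:n, , drop = FALSE], eps)[-1L, , drop = FALSE])
}

#' Simplify a closed contour
#'
#' Ramer-Douglas-Peucker simplification of a closed polygon. The curve is
#' split at its first vertex and the vertex farthest from it, each open
#' chain is simplified with the given tolerance, and the halves are
#' rejoined.
#'
#' @param pts contour vertices, (n x 2), in order.
#' @param eps tolerance in pixels: no original vertex ends up farther than
#'   this from the simplified polygon's chords.
#' @return simplified polygon vertices (m x 2), closed implicitly.
#' @export
approx_contour <- function(pts, eps) {
  n <- nrow(pts)
  if (n <= 3L) return(pts)
  d0 <- sqrt(rowSums(sweep(pts, 2L, pts[1L, ])^2))
  j <- which.max(d0)
  a1 <- dp_chain(pts[1:j, , drop = FALSE], eps)
  a2 <- dp_chain(pts[c(j:n, 1L), , drop = FALSE], eps)
  out <- rbind(a1, a2[-1L, , drop = FALSE])
  out[-nrow(out), , drop = FALSE]     # last vertex duplicates the first
}

# Index of the contour vertex equal (or nearest) to point p.
match_vertex <- function(cnt, p) {
  which.min((cnt[, 1L] - p[1L])^2 + (cnt[, 2L] - p[2L])^2)
}

# Total length of a closed polygon.
arc_length <- function(pts) {
  nxt <- rbind(pts[-1L, , drop = FALSE], pts[1L, , drop = FALSE])
  sum(sqrt(rowSums((nxt - pts)^2)))
}

#' Convexity defects of a closed polygon
#'
#' For each edge of the polygon's convex hull, the polygon vertices that
#' sag inside the hull between the edge's endpoints are examined; the
#' deepest one is a convexity defect if its distance from the hull edge
#' reaches `min_depth`. Two facing defects flag the constriction between a
#' merged mother and bud.
#'
#' @param poly polygon vertices (n x 2), in boundary order.
#' @param min_depth minimal meaningful depth in pixels; shallower raster
#'   noise is ignored.
#' @return data frame with one row per defect: hull-edge endpoint indices
#'   `start`, `end`, the defect vertex index `far`, and `depth` (pixels).
#' @export
convexity_defects <- function(poly, min_depth = 1.0) {
  n <- nrow(poly)
  out <- data.frame(start = integer(0), end = integer(0), far = integer(0),
                    depth = numeric(0))
  if (n < 4L) return(out)
  h <- sort(grDevices::chull(poly[, 1L], poly[, 2L]))
  for (k in seq_along(h)) {
    i1 <- h[k]
    i2 <- if (k < length(h)) h[k + 1L] else h[1L]
    between <- if (i2 > i1) seq(i1, i2) else c(seq(i1, n), seq_len(i2))
    inner <- between[-c(1L, length(between))]
    if (!length(inner)) next
    d <- perp_dist(poly[inner, , drop = FALSE], poly[i1, ], poly[i2, ])
    j <- which.max(d)
    if (d[j] >= min_depth)
      out <- rbind(out, data.frame(start = i1, end = i2, far = inner[j],
                                   depth = d[j]))
  }
  out
}

#' Separate a merged object along its constriction
#'
#' Splits one label (typically a mother cell merged with its bud by the
#' segmentation model) into two. The object's outer contour is simplified,
#' the convexity defects of the simplified contour relative to its convex
#' hull are computed, and if exactly two defects are found the pixels are
#' partitioned by the straight line through the two defect points. With a
#' coarse simplification tolerance shallow constrictions disappear
#' entirely, so the tolerance starts at `epsilon_fraction` of the contour
#' length and is halved until exactly two defects (depth >= `min_depth`)
#' emerge; if no tolerance down to 1/64 of the contour length does, the
#' object is deemed unsplittable and the frame is returned unchanged.
#'
#' @param frame integer label matrix.
#' @param target_id label to split.
#' @param epsilon_fraction starting simplification tolerance as a fraction
#'   of the contour length (default 0.10).
#' @param min_depth minimal defect depth in pixels.
#' @return list with `frame` (label matrix), `split` (logical), and on
#'   success `new_id` (the fresh label given to the smaller part; the
#'   larger part keeps `target_id`) plus `defects` (the two defect
#'   vertices, rows of (row, col)).
#' @export
split_object <- function(frame, target_id, epsilon_fraction = 0.10,
                         min_depth = 1.0) {
  if (!any(frame == target_id)) stop("label ", target_id, " not present in frame")
  if (epsilon_fraction <= 0 || epsilon_fraction >= 1)
    stop("'epsilon_fraction' must be in (0, 1)")
  cnt <- object_contour(frame, target_id)
  L <- arc_length(cnt)
  ef <- epsilon_fraction
  found <- NULL
  while (ef >= epsilon_fraction / 64 - 1e-12) {
    ap <- approx_contour(cnt, ef * L)
    dfs <- convexity_defects(ap, min_depth = min_depth)
    if (nrow(dfs) == 2L) {
      # refine each defect to the deepest original-contour point inside its
      # hull gap (the simplified polygon locates the gap; the raw contour
      # locates the constriction corner within it)
      found <- t(vapply(seq_len(2L), function(k) {
        a <- ap[dfs$start[k], ]; b <- ap[dfs$end[k], ]
        ia <- match_vertex(cnt, a); ib <- match_vertex(cnt, b)
        arc <- if (ia <= ib) seq(ia, ib) else c(seq(ia, nrow(cnt)), seq_len(ib))
        inner <- arc[-c(1L, length(arc))]
        if (!length(inner)) return(ap[dfs$far[k], ])
        d <- perp_dist(cnt[inner, , drop = FALSE], a, b)
        cnt[inner[which.max(d)], ]
      }, numeric(2)))
      break
    }
    ef <- ef / 2
  }
  if (is.null(found)) return(list(frame = frame, split = FALSE))

  p1 <- found[1L, ]; p2 <- found[2L, ]
  coords <- label_coords(frame, target_id)
  side <- (coords[, 1L] - p1[1L]) * (p2[2L] - p1[2L]) -
          (coords[, 2L] - p1[2L]) * (p2[1L] - p1[1L])
  n_pos <- sum(side > 0); n_neg <- sum(side < 0)
  if (n_pos == 0L || n_neg == 0L) return(list(frame = frame, split = FALSE))
  # pixels exactly on the chord go with the larger side
  on_chord_to_pos <- n_pos >= n_neg
  pos <- side > 0 | (side == 0 & on_chord_to_pos)
  new_id <- max(frame) + 1L
  out <- frame
  # the larger fragment keeps the original identity
  keep_pos <- sum(pos) >= sum(!pos)
  sel_new <- if (keep_pos) !pos else pos
  out[coords[sel_new, , drop = FALSE]] <- new_id
  list(frame = out, split = TRUE, new_id = new_id, defects = found)
}

#' Geometric properties of every labeled object
#'
#' @param frame integer label matrix.
#' @return data frame with one row per label: `id`, `area` (pixels),
#'   `solidity` (object pixels / convex-hull pixels, in (0, 1]) and
#'   `elongation` (major / minor axis of the second-moment ellipse; `Inf`
#'   for degenerate single-pixel-wide objects).
#' @export
object_props <- function(frame) {
  ids <- frame_labels(frame)
  res <- data.frame(id = ids, area = NA_real_, solidity = NA_real_,
                    elongation = NA_real_)
  for (k in seq_along(ids)) {
    coords <- label_coords(frame, ids[k])
    a <- nrow(coords)
    res$area[k] <- a
    res$solidity[k] <- a / convex_hull_pixels(coords)
    res$elongation[k] <- moment_elongation(coords)
  }
  res
}

# Number of pixels whose centers lie inside (or on) the convex hull of the
# object's pixel centers, by row-wise scanline over the hull polygon.
convex_hull_pixels <- function(coords) {
  if (nrow(coords) <= 2L) return(nrow(coords))
  h <- grDevices::chull(coords[, 1L], coords[, 2L])
  hull <- coords[h, , drop = FALSE]
  nh <- nrow(hull)
  if (nh <= 2L) return(nrow(unique(coords)))
  rows <- seq(min(hull[, 1L]), max(hull[, 1L]))
  total <- 0L
  eps <- 1e-9
  for (r in rows) {
    xs <- numeric(0)
    for (k in seq_len(nh)) {
      a <- hull[k, ]; b <- hull[if (k == nh) 1L else k + 1L, ]
      if (a[1L] == b[1L]) {
        if (a[1L] == r) xs <- c(xs, a[2L], b[2L])
      } else if (r >= min(a[1L], b[1L]) && r <= max(a[1L], b[1L])) {
        t <- (r - a[1L]) / (b[1L] - a[1L])
        xs <- c(xs, a[2L] + t * (b[2L] - a[2L]))
      }
    }
    if (length(xs))
      total <- total + max(0L, floor(max(xs) + eps) - ceiling(min(xs) - eps) + 1L)
  }
  total
}

# Major/minor axis ratio from second central moments of the pixel coords.
moment_elongation <- function(coords) {
  if (nrow(coords) == 1L) return(1.0)
  mu <- colMeans(coords)
  xc <- coords[, 1L] - mu[1L]; yc <- coords[, 2L] - mu[2L]
  m20 <- mean(xc^2); m02 <- mean(yc^2); m11 <- mean(xc * yc)
  tr <- m20 + m02
  det <- sqrt(max(0, (m20 - m02)^2 + 4 * m11^2))
  l1 <- (tr + det) / 2
  l2 <- (tr - det) / 2
  if (l2 <= 1e-12) return(Inf)
  sqrt(l1 / l2)
}

#' Remove false-positive objects
#'
#' Post-processing filter for segmentation output: an object is erased
#' (set to background) when its area is below `min_size`, its solidity is
#' below `min_solidity`, or its elongation exceeds `max_elongation`.
#' Surviving objects are untouched, so the filter is idempotent, and
#' tightening any parameter can only remove more objects.
#'
#' @param frame integer label matrix.
#' @param min_size minimal area in pixels.
#' @param min_solidity minimal solidity in `[0, 1]`.
#' @param max_elongation maximal major/minor axis ratio (>= 1).
#' @return filtered label matrix.
#' @export
filter_false_positives <- function(frame, min_size = 0, min_solidity = 0,
                                   max_elongation = Inf) {
  if (min_size < 0) stop("'min_size' must be >= 0")
  props <- object_props(frame)
  kill <- props$id[props$area < min_size | props$solidity < min_solidity |
                     props$elongation > max_elongation]
  out <- frame
  out[out %in% kill] <- 0L
  out
}
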