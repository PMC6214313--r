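# Planar geometry primitives for the spatial adapter. All coordinates are
# projected planar units; polygons are matrices with columns x, y holding one
# exterior ring (open: last vertex != first).

close_ring <- function(p) {
  if (!all(p[1, ] == p[nrow(p), ])) p <- rbind(p, p[1, , drop = FALSE])
  p
}

open_ring <- function(p) {
  if (nrow(p) > 1 && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  p
}

poly_signed_area <- function(p) {
  p <- open_ring(p)
  x <- p[, 1]; y <- p[, 2]
  j <- c(seq_len(nrow(p))[-1], 1)
  sum(x * y[j] - x[j] * y) / 2
}

#' Polygon area (shoelace formula)
#' @param p numeric matrix with columns x, y (one ring, open or closed)
#' @return non-negative area in squared coordinate units
#' @export
poly_area <- function(p) abs(poly_signed_area(p))

ensure_ccw <- function(p) {
  if (poly_signed_area(p) < 0) p[rev(seq_len(nrow(p))), , drop = FALSE] else p
}

# Drop duplicate consecutive vertices (within tol); the zero-buffer-style
# repair pass applied before any predicate.
repair_ring <- function(p, tol = 1e-12) {
  p <- open_ring(as.matrix(p))
  if (nrow(p) < 2) return(p)
  keep <- rep(TRUE, nrow(p))
  for (i in seq_len(nrow(p))) {
    if (!keep[i]) next
    j <- if (i == nrow(p)) 1 else i + 1
    if (sum((p[i, ] - p[j, ])^2) <= tol^2 && i != j) keep[j] <- FALSE
  }
  p[keep, , drop = FALSE]
}

ring_valid <- function(p) {
  p <- open_ring(p)
  n <- nrow(p)
  if (n < 3 || poly_area(p) == 0) return(FALSE)
  pc <- close_ring(p)
  # non-adjacent boundary segments must not cross
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1 || (i == 1 && j == n)) next
      if (segs_properly_intersect(pc[i, ], pc[i + 1, ], pc[j, ], pc[j + 1, ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

cross2 <- function(o, a, b) {
  (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
}

segs_properly_intersect <- function(p1, p2, q1, q2, eps = 1e-12) {
  d1 <- cross2(q1, q2, p1); d2 <- cross2(q1, q2, p2)
  d3 <- cross2(p1, p2, q1); d4 <- cross2(p1, p2, q2)
  (d1 * d2 < -eps) && (d3 * d4 < -eps)
}

point_seg_dist <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt(sum((p - a)^2)))
  t <- max(0, min(1, sum((p - a) * ab) / len2))
  sqrt(sum((p - (a + t * ab))^2))
}

seg_seg_dist <- function(p1, p2, q1, q2) {
  if (segs_properly_intersect(p1, p2, q1, q2)) return(0)
  min(point_seg_dist(p1, q1, q2), point_seg_dist(p2, q1, q2),
      point_seg_dist(q1, p1, p2), point_seg_dist(q2, p1, p2))
}

# Length of the overlap of two collinear segments; 0 when not collinear.
collinear_overlap_length <- function(p1, p2, q1, q2, tol = 1e-9) {
  d <- p2 - p1
  len <- sqrt(sum(d^2))
  if (len < tol) return(0)
  u <- d / len
  # q1, q2 must lie on the supporting line of p1-p2
  if (abs(cross2(p1, p2, q1)) / len > tol) return(0)
  if (abs(cross2(p1, p2, q2)) / len > tol) return(0)
  t1 <- sum((q1 - p1) * u)
  t2 <- sum((q2 - p1) * u)
  lo <- max(0, min(t1, t2))
  hi <- min(len, max(t1, t2))
  max(0, hi - lo)
}

point_in_poly <- function(p, poly, tol = 1e-9) {
  poly <- open_ring(poly)
  n <- nrow(poly)
  pc <- close_ring(poly)
  for (i in seq_len(n)) {               # boundary counts as inside
    if (point_seg_dist(p, pc[i, ], pc[i + 1, ]) <= tol) return(TRUE)
  }
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > p[2]) != (yj > p[2]) &&
        p[1] < (xj - xi) * (p[2] - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

is_convex_poly <- function(p, tol = 1e-9) {
  p <- ensure_ccw(open_ring(p))
  n <- nrow(p)
  if (n < 3) return(FALSE)
  pc <- rbind(p, p[1:2, , drop = FALSE])
  for (i in seq_len(n)) {
    if (cross2(pc[i, ], pc[i + 1, ], pc[i + 2, ]) < -tol) return(FALSE)
  }
  TRUE
}

# Sutherland-Hodgman: clip an arbitrary simple polygon against a CONVEX clip
# polygon. Returns an open ring (possibly with 0 rows).
clip_polygon_convex <- function(subject, clip) {
  clip <- ensure_ccw(open_ring(clip))
  out <- open_ring(subject)
  nc <- nrow(clip)
  cc <- close_ring(clip)
  for (i in seq_len(nc)) {
    a <- cc[i, ]; b <- cc[i + 1, ]
    input <- out
    if (nrow(input) == 0) break
    out <- matrix(numeric(0), ncol = 2)
    ic <- close_ring(input)
    for (k in seq_len(nrow(input))) {
      cur <- ic[k, ]; nxt <- ic[k + 1, ]
      cur_in <- cross2(a, b, cur) >= -1e-12
      nxt_in <- cross2(a, b, nxt) >= -1e-12
      if (cur_in) out <- rbind(out, cur)
      if (cur_in != nxt_in) {
        d1 <- cross2(a, b, cur)
        d2 <- cross2(a, b, nxt)
        t <- d1 / (d1 - d2)
        out <- rbind(out, cur + t * (nxt - cur))
      }
    }
  }
  if (nrow(out) >= 3) repair_ring(out) else matrix(numeric(0), ncol = 2)
}

polygon_bbox <- function(p) {
  c(xmin = min(p[, 1]), ymin = min(p[, 2]),
    xmax = max(p[, 1]), ymax = max(p[, 2]))
}

bboxes_overlap <- function(a, b, tol = 0) {
  a["xmin"] <= b["xmax"] + tol && b["xmin"] <= a["xmax"] + tol &&
    a["ymin"] <= b["ymax"] + tol && b["ymin"] <= a["ymax"] + tol
}

# Minimum Euclidean distance between two polygon boundaries; 0 when they
# touch, cross, or one contains the other.
polygon_boundary_distance <- function(a, b) {
  a <- close_ring(open_ring(a)); b <- close_ring(open_ring(b))
  if (point_in_poly(a[1, ], b) || point_in_poly(b[1, ], a)) return(0)
  best <- Inf
  for (i in seq_len(nrow(a) - 1)) {
    for (j in seq_len(nrow(b) - 1)) {
      d <- seg_seg_dist(a[i, ], a[i + 1, ], b[j, ], b[j + 1, ])
      if (d < best) best <- d
      if (best == 0) return(0)
    }
  }
  best
}

# Convenience constructor for axis-aligned rectangles.
#' Axis-aligned rectangle ring
#' @param xmin,ymin,xmax,ymax rectangle bounds
#' @return 4x2 coordinate matrix (counter-clockwise, open ring)
#' @export
rect_ring <- function(xmin, ymin, xmax, ymax) {
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}
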