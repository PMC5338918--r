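#' Polygon geometry helpers
#'
#' Small exact-geometry utilities used throughout: \code{polygonArea()} is
#' the shoelace area of a closed polygon, \code{polygonPerimeter()} its
#' boundary length (the last vertex is joined back to the first), and
#' \code{regularPolygon()} builds a regular n-gon, the discretized circle
#' used by the circularity checks.
#'
#' @param poly two-column matrix of vertices (the ring is closed
#'   implicitly; a repeated first vertex at the end is tolerated).
#' @return \code{polygonArea()} and \code{polygonPerimeter()} return a
#'   single number; \code{regularPolygon()} a two-column matrix.
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' polygonArea(sq)       # 1
#' polygonPerimeter(sq)  # 4
#' @export
polygonArea <- function(poly) {
  poly <- dropClosingVertex(poly)
  x <- poly[, 1]; y <- poly[, 2]
  i2 <- c(2:length(x), 1L)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

#' @rdname polygonArea
#' @export
polygonPerimeter <- function(poly) {
  poly <- dropClosingVertex(poly)
  i2 <- c(2:nrow(poly), 1L)
  sum(sqrt((poly[i2, 1] - poly[, 1])^2 + (poly[i2, 2] - poly[, 2])^2))
}

#' @rdname polygonArea
#' @param n number of vertices.
#' @param radius circumradius.
#' @param center centre of the polygon.
#' @export
regularPolygon <- function(n, radius = 1, center = c(0, 0)) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

dropClosingVertex <- function(poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  if (n > 1 && all(poly[1, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  poly
}

# Ramer-Douglas-Peucker simplification of an open polyline; keeps endpoints.
simplifyPolyline <- function(pts, tol) {
  n <- nrow(pts)
  if (n <= 2 || tol <= 0) return(pts)
  keep <- logical(n)
  keep[c(1L, n)] <- TRUE
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1]; j <- seg[2]
    if (j - i < 2) next
    a <- pts[i, ]; b <- pts[j, ]
    ab <- b - a
    len2 <- sum(ab^2)
    idx <- (i + 1L):(j - 1L)
    if (len2 == 0) {
      d <- sqrt((pts[idx, 1] - a[1])^2 + (pts[idx, 2] - a[2])^2)
    } else {
      # perpendicular distance to the segment's supporting line
      d <- abs(ab[2] * (pts[idx, 1] - a[1]) - ab[1] * (pts[idx, 2] - a[2])) /
        sqrt(len2)
    }
    k <- which.max(d)
    if (d[k] > tol) {
      m <- idx[k]
      keep[m] <- TRUE
      stack[[length(stack) + 1L]] <- c(i, m)
      stack[[length(stack) + 1L]] <- c(m, j)
    }
  }
  pts[keep, , drop = FALSE]
}

# Simplify a closed ring: anchor at the vertex farthest from the ring
# centroid (and its antipode) so endpoints are stable, then RDP both halves.
simplifyRing <- function(poly, tol) {
  poly <- dropClosingVertex(poly)
  n <- nrow(poly)
  if (n <= 4 || tol <= 0) return(poly)
  ctr <- colMeans(poly)
  a <- which.max((poly[, 1] - ctr[1])^2 + (poly[, 2] - ctr[2])^2)
  poly <- poly[c(a:n, seq_len(a - 1L)), , drop = FALSE]
  b <- 1L + which.max((poly[, 1] - poly[1, 1])^2 + (poly[, 2] - poly[1, 2])^2) - 1L
  if (b <= 1L || b >= n) b <- n %/% 2L
  h1 <- simplifyPolyline(poly[1:b, , drop = FALSE], tol)
  h2 <- simplifyPolyline(poly[c(b:n, 1L), , drop = FALSE], tol)
  rbind(h1, h2[-c(1L, nrow(h2)), , drop = FALSE])
}

# Marching-squares contours of a binary matrix (pixel centres at
# (i - 0.5) * pixelSize). The matrix is zero-padded so outer boundaries
# close. Returns a list of rings in micrometre coordinates, largest first.
maskContours <- function(mask, pixelSize = 1) {
  m <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- (mask > 0) * 1
  xs <- (seq_len(nrow(m)) - 1.5) * pixelSize
  ys <- (seq_len(ncol(m)) - 1.5) * pixelSize
  cl <- grDevices::contourLines(xs, ys, m, levels = 0.5)
  if (!length(cl)) return(list())
  rings <- lapply(cl, function(cc) dropClosingVertex(cbind(cc$x, cc$y)))
  rings[order(vapply(rings, polygonArea, 0), decreasing = TRUE)]
}

# Largest contour ring of a binary mask, optionally RDP-simplified.
traceMask <- function(mask, pixelSize = 1, simplifyTol = 0) {
  rings <- maskContours(mask, pixelSize)
  if (!length(rings)) stop("mask is empty; no contour to trace")
  ring <- rings[[1L]]
  if (simplifyTol > 0) ring <- simplifyRing(ring, simplifyTol)
  ring
}

# Sutherland-Hodgman clip of a ring to the half-plane y <= ymax.
clipRingBelow <- function(poly, ymax) {
  poly <- dropClosingVertex(poly)
  n <- nrow(poly)
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(n)) {
    p <- poly[i, ]
    q <- poly[if (i == n) 1L else i + 1L, ]
    pin <- p[2] <= ymax
    qin <- q[2] <= ymax
    if (pin) out <- rbind(out, p)
    if (xor(pin, qin)) {
      t <- (ymax - p[2]) / (q[2] - p[2])
      out <- rbind(out, c(p[1] + t * (q[1] - p[1]), ymax))
    }
  }
  out
}

# Distance (in pixels) from every pixel centre to the nearest cell-cell or
# cell-background interface pixel of a label image. Interface pixels are
# pixels whose 4-neighbourhood contains a different label (background
# included); they are at distance 0.
interfaceDistance <- function(label) {
  nx <- nrow(label); ny <- ncol(label)
  iface <- matrix(FALSE, nx, ny)
  d <- label[-nx, ] != label[-1, ]
  iface[-nx, ][d] <- TRUE; iface[-1, ][d] <- TRUE
  d <- label[, -ny] != label[, -1]
  iface[, -ny][d] <- TRUE; iface[, -1][d] <- TRUE
  # image edge counts as interface for foreground pixels there
  iface[c(1, nx), ][label[c(1, nx), ] > 0] <- TRUE
  iface[, c(1, ny)][label[, c(1, ny)] > 0] <- TRUE
  dm <- EBImage::distmap(EBImage::Image(1 - iface))
  matrix(EBImage::imageData(dm), nx, ny)
}

# Edge-adjacency pairs of a label image: unique (a, b) label pairs, a < b,
# sharing a pixel edge; 0 is background.
labelAdjacency <- function(label) {
  nx <- nrow(label); ny <- ncol(label)
  a <- c(label[-nx, ], label[, -ny])
  b <- c(label[-1, ], label[, -1])
  keep <- a != b
  a2 <- pmin(a[keep], b[keep]); b2 <- pmax(a[keep], b[keep])
  unique(cbind(a2, b2))
}
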