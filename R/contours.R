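#' Planar closed contour
#'
#' One closed polygon on an axial slice, in patient millimetres. Closure is
#' implicit: the first point is not repeated.
#'
#' @param z mm slice position.
#' @param points n x 2 matrix of (x, y) mm vertices, n >= 3.
#' @return An object of class \code{planar_contour}.
#' @export
planar_contour <- function(z, points) {
  points <- matrix(as.numeric(points), ncol = 2)
  if (nrow(points) < 3L) stop("a contour needs at least 3 points")
  if (abs(shoelace_area(points)) <= 0) stop("contour encloses zero area")
  structure(list(z = as.numeric(z), points = points), class = "planar_contour")
}

#' Signed polygon area (shoelace formula)
#'
#' @param points n x 2 matrix of vertices (implicitly closed).
#' @return Signed area in mm^2 (positive = counter-clockwise).
#' @export
shoelace_area <- function(points) {
  x <- points[, 1]; y <- points[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

#' Set of planar contours with a boundary dialect
#'
#' The DICOM-RT transfer currency: a named stack of closed planar contours.
#' The dialect records which boundary convention produced the polygons:
#' \code{"voxel_edge"} contours follow the outer edges of the bordering
#' voxels (staircase polygons, as in software whose volumes follow the tumor
#' bordering voxels), \code{"voxel_center"} contours pass through the
#' centers of the boundary voxels (as in software whose contours cut across
#' the frontline voxels).
#'
#' @param name ROI name.
#' @param contours list of \code{\link{planar_contour}}.
#' @param dialect \code{"voxel_edge"} or \code{"voxel_center"}.
#' @param frame_uid DICOM frame-of-reference UID string.
#' @param skipped number of degenerate per-slice components (< 3 distinct
#'   boundary centers) that could not be represented as polygons.
#' @return An object of class \code{contour_set}.
#' @export
contour_set <- function(name, contours, dialect = c("voxel_edge", "voxel_center"),
                        frame_uid = "2.25.0", skipped = 0L) {
  dialect <- match.arg(dialect)
  stopifnot(all(vapply(contours, inherits, logical(1), "planar_contour")))
  structure(list(name = name, contours = contours, dialect = dialect,
                 frame_uid = frame_uid, skipped = as.integer(skipped)),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("<contour_set> '%s': %d contours (%s dialect)%s\n",
              x$name, length(x$contours), x$dialect,
              if (x$skipped > 0) sprintf(", %d degenerate component(s) skipped", x$skipped) else ""))
  invisible(x)
}

#' Convert a binary mask to planar contours
#'
#' Traces, per axial slice and per 4-connected in-plane component, the outer
#' boundary of the mask. Under the \code{voxel_edge} dialect the polygon
#' runs along the outer voxel-box edges (vertices at voxel corners); under
#' \code{voxel_center} it passes through the centers of the boundary voxels
#' (Moore boundary tracing). Holes are ignored (outer boundary only), and
#' components whose center path has fewer than 3 distinct points or zero
#' area are skipped and counted in the result's \code{skipped} field.
#'
#' @param mask a non-empty \code{\link{binary_mask}}.
#' @param dialect \code{"voxel_edge"} or \code{"voxel_center"}.
#' @param name ROI name for the resulting set.
#' @return A \code{\link{contour_set}}.
#' @export
mask_to_contours <- function(mask, dialect = c("voxel_edge", "voxel_center"),
                             name = "MTV") {
  dialect <- match.arg(dialect)
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$member)) stop("cannot contour an empty mask")
  g <- mask$grid
  contours <- list()
  skipped <- 0L
  zs <- grid_centers_1d(g, 3)
  for (k in seq_len(g$dims[3])) {
    sl <- matrix(mask$member[, , k], g$dims[1], g$dims[2])
    if (!any(sl)) next
    if (dialect == "voxel_edge") {
      polys <- trace_edge_polygons(sl, g)
      for (p in polys) contours[[length(contours) + 1L]] <- planar_contour(zs[k], p)
    } else {
      comps <- label_components_2d(sl)
      for (cid in seq_len(max(comps))) {
        cm <- comps == cid
        pts <- trace_center_path(cm, g)
        if (is.null(pts) || nrow(pts) < 3L || abs(shoelace_area(pts)) <= 1e-12) {
          skipped <- skipped + 1L
        } else {
          contours[[length(contours) + 1L]] <- planar_contour(zs[k], pts)
        }
      }
    }
  }
  if (length(contours) == 0L && skipped > 0L)
    warning("all in-plane components were degenerate; empty contour set")
  contour_set(name, contours, dialect, skipped = skipped)
}

## 4-connected labeling of a 2-D logical matrix (two-pass not needed: BFS)
label_components_2d <- function(m) {
  d <- dim(m)
  lab <- matrix(0L, d[1], d[2])
  cur <- 0L
  todo <- which(m & lab == 0L)
  while (length(todo) > 0L) {
    cur <- cur + 1L
    frontier <- todo[1L]
    lab[frontier] <- cur
    while (length(frontier) > 0L) {
      i <- (frontier - 1L) %% d[1] + 1L
      j <- (frontier - 1L) %/% d[1] + 1L
      nxt <- integer(0)
      for (o in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        ii <- i + o[1]; jj <- j + o[2]
        ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2]
        lin <- (jj[ok] - 1L) * d[1] + ii[ok]
        nxt <- c(nxt, lin[m[lin] & lab[lin] == 0L])
      }
      nxt <- unique(nxt)
      lab[nxt] <- cur
      frontier <- nxt
    }
    todo <- which(m & lab == 0L)
  }
  lab
}

## voxel_edge polygons for one slice: chain directed boundary edges
## (interior kept on the left); returns list of n x 2 mm matrices for
## counter-clockwise (outer) loops; clockwise hole loops are dropped.
trace_edge_polygons <- function(sl, g) {
  d <- dim(sl)
  ins <- which(sl, arr.ind = TRUE)  # 1-based (i,j)
  # vertices on the doubled lattice: corner (i-1/2, j-1/2) -> (2i-1, 2j-1)
  M <- 2L * max(d) + 3L
  vkey <- function(a, b) (a + 1L) * M + (b + 1L)  # a,b in 0..2n
  edges_from <- new.env(hash = TRUE, parent = emptyenv())
  add_edge <- function(a1, b1, a2, b2) {
    k <- as.character(vkey(a1, b1))
    cur <- if (is.null(edges_from[[k]])) list() else edges_from[[k]]
    cur[[length(cur) + 1L]] <- c(a1, b1, a2, b2, 0)  # 0 = unused
    edges_from[[k]] <- cur
  }
  has_px <- function(i, j) i >= 1L && i <= d[1] && j >= 1L && j <= d[2] && sl[i, j]
  for (r in seq_len(nrow(ins))) {
    i <- ins[r, 1]; j <- ins[r, 2]
    bl <- c(2L * i - 1L, 2L * j - 1L); br <- c(2L * i + 1L, 2L * j - 1L)
    tr <- c(2L * i + 1L, 2L * j + 1L); tl <- c(2L * i - 1L, 2L * j + 1L)
    if (!has_px(i - 1L, j)) add_edge(tl[1], tl[2], bl[1], bl[2])  # left, dir -y
    if (!has_px(i + 1L, j)) add_edge(br[1], br[2], tr[1], tr[2])  # right, dir +y
    if (!has_px(i, j - 1L)) add_edge(bl[1], bl[2], br[1], br[2])  # bottom, dir +x
    if (!has_px(i, j + 1L)) add_edge(tr[1], tr[2], tl[1], tl[2])  # top, dir -x
  }
  all_keys <- sort(ls(edges_from))
  polys <- list()
  for (k0 in all_keys) {
    repeat {
      elist <- edges_from[[k0]]
      start_idx <- which(vapply(elist, function(e) e[5] == 0, logical(1)))[1]
      if (is.na(start_idx)) break
      e <- elist[[start_idx]]; elist[[start_idx]][5] <- 1; edges_from[[k0]] <- elist
      loop <- list(e[1:2])
      cur <- e[3:4]
      prev_dir <- e[3:4] - e[1:2]
      guard <- 0L
      while (!(cur[1] == e[1] && cur[2] == e[2])) {
        guard <- guard + 1L
        if (guard > 10 * length(all_keys) + 1000L) stop("contour tracing failed to close")
        loop[[length(loop) + 1L]] <- cur
        kk <- as.character(vkey(cur[1], cur[2]))
        cand <- edges_from[[kk]]
        unused <- which(vapply(cand, function(x) x[5] == 0, logical(1)))
        if (length(unused) == 0L) stop("contour tracing dead end")
        if (length(unused) > 1L) {
          # ambiguous (checkerboard) vertex: take the sharpest right turn,
          # keeping the loop maximally tight
          turns <- vapply(unused, function(u) {
            dd <- cand[[u]][3:4] - cand[[u]][1:2]
            prev_dir[1] * dd[2] - prev_dir[2] * dd[1]  # cross z; right turn < 0
          }, numeric(1))
          pick <- unused[order(turns)[1]]
        } else pick <- unused
        nxt <- cand[[pick]]
        cand[[pick]][5] <- 1; edges_from[[kk]] <- cand
        prev_dir <- nxt[3:4] - nxt[1:2]
        cur <- nxt[3:4]
      }
      pts <- do.call(rbind, loop)
      # doubled-lattice corner (a,b) -> mm: origin + ((a-2)/2)*s since
      # a = 2i+/-1 with 1-based i corresponds to 0-based index (a-2)/2... (see tests)
      mmx <- g$origin[1] + ((pts[, 1] - 2) / 2) * g$spacing[1]
      mmy <- g$origin[2] + ((pts[, 2] - 2) / 2) * g$spacing[2]
      poly <- cbind(mmx, mmy)
      if (shoelace_area(poly) > 0) polys[[length(polys) + 1L]] <- poly
    }
  }
  polys
}

## Moore boundary tracing of one 4-connected 2-D component; returns the
## ordered boundary-voxel centers in mm (consecutive duplicates removed),
## or NULL for degenerate components.
trace_center_path <- function(cm, g) {
  d <- dim(cm)
  ins <- which(cm)
  if (length(ins) == 0L) return(NULL)
  if (length(ins) == 1L) return(NULL)
  # start: smallest j, then smallest i
  ij <- cbind((ins - 1L) %% d[1] + 1L, (ins - 1L) %/% d[1] + 1L)
  o <- order(ij[, 2], ij[, 1])
  start <- ij[o[1], ]
  # Moore neighborhood in clockwise order starting from W
  moore <- rbind(c(-1, 0), c(-1, -1), c(0, -1), c(1, -1),
                 c(1, 0), c(1, 1), c(0, 1), c(-1, 1))
  inside <- function(p) p[1] >= 1 && p[1] <= d[1] && p[2] >= 1 && p[2] <= d[2] && cm[p[1], p[2]]
  path <- list(start)
  # initial backtrack: the W neighbor (outside by start choice of min j? use S)
  back <- start + c(0, -1)   # pixel below is outside by construction
  cur <- start
  first_next <- NULL
  repeat {
    # scan Moore neighbors clockwise starting after the backtrack position
    rel <- back - cur
    sidx <- which(moore[, 1] == rel[1] & moore[, 2] == rel[2])
    found <- NULL
    for (s in 1:8) {
      idx <- ((sidx - 1L + s) %% 8L) + 1L
      cand <- cur + moore[idx, ]
      if (inside(cand)) { found <- cand; break }
      back_cand <- cand
    }
    if (is.null(found)) return(NULL)  # isolated pixel
    prev <- cur
    # backtrack = last outside neighbor visited before found
    bidx <- ((sidx - 1L + s - 1L) %% 8L) + 1L
    back <- cur + moore[bidx, ]
    cur <- found
    if (is.null(first_next)) {
      first_next <- cur
    } else if (all(cur == first_next) && all(prev == start)) {
      break  # Jacob's stopping criterion
    }
    path[[length(path) + 1L]] <- cur
    if (length(path) > 4L * length(ins) + 8L) break
  }
  ijm <- do.call(rbind, path)
  # drop the final repeat of the start if present
  if (nrow(ijm) > 1L && all(ijm[nrow(ijm), ] == ijm[1L, ])) ijm <- ijm[-nrow(ijm), , drop = FALSE]
  keep <- c(TRUE, rowSums(abs(diff(ijm))) > 0)
  ijm <- ijm[keep, , drop = FALSE]
  if (nrow(unique(ijm)) < 3L) return(NULL)
  cbind(g$origin[1] + (ijm[, 1] - 1) * g$spacing[1],
        g$origin[2] + (ijm[, 2] - 1) * g$spacing[2])
}

#' Rasterize contours back onto a grid
#'
#' Re-interprets a contour stack on a voxel grid under an explicit
#' rasterization rule, the mechanism by which receiving software changes
#' transferred volumes: \code{center_inside} marks voxels whose centers lie
#' inside (or on) a polygon (even-odd rule, boundary counts as inside);
#' \code{any_overlap} marks voxels whose in-plane box touches the polygon
#' interior or boundary.
#'
#' @param cs a \code{\link{contour_set}}.
#' @param grid target \code{\link{image_grid}}; every contour z plane must
#'   coincide with a grid slice within 1e-6 mm.
#' @param rule \code{"center_inside"} or \code{"any_overlap"}.
#' @return A \code{\link{binary_mask}} on \code{grid}.
#' @export
contours_to_mask <- function(cs, grid, rule = c("center_inside", "any_overlap")) {
  rule <- match.arg(rule)
  stopifnot(inherits(cs, "contour_set"), inherits(grid, "image_grid"))
  if (length(cs$contours) == 0L) stop("empty contour set")
  zs <- grid_centers_1d(grid, 3)
  cx <- grid_centers_1d(grid, 1)
  cy <- grid_centers_1d(grid, 2)
  mem <- array(FALSE, dim = grid$dims)
  hx <- grid$spacing[1] / 2; hy <- grid$spacing[2] / 2
  for (ct in cs$contours) {
    k <- which(abs(zs - ct$z) < 1e-6)
    if (length(k) != 1L)
      stop(sprintf("contour plane z=%.6f mm does not match any grid slice", ct$z))
    P <- ct$points
    pad <- if (rule == "any_overlap") c(hx, hy) else c(0, 0)
    xi <- which(cx >= min(P[, 1]) - pad[1] - 1e-9 & cx <= max(P[, 1]) + pad[1] + 1e-9)
    yi <- which(cy >= min(P[, 2]) - pad[2] - 1e-9 & cy <= max(P[, 2]) + pad[2] + 1e-9)
    if (length(xi) == 0L || length(yi) == 0L) next
    px <- rep(cx[xi], times = length(yi))
    py <- rep(cy[yi], each = length(xi))
    hit <- if (rule == "center_inside") {
      points_in_polygon(px, py, P)
    } else {
      boxes_touch_polygon(px, py, hx, hy, P)
    }
    sub <- matrix(hit, length(xi), length(yi))
    mem[xi, yi, k] <- mem[xi, yi, k] | sub
  }
  binary_mask(grid, mem)
}

## even-odd point-in-polygon, boundary (within eps) counts as inside; vectorized
points_in_polygon <- function(px, py, P, eps = 1e-9) {
  n <- nrow(P)
  inside <- logical(length(px))
  onb <- logical(length(px))
  x1 <- P[, 1]; y1 <- P[, 2]
  x2 <- P[c(2:n, 1), 1]; y2 <- P[c(2:n, 1), 2]
  for (e in seq_len(n)) {
    ax <- x1[e]; ay <- y1[e]; bx <- x2[e]; by <- y2[e]
    # boundary test: |cross| small and projection within segment
    vx <- bx - ax; vy <- by - ay
    len2 <- vx * vx + vy * vy
    cr <- abs(vx * (py - ay) - vy * (px - ax))
    t <- ((px - ax) * vx + (py - ay) * vy) / max(len2, eps^2)
    onb <- onb | (cr <= eps * sqrt(max(len2, eps^2)) & t >= -eps & t <= 1 + eps)
    # crossing test (half-open in y to count shared vertices once)
    cond <- ((ay > py) != (by > py))
    xin <- ax + (py - ay) / (by - ay) * (bx - ax)
    inside <- xor(inside, cond & !is.na(xin) & px < xin)
  }
  inside | onb
}

## does each in-plane box [px +/- hx] x [py +/- hy] touch the polygon?
boxes_touch_polygon <- function(px, py, hx, hy, P, eps = 1e-9) {
  n <- nrow(P)
  hit <- points_in_polygon(px, py, P, eps)  # center covered (also handles box containing tiny polygon via vertex test below)
  # polygon vertex inside a box
  for (v in seq_len(n)) {
    hit <- hit | (abs(P[v, 1] - px) <= hx + eps & abs(P[v, 2] - py) <= hy + eps)
  }
  # any polygon edge intersecting a box (slab clipping, closed boxes)
  x2 <- P[c(2:n, 1), ]; x1 <- P
  for (e in seq_len(n)) {
    ax <- x1[e, 1]; ay <- x1[e, 2]; bx <- x2[e, 1]; by <- x2[e, 2]
    dx <- bx - ax; dy <- by - ay
    lo_x <- px - hx - eps; hi_x <- px + hx + eps
    lo_y <- py - hy - eps; hi_y <- py + hy + eps
    if (abs(dx) < eps) {
      tx0 <- ifelse(ax >= lo_x & ax <= hi_x, 0, 1)
      tx1 <- ifelse(ax >= lo_x & ax <= hi_x, 1, 0)
    } else {
      ta <- (lo_x - ax) / dx; tb <- (hi_x - ax) / dx
      tx0 <- pmin(ta, tb); tx1 <- pmax(ta, tb)
    }
    if (abs(dy) < eps) {
      ty0 <- ifelse(ay >= lo_y & ay <= hi_y, 0, 1)
      ty1 <- ifelse(ay >= lo_y & ay <= hi_y, 1, 0)
    } else {
      ta <- (lo_y - ay) / dy; tb <- (hi_y - ay) / dy
      ty0 <- pmin(ta, tb); ty1 <- pmax(ta, tb)
    }
    t0 <- pmax(tx0, ty0, 0); t1 <- pmin(tx1, ty1, 1)
    hit <- hit | (t0 <= t1)
  }
  hit
}

#' Contour round-trip volume change
#'
#' Quantifies how much a mask's volume changes when exported as planar
#' contours under one boundary dialect and re-rasterized under one rule —
#' the mechanism behind volume shifts observed after DICOM-RT transfer
#' between workstations.
#'
#' @param mask a non-empty \code{\link{binary_mask}}.
#' @param dialect boundary dialect for \code{\link{mask_to_contours}}.
#' @param rule rasterization rule for \code{\link{contours_to_mask}}.
#' @param target_grid grid to rasterize onto; default the mask's own grid.
#' @return List with \code{v_before}, \code{v_after}, \code{delta} (ml,
#'   after minus before).
#' @export
round_trip_volume_change <- function(mask,
                                     dialect = c("voxel_edge", "voxel_center"),
                                     rule = c("center_inside", "any_overlap"),
                                     target_grid = NULL) {
  dialect <- match.arg(dialect)
  rule <- match.arg(rule)
  if (is.null(target_grid)) target_grid <- mask$grid
  cs <- mask_to_contours(mask, dialect)
  after <- contours_to_mask(cs, target_grid, rule)
  v0 <- mask_volume_ml(mask)
  v1 <- mask_volume_ml(after)
  list(v_before = v0, v_after = v1, delta = v1 - v0)
}
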