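signed_area <- function(x, y = NULL) {
  if (is.null(y)) { y <- x$y; x <- x$x }
  n <- length(x)
  if (n < 3) return(0)
  0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
}

area_paths <- function(paths) {
  if (length(paths) == 0) return(0)
  abs(sum(vapply(paths, function(p) signed_area(p$x, p$y), numeric(1))))
}

as_path <- function(p) {
  if (inherits(p, "search_polygon"))
    return(list(x = p$vertices[, 1], y = p$vertices[, 2]))
  if (is.list(p) && !is.null(p$x) && !is.null(p$y)) return(p)
  if (is.matrix(p)) return(list(x = p[, 1], y = p[, 2]))
  stop("expected a search_polygon, a list(x, y) or a 2-column matrix")
}

union_paths <- function(u, v) {
  if (length(u) == 0) return(v)
  if (length(v) == 0) return(u)
  polyclip::polyclip(u, v, op = "union", fillA = "nonzero",
                     fillB = "nonzero")
}

#' Prepare an avatar trajectory for search-area analysis
#'
#' Downsamples a tick-rate position series to `rate` Hz (nearest-sample
#' decimation when the tick rate is not an exact multiple) and removes the
#' first `trim` seconds to strip the transient after spawn. The final sample
#' is treated as an exclusive endpoint, so a full 300 s trial at 90 Hz
#' yields 299 s x 5 Hz = 1495 points.
#'
#' @param traj matrix (or data.frame) of per-tick (x, y) positions, first
#'   row at t = 0.
#' @param tick_rate sampling rate of `traj`, Hz.
#' @param rate output rate, Hz.
#' @param trim initial transient to delete, s.
#' @return Matrix of (x, y) points at `rate` Hz.
#' @export
preprocess_trajectory <- function(traj, tick_rate = 90, rate = 5, trim = 1) {
  traj <- as.matrix(traj)
  if (ncol(traj) != 2) stop("preprocess_trajectory: need 2 columns (x, y)")
  n <- nrow(traj)
  duration <- (n - 1) / tick_rate
  if (duration < trim)
    stop("preprocess_trajectory: trajectory shorter than ", trim, " s")
  step <- max(1L, as.integer(round(tick_rate / rate)))
  start <- as.integer(round(trim * tick_rate)) + 1L
  if (start > n - 1L) return(traj[0, , drop = FALSE])
  traj[seq.int(start, n - 1L, by = step), , drop = FALSE]
}

# Circumradii of triangles (rows of vertex indices into pts); R = abc / 4K,
# Inf for (near-)collinear triangles.
circumradii <- function(vtx, pts) {
  p1 <- pts[vtx[, 1], , drop = FALSE]
  p2 <- pts[vtx[, 2], , drop = FALSE]
  p3 <- pts[vtx[, 3], , drop = FALSE]
  a <- sqrt(rowSums((p2 - p1)^2))
  b <- sqrt(rowSums((p3 - p2)^2))
  cc <- sqrt(rowSums((p1 - p3)^2))
  k <- abs((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
             (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])) / 2
  r <- a * b * cc / (4 * k)
  r[k <= .Machine$double.eps * pmax(a, b, cc)^2] <- Inf
  r
}

# Stitch undirected boundary edges (rows of a 2-column index matrix) into
# closed rings of vertex indices.
stitch_rings <- function(edges) {
  rings <- list()
  used <- rep(FALSE, nrow(edges))
  adj <- split(rep(seq_len(nrow(edges)), 2L), c(edges[, 1], edges[, 2]))
  while (any(!used)) {
    e0 <- which(!used)[1]
    used[e0] <- TRUE
    ring <- c(edges[e0, 1], edges[e0, 2])
    repeat {
      cur <- ring[length(ring)]
      cand <- adj[[as.character(cur)]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break
      e <- cand[1]
      used[e] <- TRUE
      nxt <- if (edges[e, 1] == cur) edges[e, 2] else edges[e, 1]
      if (nxt == ring[1]) break
      ring <- c(ring, nxt)
    }
    rings[[length(rings) + 1]] <- ring
  }
  rings
}

#' Concave search polygon of a point set (alpha shape)
#'
#' Computes the alpha shape of the points via their Delaunay triangulation:
#' triangles whose circumradius exceeds the probe radius are discarded, and
#' the probe radius is shrunk by bisection to the smallest value (within
#' `rel_tol` relative tolerance) at which the remaining complex is still a
#' single edge-connected polygon touching every input point -- the
#' tightest-fitting single bounding polygon a circle of that radius can
#' "roll" around. If no radius below the convex hull's satisfies the
#' acceptance test, the convex hull itself is returned and flagged.
#' Interior voids of the complex are reduced to the outer boundary
#' (`holes_filled` is set when that happens).
#'
#' @param points matrix of (x, y) coordinates (>= 3 distinct, not all
#'   collinear).
#' @param rel_tol relative bisection tolerance on the probe radius.
#' @return An object of class `search_polygon`: `vertices` (outer ring,
#'   counter-clockwise, not closed), `area` (m^2), `method` (`"alpha_shape"`
#'   or `"convex_hull_fallback"`), `alpha` (accepted probe radius),
#'   `holes_filled`, `n_points`.
#' @export
search_polygon <- function(points, rel_tol = 1e-3) {
  points <- as.matrix(points)
  pts <- unique(points)
  if (nrow(pts) < 3)
    stop("search_polygon: degenerate geometry (fewer than 3 distinct points)")
  tri <- tryCatch(
    suppressWarnings(interp::tri.mesh(pts[, 1], pts[, 2],
                                      duplicate = "remove")),
    error = function(e) NULL)
  vtx <- if (is.null(tri)) NULL else
    tryCatch(unname(interp::triangles(tri)[, 1:3, drop = FALSE]),
             error = function(e) NULL)
  if (!is.null(tri)) pts <- cbind(tri$x, tri$y)
  hull_fallback <- function() {
    h <- grDevices::chull(pts)
    ring <- pts[h, , drop = FALSE]
    a <- signed_area(ring[, 1], ring[, 2])
    if (abs(a) <= .Machine$double.eps * max(abs(pts))^2)
      stop("search_polygon: degenerate geometry (points are collinear)")
    if (a < 0) ring <- ring[rev(seq_len(nrow(ring))), , drop = FALSE]
    structure(list(vertices = ring, area = abs(a),
                   method = "convex_hull_fallback", alpha = Inf,
                   holes_filled = FALSE, n_points = nrow(pts)),
              class = "search_polygon")
  }
  if (is.null(vtx) || nrow(vtx) == 0) return(hull_fallback())

  nt <- nrow(vtx)
  n_pts <- nrow(pts)
  rad <- circumradii(vtx, pts)
  all_edges <- rbind(cbind(vtx[, 1], vtx[, 2]), cbind(vtx[, 2], vtx[, 3]),
                     cbind(vtx[, 3], vtx[, 1]))
  all_edges <- cbind(pmin(all_edges[, 1], all_edges[, 2]),
                     pmax(all_edges[, 1], all_edges[, 2]))
  all_keys <- (all_edges[, 1] - 1) * n_pts + all_edges[, 2]
  tri_of_edge <- rep(seq_len(nt), 3)
  # triangle pairs sharing an edge (interior edges appear exactly twice)
  ord <- order(all_keys)
  same <- which(diff(all_keys[ord]) == 0)
  adj_pairs <- cbind(tri_of_edge[ord[same]], tri_of_edge[ord[same + 1]])
  # points actually present in the triangulation (deldir may merge points
  # closer than its rounding tolerance)
  active_pts <- sort(unique(as.vector(vtx)))

  # single edge-connected component covering every triangulated point?
  complex_ok <- function(keep) {
    if (!any(keep)) return(FALSE)
    cnt <- tabulate(vtx[keep, , drop = FALSE], nbins = n_pts)
    if (any(cnt[active_pts] == 0)) return(FALSE)
    ee <- adj_pairs[keep[adj_pairs[, 1]] & keep[adj_pairs[, 2]], ,
                    drop = FALSE]
    g <- igraph::make_graph(as.integer(t(ee)), n = nt, directed = FALSE)
    memb <- igraph::components(g)$membership
    length(unique(memb[keep])) == 1
  }

  r_hi <- max(rad[is.finite(rad)], 0)
  if (!complex_ok(rad <= r_hi)) return(hull_fallback())
  r_lo <- 0
  while ((r_hi - r_lo) > rel_tol * max(r_hi, .Machine$double.eps)) {
    mid <- (r_lo + r_hi) / 2
    if (complex_ok(rad <= mid)) r_hi <- mid else r_lo <- mid
  }
  keep <- rad <= r_hi

  sel <- keep[tri_of_edge]
  kk <- all_keys[sel]
  bnd <- all_edges[sel, , drop = FALSE][!(kk %in% kk[duplicated(kk)]), ,
                                        drop = FALSE]
  rings <- stitch_rings(bnd)
  areas <- vapply(rings, function(r)
    abs(signed_area(pts[r, 1], pts[r, 2])), numeric(1))
  outer <- rings[[which.max(areas)]]
  ring <- pts[outer, , drop = FALSE]
  if (signed_area(ring[, 1], ring[, 2]) < 0)
    ring <- ring[rev(seq_len(nrow(ring))), , drop = FALSE]
  structure(list(vertices = ring, area = max(areas), method = "alpha_shape",
                 alpha = r_hi, holes_filled = length(rings) > 1,
                 n_points = n_pts),
            class = "search_polygon")
}

#' @export
print.search_polygon <- function(x, ...) {
  cat(sprintf("<search_polygon> %s: area %.2f m^2, %d vertices (alpha %.3g)\n",
              x$method, x$area, nrow(x$vertices), x$alpha))
  invisible(x)
}

#' Proportion of the team search area covered by two or more players
#'
#' The division-of-labor statistic: the three per-player search polygons are
#' pairwise intersected, the three intersections are unioned (so regions
#' covered by all three count once), and the result is divided by the area
#' of the union of all three polygons. 0 means the players partitioned the
#' space cleanly; 1 means they all searched the same locations.
#'
#' @param polygons list of three `search_polygon` objects (or plain
#'   `list(x, y)` rings / 2-column matrices).
#' @return An object of class `overlap_result`: `overlap_area`,
#'   `total_area` (m^2) and `proportion`.
#' @export
proportion_overlap <- function(polygons) {
  if (length(polygons) != 3)
    stop("proportion_overlap: need exactly three polygons")
  paths <- lapply(polygons, as_path)
  pc <- function(a, b, op)
    polyclip::polyclip(a, b, op = op, fillA = "nonzero", fillB = "nonzero")
  ab <- pc(paths[[1]], paths[[2]], "intersection")
  ac <- pc(paths[[1]], paths[[3]], "intersection")
  bc <- pc(paths[[2]], paths[[3]], "intersection")
  ov <- union_paths(union_paths(ab, ac), bc)
  tot <- union_paths(union_paths(list(paths[[1]]), list(paths[[2]])),
                     list(paths[[3]]))
  total_area <- area_paths(tot)
  if (total_area <= 0)
    stop("proportion_overlap: zero total search area")
  overlap_area <- area_paths(ov)
  structure(list(overlap_area = overlap_area, total_area = total_area,
                 proportion = overlap_area / total_area),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "<overlap_result> overlap %.2f / total %.2f m^2 = proportion %.3f\n",
    x$overlap_area, x$total_area, x$proportion))
  invisible(x)
}

#' Search-overlap proportion of one simulated trial
#'
#' Convenience wrapper: preprocesses each ground player's trajectory
#' ([preprocess_trajectory()]), fits the three search polygons
#' ([search_polygon()]) and computes [proportion_overlap()].
#'
#' @param record a [run_trial()] result.
#' @return list with the `overlap_result`, the three polygons, and the
#'   per-player method flags.
#' @export
trial_overlap <- function(record) {
  stopifnot(inherits(record, "trial_record"))
  polys <- lapply(1:3, function(i) {
    pts <- preprocess_trajectory(cbind(record$player_x[, i],
                                       record$player_y[, i]),
                                 tick_rate = record$params$tick_rate)
    search_polygon(pts)
  })
  res <- proportion_overlap(polys)
  list(overlap = res, polygons = polys,
       methods = vapply(polys, function(p) p$method, character(1)))
}
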