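# Planar graph representation of segmented axon networks and the
# coarsening statistics computed on them: total length, junction counts,
# chordless-loop (bounded face) areas, zipper angles via the
# sharpest-of-three rule, and time-series correlations.
#
# A segmentation export is a set of polylines (one per drawn axon/fascicle
# edge). Polyline endpoints within the snap tolerance are merged into
# graph nodes; crossings are drawn as overlapping polylines with no shared
# endpoint and therefore never create graph connectivity.

#' Build a network frame from polylines
#'
#' @param polylines List of numeric matrices (>= 2 rows, 2 columns), each
#'   a polyline in um. Matrices may carry a `kind` attribute (e.g.
#'   `"crossing"`) which is stored per edge.
#' @param timestamp Acquisition time (min).
#' @param snap_tol Endpoint merge tolerance (um); endpoints closer than
#'   this collapse into one node (manual segmentation jitter).
#' @param bounds Optional field-of-view bounds `c(xmin, xmax, ymin, ymax)`.
#' @return An object of class `network_frame`: list with `nodes` (id, x,
#'   y, degree, kind), `edges` (from, to, length, kind), `polylines`, and
#'   `timestamp`. Node kind is `"junction"` (degree >= 3), `"endpoint"`
#'   (degree 1) or `"connector"`.
#' @export
network_frame <- function(polylines, timestamp = 0, snap_tol = 1,
                          bounds = NULL) {
  if (!length(polylines)) stop("no polylines", call. = FALSE)
  for (i in seq_along(polylines)) {
    p <- polylines[[i]]
    if (!is.matrix(p) || ncol(p) != 2 || nrow(p) < 2 || anyNA(p)) {
      stop("polyline ", i, " must be a numeric matrix with 2 columns and >= 2 rows",
           call. = FALSE)
    }
  }
  ends <- do.call(rbind, lapply(polylines, function(p) {
    rbind(p[1, ], p[nrow(p), ])
  }))
  n_end <- nrow(ends)
  # greedy endpoint clustering within snap tolerance
  node_of <- integer(n_end)
  centers <- matrix(NA_real_, 0, 2)
  for (i in seq_len(n_end)) {
    if (nrow(centers)) {
      d2 <- (centers[, 1] - ends[i, 1])^2 + (centers[, 2] - ends[i, 2])^2
      j <- which(d2 <= snap_tol^2)
    } else j <- integer(0)
    if (length(j)) {
      node_of[i] <- j[1]
    } else {
      centers <- rbind(centers, ends[i, ])
      node_of[i] <- nrow(centers)
    }
  }
  kinds <- vapply(polylines, function(p) {
    k <- attr(p, "kind")
    if (is.null(k)) "axon" else as.character(k)
  }, character(1))
  edges <- data.frame(
    from = node_of[seq(1, n_end, by = 2)],
    to = node_of[seq(2, n_end, by = 2)],
    length = vapply(polylines, polyline_length, numeric(1)),
    kind = kinds
  )
  deg <- tabulate(c(edges$from, edges$to), nbins = nrow(centers))
  nodes <- data.frame(id = seq_len(nrow(centers)),
                      x = centers[, 1], y = centers[, 2], degree = deg,
                      kind = ifelse(deg >= 3, "junction",
                                    ifelse(deg == 1, "endpoint", "connector")))
  structure(list(nodes = nodes, edges = edges, polylines = polylines,
                 timestamp = timestamp, snap_tol = snap_tol, bounds = bounds),
            class = "network_frame")
}

polyline_length <- function(p) {
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' @export
print.network_frame <- function(x, ...) {
  cat(sprintf("network_frame at t = %g min: %d polylines, %d nodes (%d junctions), L = %.1f um\n",
              x$timestamp, length(x$polylines), nrow(x$nodes),
              count_junctions(x), total_length(x)))
  invisible(x)
}

#' Load a segmentation export
#'
#' Reads the documented plain-text schema: CSV with columns `frame`,
#' `polyline_id`, `point_index`, `x`, `y` and optional `kind`, or a JSON
#' file mirroring it (list of frames, each a list of polylines with `points`
#' and optional `kind`). Coordinates are multiplied by `pixel_size`.
#'
#' @param path File path.
#' @param pixel_size um per coordinate unit (scaling is a required part of
#'   the schema; default 1 means coordinates already in um).
#' @param snap_tol Endpoint merge tolerance (um).
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return A [network_frame()], or a list of them if the file holds
#'   several frames.
#' @export
load_segmentation <- function(path, pixel_size = 1, snap_tol = 1,
                              format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    frames <- lapply(raw$frames, function(fr) {
      pls <- lapply(fr$polylines, function(pl) {
        m <- as.matrix(pl$points) * pixel_size
        if (!is.null(pl$kind)) attr(m, "kind") <- pl$kind
        m
      })
      network_frame(pls, timestamp = fr$timestamp %||% 0, snap_tol = snap_tol)
    })
    return(if (length(frames) == 1) frames[[1]] else frames)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("frame", "polyline_id", "point_index", "x", "y")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("segmentation file misses columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!stats::complete.cases(df[c("x", "y")]) |
                 !is.numeric(df$x) | !is.numeric(df$y))
  if (length(bad)) {
    stop("malformed segmentation row(s) at line(s): ",
         paste(bad[seq_len(min(5, length(bad)))] + 1, collapse = ", "),
         call. = FALSE)
  }
  frames <- lapply(split(df, df$frame), function(fd) {
    fd <- fd[order(fd$polyline_id, fd$point_index), ]
    pls <- lapply(split(fd, fd$polyline_id), function(pd) {
      m <- cbind(pd$x, pd$y) * pixel_size
      if ("kind" %in% names(pd) && any(nzchar(pd$kind))) {
        attr(m, "kind") <- pd$kind[nzchar(pd$kind)][1]
      }
      m
    })
    ts <- if ("timestamp" %in% names(fd)) fd$timestamp[1] else
      suppressWarnings(as.numeric(fd$frame[1]))
    network_frame(unname(pls), timestamp = if (is.na(ts)) 0 else ts,
                  snap_tol = snap_tol)
  })
  if (length(frames) == 1) frames[[1]] else unname(frames)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a network frame to the CSV segmentation schema
#'
#' @param frames A [network_frame()] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(frames, path) {
  if (inherits(frames, "network_frame")) frames <- list(frames)
  rows <- do.call(rbind, lapply(seq_along(frames), function(fi) {
    fr <- frames[[fi]]
    do.call(rbind, lapply(seq_along(fr$polylines), function(pi) {
      p <- fr$polylines[[pi]]
      data.frame(frame = fi, timestamp = fr$timestamp, polyline_id = pi,
                 point_index = seq_len(nrow(p)), x = p[, 1], y = p[, 2],
                 kind = attr(p, "kind") %||% "axon")
    }))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Total network length and junction count
#'
#' Total length is the sum of the drawn polyline lengths (shared zippered
#' segments are drawn once and counted once). The junction count includes
#' only merged endpoint nodes of degree >= 3; crossings never form nodes
#' and are excluded.
#'
#' @param frame A [network_frame()].
#' @return `total_length`: length in um; `count_junctions`: integer.
#' @export
total_length <- function(frame) sum(frame$edges$length)

#' @rdname total_length
#' @export
count_junctions <- function(frame) sum(frame$nodes$degree >= 3)

# Tangent direction at a node along an edge, averaged over the polyline
# geometry within arm_length of the node.
edge_direction_at <- function(p, from_start, arm_length) {
  if (!from_start) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
  segs <- p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE]
  lens <- sqrt(rowSums(segs^2))
  cum <- cumsum(lens)
  target <- min(arm_length, cum[length(cum)])
  k <- which(cum >= target)[1]
  # point at arc length `target` along the polyline
  excess <- cum[k] - target
  pt <- p[k + 1, ] - segs[k, ] / lens[k] * excess
  d <- pt - p[1, ]
  d / vnorm(d)
}

#' Zipper angles at degree-3 junctions
#'
#' At each degree-3 junction, edge tangents are estimated from the
#' polyline geometry within `arm_length` of the node, and the zipper angle
#' is taken as the sharpest of the three pairwise inter-edge angles,
#' unless an override annotation selects a different pair. Junctions of
#' other degrees are skipped (recorded in the `skipped` attribute);
#' crossings never appear since they are not nodes.
#'
#' @param frame A [network_frame()].
#' @param arm_length Tangent estimation window (um).
#' @param overrides Optional named list: junction node id (as character)
#'   to an index pair `c(i, j)` selecting which two of its edges form the
#'   zipper angle.
#' @return Numeric vector of angles (degrees), named by junction node id,
#'   with attribute `skipped` listing nodes of degree other than 3.
#' @export
zipper_angles <- function(frame, arm_length = 5, overrides = NULL) {
  juncs <- frame$nodes$id[frame$nodes$degree >= 3]
  skipped <- frame$nodes$id[frame$nodes$degree > 3]
  juncs <- frame$nodes$id[frame$nodes$degree == 3]
  out <- numeric(0)
  for (nid in juncs) {
    inc <- which(frame$edges$from == nid | frame$edges$to == nid)
    dirs <- lapply(inc, function(ei) {
      edge_direction_at(frame$polylines[[ei]],
                        from_start = frame$edges$from[ei] == nid,
                        arm_length = arm_length)
    })
    pair_angle <- function(i, j) {
      rad2deg(acos(pmin(1, pmax(-1, sum(dirs[[i]] * dirs[[j]])))))
    }
    ov <- overrides[[as.character(nid)]]
    ang <- if (!is.null(ov)) {
      pair_angle(ov[1], ov[2])
    } else {
      min(pair_angle(1, 2), pair_angle(1, 3), pair_angle(2, 3))
    }
    out <- c(out, stats::setNames(ang, nid))
  }
  attr(out, "skipped") <- skipped
  out
}

# ---- planar faces (chordless loops) --------------------------------------

#' Chordless loops (bounded faces) of a network frame
#'
#' Interprets the "chordless closed loops" of the segmentation as the
#' bounded faces of the planar embedding defined by the node coordinates,
#' found by rotational face traversal (leftmost-turn rule). Areas are
#' computed with the shoelace formula on the full polyline geometry of
#' each face. Crossings do not split faces because they are not nodes.
#'
#' @param frame A [network_frame()].
#' @return Data frame with one row per bounded face: `area` (um^2) and
#'   `n_edges`. Zero rows if the graph is a forest.
#' @export
chordless_loops <- function(frame) {
  ed <- frame$edges
  nd <- frame$nodes
  ne <- nrow(ed)
  if (!ne) return(data.frame(area = numeric(0), n_edges = integer(0)))
  # darts: 2*ne directed edges; dart 2i-1 = from->to, dart 2i = to->from
  dart_tail <- c(rbind(ed$from, ed$to))
  dart_head <- c(rbind(ed$to, ed$from))
  dart_edge <- rep(seq_len(ne), each = 2)
  # outgoing direction of each dart (tangent at the tail node)
  dart_ang <- vapply(seq_len(2 * ne), function(d) {
    p <- frame$polylines[[dart_edge[d]]]
    from_start <- (d %% 2) == 1
    v <- edge_direction_at(p, from_start, arm_length = 1e-6)
    atan2(v[2], v[1])
  }, numeric(1))
  twin <- ifelse(seq_len(2 * ne) %% 2 == 1, seq_len(2 * ne) + 1L,
                 seq_len(2 * ne) - 1L)
  # rotation system: darts around each node ordered by angle
  nxt <- integer(2 * ne)
  for (v in unique(dart_tail)) {
    darts_v <- which(dart_tail == v)
    ord <- darts_v[order(dart_ang[darts_v])]
    for (d in seq_len(2 * ne)) {
      if (dart_head[d] == v) {
        tw <- twin[d]
        pos <- match(tw, ord)
        # next dart clockwise from the reversed dart
        nxt[d] <- ord[if (pos == 1) length(ord) else pos - 1]
      }
    }
  }
  visited <- logical(2 * ne)
  faces <- list()
  for (d0 in seq_len(2 * ne)) {
    if (visited[d0]) next
    cyc <- integer(0)
    d <- d0
    repeat {
      visited[d] <- TRUE
      cyc <- c(cyc, d)
      d <- nxt[d]
      if (d == d0) break
      if (length(cyc) > 4 * ne) stop("face traversal failed", call. = FALSE)
    }
    # concatenate polyline geometry along the cycle
    pts <- do.call(rbind, lapply(cyc, function(dd) {
      p <- frame$polylines[[dart_edge[dd]]]
      if ((dd %% 2) == 0) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
      p[-nrow(p), , drop = FALSE]
    }))
    a <- shoelace(pts)
    faces[[length(faces) + 1]] <- list(area = a, n_edges = length(cyc),
                                       darts = cyc)
  }
  areas <- vapply(faces, function(f) f$area, numeric(1))
  nedges <- vapply(faces, function(f) f$n_edges, integer(1))
  # bounded faces: positive signed area under the traversal convention;
  # the outer face of each component has the opposite sign. Degenerate
  # tree-like faces have ~zero area and are dropped.
  keep <- areas > 1e-9
  data.frame(area = areas[keep], n_edges = nedges[keep])
}

shoelace <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  n <- nrow(p)
  sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y) / 2
}

#' Per-frame network statistics and the angle-length correlation
#'
#' Computes, for each frame, the total length, junction count, number and
#' mean area of chordless loops, and the median zipper angle; then the
#' Pearson correlation between the median angle and the total length
#' across frames. Statistics can be normalized by a reference frame (e.g.
#' the last time point before a drug was added).
#'
#' @param frames List of [network_frame()] objects (>= 3 for the
#'   correlation).
#' @param normalize_to Optional frame index; length, junction count and
#'   loop area are divided by that frame's values.
#' @param arm_length Passed to [zipper_angles()].
#' @return List with `stats` (data frame, one row per frame) and
#'   `r_angle_length` (Pearson r; `NaN` with a warning if undefined).
#' @export
timeseries_stats <- function(frames, normalize_to = NULL, arm_length = 5) {
  stats_df <- do.call(rbind, lapply(frames, function(fr) {
    loops <- chordless_loops(fr)
    ang <- zipper_angles(fr, arm_length = arm_length)
    data.frame(timestamp = fr$timestamp,
               total_length = total_length(fr),
               n_junctions = count_junctions(fr),
               n_loops = nrow(loops),
               mean_loop_area = if (nrow(loops)) mean(loops$area) else NA_real_,
               median_angle = if (length(ang)) stats::median(ang) else NA_real_)
  }))
  if (!is.null(normalize_to)) {
    ref <- stats_df[normalize_to, ]
    for (col in c("total_length", "n_junctions", "mean_loop_area")) {
      stats_df[[paste0(col, "_norm")]] <- stats_df[[col]] / ref[[col]]
    }
  }
  r <- NA_real_
  if (nrow(stats_df) >= 3) {
    ok <- stats::complete.cases(stats_df[c("median_angle", "total_length")])
    if (sum(ok) >= 3 &&
        stats::sd(stats_df$median_angle[ok]) > 0 &&
        stats::sd(stats_df$total_length[ok]) > 0) {
      r <- stats::cor(stats_df$median_angle[ok], stats_df$total_length[ok])
    } else {
      warning("correlation undefined (constant series)")
      r <- NaN
    }
  }
  list(stats = stats_df, r_angle_length = r)
}

#' Vertex-type percentages
#'
#' Integer-rounded percentages of simple zippers, entangled zippers and
#' crossings among the counted network vertices.
#'
#' @param counts Named or positional integer vector
#'   `c(simple, entangled, crossing)`.
#' @return Named numeric vector of percentages summing to ~100.
#' @export
vertex_type_fractions <- function(counts) {
  if (length(counts) != 3 || any(counts < 0)) {
    stop("counts must be 3 non-negative integers", call. = FALSE)
  }
  tot <- sum(counts)
  if (tot == 0) stop("zero total count", call. = FALSE)
  out <- round(100 * counts / tot)
  names(out) <- c("simple", "entangled", "crossing")
  out
}
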