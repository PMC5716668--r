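#' Neuron morphologies as segment trees
#'
#' A `segment_tree` represents a neuron morphology as a rooted tree of
#' cylindrical segments. Each segment runs from a proximal to a distal 3-D
#' point (coordinates in micrometres) and carries a radius and an SWC
#' structure tag. Following the usual SWC convention, every non-root SWC
#' point defines one segment ending at that point; the root point only
#' contributes its coordinate. Multi-point soma contours therefore become a
#' chain of ordinary segments -- the estimator treats soma cable like any
#' other part of the loop.
#'
#' @param segments data frame with columns `id`, `parent` (0 denotes
#'   attachment at the root point), `x0`,`y0`,`z0` (proximal), `x1`,`y1`,`z1`
#'   (distal), `radius` (micrometres) and `tag` (SWC type code).
#' @param root_pos numeric length-3, coordinate of the root (soma) point.
#' @param root_radius radius recorded for the root SWC point (micrometres).
#' @param root_tag SWC type code of the root point.
#' @return An object of class `segment_tree` with elements `segments`
#'   (including a computed `length` column), `root_pos`, `root_radius`,
#'   `root_tag` and `total_length` (micrometres).
#' @seealso [read_swc()], [resample_tree()], [build_loop()]
#' @export
segment_tree <- function(segments, root_pos, root_radius = segments$radius[1L],
                         root_tag = 1L) {
  required <- c("id", "parent", "x0", "y0", "z0", "x1", "y1", "z1",
                "radius", "tag")
  missing_cols <- setdiff(required, names(segments))
  if (length(missing_cols) > 0L) {
    stopf("segment table lacks column(s): %s",
          paste(missing_cols, collapse = ", "),
          class = "skcsd_structure_error")
  }
  segments <- as.data.frame(segments)[required]
  segments$length <- sqrt((segments$x1 - segments$x0)^2 +
                          (segments$y1 - segments$y0)^2 +
                          (segments$z1 - segments$z0)^2)
  tree <- structure(
    list(segments = segments,
         root_pos = as.numeric(root_pos),
         root_radius = root_radius,
         root_tag = root_tag,
         total_length = sum(segments$length)),
    class = "segment_tree")
  validate_segment_tree(tree)
}

validate_segment_tree <- function(tree) {
  seg <- tree$segments
  n <- nrow(seg)
  if (n < 1L) stopf("morphology has no segments", class = "skcsd_structure_error")
  if (anyDuplicated(seg$id)) {
    stopf("duplicated segment ids", class = "skcsd_structure_error")
  }
  if (any(seg$radius <= 0)) {
    stopf("non-positive segment radius", class = "skcsd_structure_error")
  }
  if (any(seg$length <= 0)) {
    stopf("zero-length segment (id %s)", seg$id[which(seg$length <= 0)[1L]],
          class = "skcsd_structure_error")
  }
  known <- c(0, seg$id)
  bad <- !(seg$parent %in% known)
  if (any(bad)) {
    stopf("segment %s references missing parent %s",
          seg$id[which(bad)[1L]], seg$parent[which(bad)[1L]],
          class = "skcsd_structure_error")
  }
  if (any(seg$parent == seg$id)) {
    stopf("cycle: segment %s is its own parent",
          seg$id[which(seg$parent == seg$id)[1L]],
          class = "skcsd_structure_error")
  }
  ## parent must precede child in the table (guarantees acyclicity and a
  ## single connected component rooted at the root point)
  pos <- match(seg$parent, seg$id)            # NA for parent == 0
  before <- is.na(pos) | pos < seq_len(n)
  if (!all(before)) {
    stopf("segment %s appears before its parent %s",
          seg$id[which(!before)[1L]], seg$parent[which(!before)[1L]],
          class = "skcsd_structure_error")
  }
  ## geometric continuity: proximal point of every segment coincides with
  ## its parent's distal point (or the root point)
  par_end <- matrix(rep(tree$root_pos, each = n), ncol = 3L)
  has_par <- !is.na(pos)
  par_end[has_par, ] <- as.matrix(seg[pos[has_par], c("x1", "y1", "z1")])
  gap <- sqrt(rowSums((as.matrix(seg[, c("x0", "y0", "z0")]) - par_end)^2))
  if (any(gap > 1e-6)) {
    stopf("segment %s is detached from its parent (gap %.3g)",
          seg$id[which.max(gap)], max(gap), class = "skcsd_structure_error")
  }
  tree
}

#' @export
print.segment_tree <- function(x, ...) {
  cat(sprintf("segment_tree: %d segments, total length %.2f um, %d tip(s)\n",
              nrow(x$segments), x$total_length,
              sum(!(x$segments$id %in% x$segments$parent))))
  invisible(x)
}

## ids of the children of segment `id` (0 = root), in ascending order
tree_children <- function(tree, id) {
  sort(tree$segments$id[tree$segments$parent == id])
}

#' Read a neuron morphology from an SWC file
#'
#' Parses the standard 7-column SWC format (`id type x y z radius parent`,
#' `#` comments, blank lines and arbitrary whitespace allowed) and converts
#' the point list into a [segment_tree()]: every point whose parent is not
#' `-1` defines a segment from the parent's coordinate to its own.
#'
#' @param path path to an SWC file.
#' @return A [segment_tree()].
#' @examples
#' f <- tempfile(fileext = ".swc")
#' writeLines(c("# toy cell",
#'              "1 1 0 0 0 10 -1",
#'              "2 3 0 250 0 2 1",
#'              "3 3 0 500 0 2 2"), f)
#' tree <- read_swc(f)
#' tree$total_length   # 500
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) {
    stopf("SWC file not found: %s", path, class = "skcsd_data_error")
  }
  raw <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z",
                                         "radius", "parent"),
                           colClasses = "numeric")
  if (nrow(raw) < 2L) {
    stopf("SWC file %s has fewer than 2 points", path,
          class = "skcsd_structure_error")
  }
  if (any(raw$id == raw$parent)) {
    bad <- which(raw$id == raw$parent)[1L]
    stopf("cycle in SWC file %s: point %d (line entry %d) is its own parent",
          path, raw$id[bad], bad, class = "skcsd_structure_error")
  }
  roots <- which(raw$parent == -1)
  if (length(roots) == 0L) {
    stopf("SWC file %s has no root point (parent -1)", path,
          class = "skcsd_structure_error")
  }
  if (length(roots) > 1L) {
    stopf("SWC file %s has %d root points; expected exactly one",
          path, length(roots), class = "skcsd_structure_error")
  }
  miss <- raw$parent != -1 & !(raw$parent %in% raw$id)
  if (any(miss)) {
    bad <- which(miss)[1L]
    stopf("SWC file %s: point %d references missing parent %d",
          path, raw$id[bad], raw$parent[bad], class = "skcsd_structure_error")
  }
  root <- roots[1L]
  ## depth-first preorder (children in ascending id) so that branches stay
  ## contiguous in the segment table and re-reading a written tree
  ## reproduces its ordering; unreachable points indicate a cycle or break
  kids_of <- split(seq_len(nrow(raw)), as.character(raw$parent))
  kids_of <- lapply(kids_of, function(ix) ix[order(raw$id[ix])])
  ord <- integer(0)
  placed <- rep(FALSE, nrow(raw))
  placed[root] <- TRUE
  stack <- rev(kids_of[[as.character(raw$id[root])]])
  while (length(stack) > 0L) {
    i <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    ord <- c(ord, i)
    placed[i] <- TRUE
    stack <- c(stack, rev(kids_of[[as.character(raw$id[i])]]))
  }
  if (!all(placed)) {
    stopf("SWC file %s: %d point(s) unreachable from the root (cycle or break)",
          path, sum(!placed), class = "skcsd_structure_error")
  }
  pts <- raw[ord, , drop = FALSE]
  pidx <- match(pts$parent, raw$id)
  seg <- data.frame(
    id = seq_len(nrow(pts)),
    parent = match(pts$parent, raw$id[ord]),  # NA if parent is the root
    x0 = raw$x[pidx], y0 = raw$y[pidx], z0 = raw$z[pidx],
    x1 = pts$x, y1 = pts$y, z1 = pts$z,
    radius = pts$radius, tag = pts$type)
  seg$parent[is.na(seg$parent)] <- 0L
  segment_tree(seg, root_pos = c(raw$x[root], raw$y[root], raw$z[root]),
               root_radius = raw$radius[root], root_tag = raw$type[root])
}

#' Write a segment tree to an SWC file
#'
#' Inverse of [read_swc()]: the root point plus each segment's distal point
#' are written as SWC points, so `read_swc(write_swc(tree, f))` reproduces
#' the segment endpoints and parent relations exactly.
#'
#' @param tree a [segment_tree()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(tree, path) {
  seg <- tree$segments
  lines <- c(
    sprintf("%d %d %.17g %.17g %.17g %.17g %d", 1L, tree$root_tag,
            tree$root_pos[1L], tree$root_pos[2L], tree$root_pos[3L],
            tree$root_radius, -1L),
    sprintf("%d %d %.17g %.17g %.17g %.17g %d",
            seg$id + 1L, seg$tag, seg$x1, seg$y1, seg$z1, seg$radius,
            ifelse(seg$parent == 0L, 1L, seg$parent + 1L)))
  writeLines(c("# SWC written by skcsd", lines), path)
  invisible(path)
}

#' Subdivide segments to a maximum length
#'
#' Splits every segment longer than `max_seg_len` into equal collinear
#' pieces. Topology (branch-point connectivity) and total cable length are
#' preserved; radii and structure tags are inherited.
#'
#' @param tree a [segment_tree()].
#' @param max_seg_len maximum allowed segment length (micrometres).
#' @return A [segment_tree()] with all segment lengths `<= max_seg_len`.
#' @export
resample_tree <- function(tree, max_seg_len) {
  check_scalar_pos(max_seg_len, "max_seg_len")
  seg <- tree$segments
  n_pieces <- pmax(1L, ceiling(seg$length / max_seg_len - 1e-12))
  new_id_of <- cumsum(n_pieces)              # id of the last piece of each old segment
  rows <- vector("list", nrow(seg))
  for (i in seq_len(nrow(seg))) {
    k <- n_pieces[i]
    p0 <- c(seg$x0[i], seg$y0[i], seg$z0[i])
    p1 <- c(seg$x1[i], seg$y1[i], seg$z1[i])
    fr <- seq(0, 1, length.out = k + 1L)
    first_id <- new_id_of[i] - k + 1L
    parent0 <- if (seg$parent[i] == 0L) 0L else
      new_id_of[match(seg$parent[i], seg$id)]
    rows[[i]] <- data.frame(
      id = first_id:new_id_of[i],
      parent = c(parent0, if (k > 1L) (first_id:(new_id_of[i] - 1L))),
      x0 = p0[1L] + fr[-(k + 1L)] * (p1[1L] - p0[1L]),
      y0 = p0[2L] + fr[-(k + 1L)] * (p1[2L] - p0[2L]),
      z0 = p0[3L] + fr[-(k + 1L)] * (p1[3L] - p0[3L]),
      x1 = p0[1L] + fr[-1L] * (p1[1L] - p0[1L]),
      y1 = p0[2L] + fr[-1L] * (p1[2L] - p0[2L]),
      z1 = p0[3L] + fr[-1L] * (p1[3L] - p0[3L]),
      radius = seg$radius[i], tag = seg$tag[i])
  }
  segment_tree(do.call(rbind, rows), root_pos = tree$root_pos,
               root_radius = tree$root_radius, root_tag = tree$root_tag)
}
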