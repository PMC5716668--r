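#' Construct the morphology loop
#'
#' Builds the closed curve that covers the whole dendritic tree -- the
#' *morphology loop* -- by a depth-first closed walk from the root in which
#' unvisited neighbours are preferred and children are taken in ascending
#' segment id. Every tree edge is traversed exactly twice (once per
#' direction), so the loop length is `l = 2 * tree$total_length` and the
#' walk starts and ends at the root (soma). The arc-length parameter
#' `s in [0, l)` gives a one-dimensional coordinate for the whole cell:
#' dendritic tips are visited once, ordinary interior points twice and
#' branch points more often.
#'
#' @param tree a [segment_tree()].
#' @param spline if `TRUE`, fit periodic interpolating splines through the
#'   traversal endpoints so that [loop_point()] returns a smooth closed
#'   curve; the default is the piecewise-linear curve through the segment
#'   endpoints, which is exactly testable.
#' @return An object of class `morphology_loop` with elements `visits`
#'   (data frame: segment `seg`, direction `dir` (+1 proximal-to-distal),
#'   arc-length interval `[s0, s1)`), `l` (loop length, micrometres) and
#'   `tree`.
#' @examples
#' bs <- make_ball_and_stick()
#' loop <- build_loop(bs)
#' loop$l                      # 1032 = 2 * 516
#' loop_point(loop, 0)         # the soma
#' @export
build_loop <- function(tree, spline = FALSE) {
  seg <- tree$segments
  idx <- function(id) match(id, seg$id)
  visits_seg <- integer(0)
  visits_dir <- integer(0)
  ## iterative depth-first closed walk; preference to unvisited children,
  ## ascending id as the deterministic tie-break
  walk <- function(children_of) {
    stack <- list(list(node = 0L, todo = children_of[["0"]]))
    while (length(stack) > 0L) {
      top <- stack[[length(stack)]]
      if (length(top$todo) == 0L) {
        stack[[length(stack)]] <- NULL
        if (top$node != 0L) {                     # go back up through `node`
          visits_seg <<- c(visits_seg, top$node)
          visits_dir <<- c(visits_dir, -1L)
        }
      } else {
        child <- top$todo[1L]
        stack[[length(stack)]]$todo <- top$todo[-1L]
        visits_seg <<- c(visits_seg, child)       # go down through `child`
        visits_dir <<- c(visits_dir, 1L)
        stack[[length(stack) + 1L]] <-
          list(node = child, todo = children_of[[as.character(child)]])
      }
    }
  }
  children_of <- split(seg$id, as.character(seg$parent))
  children_of <- lapply(children_of, sort)
  walk(children_of)
  lens <- seg$length[idx(visits_seg)]
  s1 <- cumsum(lens)
  visits <- data.frame(seg = visits_seg, dir = visits_dir,
                       s0 = c(0, s1[-length(s1)]), s1 = s1)
  loop <- structure(list(visits = visits, l = s1[length(s1)], tree = tree,
                         spline = isTRUE(spline)),
                    class = "morphology_loop")
  if (isTRUE(spline)) {
    knots_s <- c(visits$s0, loop$l)
    pts <- rbind(t(vapply(seq_len(nrow(visits)), function(i) {
      visit_endpoints(loop, i)$a
    }, numeric(3L))), tree$root_pos)
    loop$fx <- stats::splinefun(knots_s, pts[, 1L], method = "periodic")
    loop$fy <- stats::splinefun(knots_s, pts[, 2L], method = "periodic")
    loop$fz <- stats::splinefun(knots_s, pts[, 3L], method = "periodic")
  }
  loop
}

## proximal/distal endpoints of the i-th traversal, oriented along the walk
visit_endpoints <- function(loop, i) {
  v <- loop$visits[i, ]
  s <- loop$tree$segments[match(v$seg, loop$tree$segments$id), ]
  p0 <- c(s$x0, s$y0, s$z0)
  p1 <- c(s$x1, s$y1, s$z1)
  if (v$dir > 0L) list(a = p0, b = p1) else list(a = p1, b = p0)
}

#' @export
print.morphology_loop <- function(x, ...) {
  cat(sprintf("morphology_loop: %d traversals, length %.2f um (%s curve)\n",
              nrow(x$visits), x$l,
              if (isTRUE(x$spline)) "spline" else "piecewise-linear"))
  invisible(x)
}

#' Evaluate the loop curve at arc length s
#'
#' Maps arc-length positions on the morphology loop to 3-D coordinates
#' (micrometres). Values of `s` outside `[0, l)` are wrapped modulo `l`,
#' so `loop_point(loop, loop$l)` equals `loop_point(loop, 0)` (the root).
#'
#' @param loop a [build_loop()] result.
#' @param s numeric vector of arc lengths (micrometres).
#' @return A matrix with one row per `s` and columns `x`, `y`, `z`.
#' @export
loop_point <- function(loop, s) {
  s <- s %% loop$l
  if (isTRUE(loop$spline)) {
    out <- cbind(x = loop$fx(s), y = loop$fy(s), z = loop$fz(s))
    return(out)
  }
  v <- loop$visits
  i <- findInterval(s, v$s0, rightmost.closed = FALSE)
  fr <- (s - v$s0[i]) / (v$s1[i] - v$s0[i])
  out <- matrix(NA_real_, length(s), 3L, dimnames = list(NULL, c("x", "y", "z")))
  for (vi in unique(i)) {
    ep <- visit_endpoints(loop, vi)
    sel <- i == vi
    out[sel, ] <- rep(ep$a, each = sum(sel)) +
      fr[sel] %o% (ep$b - ep$a)
  }
  out
}

#' Map arc length to segment and fractional position
#'
#' Inverse bookkeeping of the loop traversal: every `s` lies on exactly one
#' traversal of one segment. The fraction is measured from the proximal end
#' of the segment, so the two traversals of an interior segment yield
#' mirrored fractions at mirrored `s`.
#'
#' @inheritParams loop_point
#' @return Data frame with columns `seg` (segment id), `frac` (position
#'   along the segment from its proximal end, in `[0, 1]`), `visit`
#'   (traversal index) and `dir`.
#' @export
loop_locate <- function(loop, s) {
  s <- s %% loop$l
  v <- loop$visits
  i <- findInterval(s, v$s0, rightmost.closed = FALSE)
  fr_walk <- (s - v$s0[i]) / (v$s1[i] - v$s0[i])
  data.frame(seg = v$seg[i],
             frac = ifelse(v$dir[i] > 0L, fr_walk, 1 - fr_walk),
             visit = i, dir = v$dir[i])
}

## Uniform midpoint quadrature grid on [0, l): G = ceiling(l / ds_target)
## points at s_g = (g - 1/2) * ds, with ds = l / G dividing l exactly.
loop_grid <- function(loop, ds_target) {
  G <- max(8L, as.integer(ceiling(loop$l / ds_target - 1e-12)))
  ds <- loop$l / G
  list(s = (seq_len(G) - 0.5) * ds, ds = ds, G = G)
}

#' Export the loop traversal order
#'
#' Returns (and optionally writes as tab-separated text) the ordered visit
#' sequence with its arc-length breakpoints. This is the ordering used by
#' the interval representation: the soma-adjacent cable comes first, then
#' the branches in loop order.
#'
#' @param loop a [build_loop()] result.
#' @param path optional output file; if given the table is written as TSV.
#' @return The visit table, invisibly when `path` is given.
#' @export
export_loop <- function(loop, path = NULL) {
  tab <- loop$visits
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(tab))
  }
  tab
}
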