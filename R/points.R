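# JSON point/axis files. Coordinates are always physical mm in the image's
# affine frame; voxel-index input is deliberately not accepted (0/1-based
# ambiguity).

#' Read a point file
#'
#' Accepts a JSON file containing either `{"point": [x, y, z]}`,
#' `{"points": [[...], [...], ...]}`, or a bare array. Coordinates are
#' physical mm.
#'
#' @param path JSON file path.
#' @return an n x 3 matrix of mm points.
#' @export
read_point_file <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  pts <- if (is.list(j) && !is.null(j$points)) j$points
         else if (is.list(j) && !is.null(j$point)) j$point
         else j
  if (!is.matrix(pts))
    pts <- matrix(as.numeric(unlist(pts)), ncol = 3, byrow = TRUE)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 3 || anyNA(pts))
    stop("point file must contain mm triples: ", path)
  pts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a point file
#'
#' @param pts n x 3 matrix or length-3 vector of mm points.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_point_file <- function(pts, path) {
  pts <- matrix(pts, ncol = 3)
  obj <- if (nrow(pts) == 1) list(point = as.numeric(pts[1, ]))
         else list(points = lapply(seq_len(nrow(pts)), function(i) pts[i, ]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an axis file
#'
#' Accepts either the package's own serialization
#' (`anchor`/`direction`/`t_min`/`t_max`, mm) or a physician two-point axis
#' (`points` list with exactly two mm triples, first basal, second apical),
#' which is converted to an axis anchored at the first point.
#'
#' @param path JSON file path.
#' @return an [lv_axis].
#' @export
read_axis_file <- function(path) {
  j <- jsonlite::fromJSON(path)
  if (!is.null(j$anchor)) {
    return(lv_axis(j$anchor, j$direction, j$t_min, j$t_max))
  }
  pts <- read_point_file(path)
  if (nrow(pts) != 2)
    stop("two-point axis file must contain exactly two points: ", path)
  d <- pts[2, ] - pts[1, ]
  lv_axis(pts[1, ], d, 0, sqrt(sum(d^2)))
}

#' Write an axis file
#'
#' @param axis an [lv_axis].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_axis_file <- function(axis, path) {
  jsonlite::write_json(
    list(anchor = axis$anchor, direction = axis$direction,
         t_min = axis$t_min, t_max = axis$t_max),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
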