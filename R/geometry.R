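#' Bounding-box geometry
#'
#' Boxes follow the MOT-16 convention: top-left origin, x to the right,
#' y downwards, continuous (float) pixel coordinates.  A box in
#' top-left/width/height ("tlwh") form is the numeric vector
#' `c(left, top, width, height)`; sets of boxes are matrices with one box
#' per row and those four columns.  The alternative "xyah" form used as
#' the Kalman measurement space is `c(cx, cy, a, h)` with `cx, cy` the
#' box centre, `a = width/height` the aspect ratio and `h` the height.
#'
#' @name geometry
NULL

# Coerce boxes to an n x 4 matrix and check validity.
as_box_matrix <- function(b, what = "box") {
  if (is.null(dim(b))) {
    if (length(b) != 4L) stop(what, " must have 4 elements (l, t, w, h)")
    b <- matrix(b, nrow = 1L)
  }
  b <- as.matrix(b)
  if (ncol(b) != 4L) stop(what, " matrix must have 4 columns (l, t, w, h)")
  storage.mode(b) <- "double"
  if (nrow(b) && (!all(is.finite(b)))) stop(what, ": coordinates must be finite")
  if (nrow(b) && (any(b[, 3L] <= 0) || any(b[, 4L] <= 0)))
    stop(what, ": width and height must be positive")
  b
}

#' Intersection over union of two boxes
#'
#' Continuous-area IoU; touching but non-overlapping boxes score 0.
#'
#' @param b1,b2 boxes in tlwh form (`c(left, top, width, height)`).
#' @return A scalar in `[0, 1]`.
#' @examples
#' box_iou(c(0, 0, 10, 10), c(5, 0, 10, 10))  # 1/3
#' @export
box_iou <- function(b1, b2) {
  m <- box_iou_matrix(as_box_matrix(b1), as_box_matrix(b2))
  m[1L, 1L]
}

#' Pairwise IoU matrix
#'
#' @param A,B matrices of boxes in tlwh form, one row per box.
#' @return A `nrow(A)` by `nrow(B)` matrix of IoU values.
#' @export
box_iou_matrix <- function(A, B) {
  A <- as_box_matrix(A, "A")
  B <- as_box_matrix(B, "B")
  nA <- nrow(A); nB <- nrow(B)
  if (nA == 0L || nB == 0L) return(matrix(numeric(0), nA, nB))
  l1 <- A[, 1L]; t1 <- A[, 2L]; r1 <- l1 + A[, 3L]; d1 <- t1 + A[, 4L]
  l2 <- B[, 1L]; t2 <- B[, 2L]; r2 <- l2 + B[, 3L]; d2 <- t2 + B[, 4L]
  iw <- pmin(outer(r1, r2, pmin) - outer(l1, l2, pmax), Inf)
  ih <- pmin(outer(d1, d2, pmin) - outer(t1, t2, pmax), Inf)
  iw[iw < 0] <- 0
  ih[ih < 0] <- 0
  inter <- iw * ih
  areaA <- A[, 3L] * A[, 4L]
  areaB <- B[, 3L] * B[, 4L]
  union <- outer(areaA, areaB, `+`) - inter
  inter / union
}

#' IoU matching cost matrix
#'
#' Entry `(i, j)` is `1 - IoU(track_i, det_j)`, the cost used by the
#' IOU association stages.
#'
#' @param tracks,dets matrices of boxes in tlwh form (possibly 0-row).
#' @return A `nrow(tracks)` by `nrow(dets)` cost matrix with entries in
#'   `[0, 1]`.
#' @export
iou_cost_matrix <- function(tracks, dets) {
  1 - box_iou_matrix(tracks, dets)
}

#' Convert between tlwh and xyah box forms
#'
#' `tlwh_to_xyah()` maps `c(l, t, w, h)` to the measurement-space form
#' `c(cx, cy, a, h)`; `xyah_to_tlwh()` is its exact inverse.
#'
#' @param b a box (vector) or boxes (matrix rows) in the source form.
#' @return The converted box(es), same shape as the input.
#' @export
tlwh_to_xyah <- function(b) {
  vec <- is.null(dim(b))
  m <- as_box_matrix(b)
  out <- cbind(m[, 1L] + m[, 3L] / 2, m[, 2L] + m[, 4L] / 2,
               m[, 3L] / m[, 4L], m[, 4L])
  colnames(out) <- c("cx", "cy", "a", "h")
  if (vec) out[1L, ] else out
}

#' @rdname tlwh_to_xyah
#' @export
xyah_to_tlwh <- function(b) {
  vec <- is.null(dim(b))
  if (vec) b <- matrix(b, nrow = 1L)
  b <- as.matrix(b)
  if (ncol(b) != 4L) stop("xyah box must have 4 columns")
  if (nrow(b) && (any(b[, 3L] <= 0) || any(b[, 4L] <= 0)))
    stop("aspect ratio and height must be positive")
  w <- b[, 3L] * b[, 4L]
  out <- cbind(b[, 1L] - w / 2, b[, 2L] - b[, 4L] / 2, w, b[, 4L])
  colnames(out) <- c("l", "t", "w", "h")
  if (vec) out[1L, ] else out
}
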