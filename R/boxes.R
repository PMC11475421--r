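#' Box geometry and parameterisations
#'
#' Bounding boxes cross the package in two forms. At every file boundary a box
#' is `(left, top, width, height)` in pixels with the origin at the image's
#' top-left (the MOTChallenge convention). Inside the Kalman filter the same
#' box is the observation vector `z = (u, v, s, r)`: centre coordinates,
#' area `s = w * h` and aspect ratio `r = w / h`. These two helpers are the
#' single conversion point between the conventions.
#'
#' @param box numeric vector `(left, top, width, height)`, width and height
#'   strictly positive.
#' @return `box_to_obs()` returns the observation vector `(u, v, s, r)`;
#'   `obs_to_box()` inverts it back to `(left, top, width, height)`.
#' @examples
#' z <- box_to_obs(c(10, 20, 30, 40))
#' obs_to_box(z)
#' @export
box_to_obs <- function(box) {
  stopifnot(length(box) == 4, box[3] > 0, box[4] > 0)
  c(u = box[[1]] + box[[3]] / 2,
    v = box[[2]] + box[[4]] / 2,
    s = box[[3]] * box[[4]],
    r = box[[3]] / box[[4]])
}

#' @param z numeric vector `(u, v, s, r)` with `s > 0`, `r > 0`.
#' @rdname box_to_obs
#' @export
obs_to_box <- function(z) {
  stopifnot(length(z) == 4)
  s <- max(z[[3]], .Machine$double.eps)
  r <- max(z[[4]], .Machine$double.eps)
  w <- sqrt(s * r)
  h <- s / w
  c(left = z[[1]] - w / 2, top = z[[2]] - h / 2, width = w, height = h)
}

#' Intersection over union of two boxes
#'
#' @param box_a,box_b boxes as `(left, top, width, height)`.
#' @return IoU in `[0, 1]`; symmetric in its arguments.
#' @examples
#' iou(c(0, 0, 10, 10), c(5, 0, 10, 10)) # 1/3
#' @export
iou <- function(box_a, box_b) {
  ix <- min(box_a[1] + box_a[3], box_b[1] + box_b[3]) - max(box_a[1], box_b[1])
  iy <- min(box_a[2] + box_a[4], box_b[2] + box_b[4]) - max(box_a[2], box_b[2])
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  inter / (box_a[3] * box_a[4] + box_b[3] * box_b[4] - inter)
}

#' IoU matrix between two sets of boxes
#'
#' @param boxes_a,boxes_b matrices with one `(left, top, width, height)` row
#'   per box (zero-row matrices allowed).
#' @return `nrow(boxes_a) x nrow(boxes_b)` matrix of pairwise IoU values.
#' @export
iou_matrix <- function(boxes_a, boxes_b) {
  na <- nrow(boxes_a); nb <- nrow(boxes_b)
  out <- matrix(0, na, nb)
  if (na == 0L || nb == 0L) return(out)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    out[i, j] <- iou(boxes_a[i, ], boxes_b[j, ])
  }
  out
}
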