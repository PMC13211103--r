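# Shared helpers: seeded evaluation, box arithmetic, validation.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so library functions are deterministic
#' without disturbing the caller's RNG stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stopf <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "stripedet_error")))
}

#' Validate a box matrix against image bounds
#'
#' Boxes are 0-based half-open pixel coordinates `[x1, x2) x [y1, y2)`.
#' @param boxes numeric matrix with columns x1, y1, x2, y2.
#' @param width,height image size in pixels (or 1 for normalized boxes).
#' @keywords internal
check_boxes <- function(boxes, width, height) {
  if (length(boxes) == 0L) return(invisible(boxes))
  ok <- boxes[, 1] >= 0 & boxes[, 1] < boxes[, 3] & boxes[, 3] <= width &
        boxes[, 2] >= 0 & boxes[, 2] < boxes[, 4] & boxes[, 4] <= height
  if (!all(ok)) {
    stopf("stripedet_box_error", "box %d violates 0 <= x1 < x2 <= %s, 0 <= y1 < y2 <= %s",
          which(!ok)[1], format(width), format(height))
  }
  invisible(boxes)
}

box_matrix <- function(x1 = numeric(), y1 = numeric(),
                       x2 = numeric(), y2 = numeric()) {
  m <- cbind(x1 = x1, y1 = y1, x2 = x2, y2 = y2)
  storage.mode(m) <- "double"
  m
}

#' Intersection-over-union of two boxes
#'
#' Half-open convention: a box `(x1, y1, x2, y2)` has area
#' `(x2 - x1) * (y2 - y1)`.
#' @param a,b numeric vectors `c(x1, y1, x2, y2)`.
#' @return IoU in `[0, 1]`; degenerate boxes give 0 with a warning.
#' @export
#' @examples
#' iou(c(0, 0, 10, 10), c(5, 0, 15, 10))  # 50 / 150
iou <- function(a, b) {
  aa <- (a[3] - a[1]) * (a[4] - a[2])
  ab <- (b[3] - b[1]) * (b[4] - b[2])
  if (aa <= 0 || ab <= 0) {
    warning("degenerate box in iou(); returning 0")
    return(0)
  }
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / (aa + ab - inter)
}

# Pairwise IoU: boxes as n x 4 and m x 4 matrices -> n x m
iou_matrix <- function(a, b) {
  n <- nrow(a); m <- nrow(b)
  out <- matrix(0, n, m)
  if (n == 0L || m == 0L) return(out)
  aa <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  ab <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  for (j in seq_len(m)) {
    iw <- pmin(a[, 3], b[j, 3]) - pmax(a[, 1], b[j, 1])
    ih <- pmin(a[, 4], b[j, 4]) - pmax(a[, 2], b[j, 2])
    inter <- pmax(iw, 0) * pmax(ih, 0)
    out[, j] <- inter / (aa + ab[j] - inter)
  }
  out
}

#' Default class-name table
#'
#' The synthetic scenes use three fruit classes: two green morphs and one
#' red, loosely mimicking green pepper / green chili / red chili.
#' @param n number of classes.
#' @return character vector of class names; labels are 1-based indices into
#'   this table.
#' @export
default_classes <- function(n = 3L) {
  base <- c("green_a", "green_b", "red")
  if (n <= 3L) base[seq_len(n)] else c(base, paste0("class", seq_len(n - 3L) + 3L))
}
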