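#' Build a homothetic anchor frame
#'
#' An anchor frame is the ordered list of `(source cM, destination cM)`
#' pairs for one chromosome, through which positions are projected from
#' one map's coordinates into another's. Anchors sharing a source position
#' are collapsed to a single anchor at the mean of their destination
#' positions, so source positions are strictly increasing afterwards.
#'
#' @param src,dst numeric vectors of equal length: positions of the shared
#'   anchor markers on the source and destination map.
#' @return An `anchor_frame`: data.frame with columns `src` and `dst`,
#'   sorted by `src`.
#' @export
anchor_frame <- function(src, dst) {
  stopifnot(length(src) == length(dst))
  keep <- !(is.na(src) | is.na(dst))
  src <- src[keep]; dst <- dst[keep]
  o <- order(src, dst, method = "radix")
  src <- src[o]; dst <- dst[o]
  if (anyDuplicated(src)) {
    dst <- as.numeric(tapply(dst, factor(src, levels = unique(src)), mean))
    src <- unique(src)
  }
  structure(data.frame(src = src, dst = dst),
            class = c("anchor_frame", "data.frame"))
}

#' @rdname anchor_frame
#' @param frame an `anchor_frame`.
#' @export
n_anchors <- function(frame) nrow(frame)

#' Project positions through an anchor frame
#'
#' Homothetic (piecewise-linear) projection: a position `p` lying between
#' consecutive anchors `(a_s, a_d)` and `(b_s, b_d)` maps to
#' `a_d + (p - a_s) * (b_d - a_d) / (b_s - a_s)`, i.e. its relative
#' distance to the flanking shared markers is preserved. Positions beyond
#' the terminal anchors extend the adjacent interval's scale factor (scale
#' 1 if that interval has zero destination length). The projection is
#' monotone non-decreasing whenever the frame's destination positions are.
#'
#' @param p numeric vector of source-map positions (cM).
#' @param frame an [anchor_frame()] with at least two anchors.
#' @return Numeric vector of destination-map positions.
#' @examples
#' fr <- anchor_frame(c(0, 10, 30), c(0, 15, 30))
#' project_position(c(5, 20), fr)  # 7.5, 22.5
#' @export
project_position <- function(p, frame) {
  if (n_anchors(frame) < 2L) {
    stop("projection requires at least 2 anchors (got ", n_anchors(frame), ")")
  }
  src <- frame$src
  dst <- frame$dst
  n <- length(src)
  # interval index: p in [src[i], src[i+1]) -> i, clamped to terminal intervals
  i <- findInterval(p, src, all.inside = TRUE)
  scale <- (dst[i + 1L] - dst[i]) / (src[i + 1L] - src[i])
  # terminal extrapolation with a degenerate destination interval: scale 1
  degen <- scale == 0 & (p < src[1L] | p > src[n])
  scale[degen] <- 1
  dst[i] + (p - src[i]) * scale
}

#' Invert an anchor frame
#'
#' Swaps source and destination coordinates. Only valid when the
#' destination positions are strictly increasing.
#'
#' @param frame an `anchor_frame`.
#' @return The inverse `anchor_frame`.
#' @export
invert_frame <- function(frame) {
  if (any(diff(frame$dst) <= 0)) {
    stop("frame is not invertible: destination positions not strictly increasing")
  }
  anchor_frame(frame$dst, frame$src)
}
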