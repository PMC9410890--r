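#' Pearson correlation between two channels
#'
#' Sample linear correlation of the two channels' intensities over the
#' analysis mask, describing how signal changes in one channel follow the
#' other across the image. Intended for background-subtracted images.
#'
#' @param a,b Numeric matrices (or vectors) of equal shape: the two
#'   channels.
#' @param mask Optional logical matrix of the same shape selecting the
#'   pixels to analyse (default: all).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(a, b, mask = NULL) {
  v <- coloc_pixels(a, b, mask)
  if (length(v$a) < 2L) stop("need at least 2 masked pixels")
  if (sd(v$a) == 0 || sd(v$b) == 0) {
    stop("undefined correlation: a channel is constant over the mask")
  }
  cor(v$a, v$b)
}

#' Manders colocalization coefficients
#'
#' Computes the intensity-weighted Manders coefficients
#' `M1 = sum(A over pixels with B > tB) / sum(A)` and
#' `M2 = sum(B over pixels with A > tA) / sum(B)`, plus a pixel-count
#' reading of M2, the fraction of B-positive pixels that also carry A
#' signal: `count(A > tA and B > tB) / count(B > tB)`. Both variants are
#' reported because published legends sometimes describe the pixel-count
#' quantity while standard plugins compute the intensity-weighted one.
#'
#' @param a,b Numeric matrices (or vectors) of equal shape, non-negative
#'   (background-subtracted).
#' @param tA,tB Channel thresholds (default 0: any signal above zero
#'   counts as positive).
#' @param mask Optional logical mask.
#' @return List with `m1`, `m2`, `m2_pixel`, and the thresholds used.
#' @export
manders <- function(a, b, tA = 0, tB = 0, mask = NULL) {
  stopifnot(tA >= 0, tB >= 0)
  v <- coloc_pixels(a, b, mask)
  if (any(v$a < 0) || any(v$b < 0)) {
    stop("channels must be non-negative (background-subtracted)")
  }
  sum_a <- sum(v$a); sum_b <- sum(v$b)
  n_bpos <- sum(v$b > tB)
  if (sum_a <= 0 || sum_b <= 0 || n_bpos == 0L) {
    stop("undefined Manders coefficient: a denominator is zero ",
         "(no positive signal)")
  }
  list(m1 = sum(v$a[v$b > tB]) / sum_a,
       m2 = sum(v$b[v$a > tA]) / sum_b,
       m2_pixel = sum(v$a > tA & v$b > tB) / n_bpos,
       tA = tA, tB = tB)
}

coloc_pixels <- function(a, b, mask) {
  if (!identical(dim(a), dim(b)) || length(a) != length(b)) {
    stop("channel shapes differ")
  }
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("channel intensities must be finite")
  }
  if (is.null(mask)) {
    list(a = as.numeric(a), b = as.numeric(b))
  } else {
    stopifnot(identical(dim(mask), dim(a)) || length(mask) == length(a))
    list(a = as.numeric(a)[as.logical(mask)],
         b = as.numeric(b)[as.logical(mask)])
  }
}
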