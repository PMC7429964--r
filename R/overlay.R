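# Calibration of the projective mapping between the dynamic-imaging and
# fluorescence cameras, and grey-plus-red overlay rendering.

#' Fit a projective transform (homography) to point correspondences
#'
#' Least-squares homography through the normalised direct linear transform:
#' both point sets are translated to their centroid and scaled to mean
#' distance \eqn{\sqrt 2} before the 2n x 9 design matrix is solved by SVD.
#' Requires at least 4 pairs in general position (no 3 collinear among any 4
#' used).  The root-mean-square reprojection error is attached as attribute
#' \code{"rms"}.
#'
#' @param pointsA n x 2 matrix of \code{(x, y)} coordinates in camera A.
#' @param pointsB n x 2 matrix of matching coordinates in camera B.
#' @return a projective \linkS4class{PlanarTransform} mapping A onto B.
#' @export
fitProjective <- function(pointsA, pointsB) {
  A <- as.matrix(pointsA); B <- as.matrix(pointsB)
  if (nrow(A) != nrow(B))
    .err("point sets must have equal counts", "dynoct_bad_args")
  if (nrow(A) < 4L)
    .err("at least 4 correspondences are required", "dynoct_degenerate")
  normalise <- function(P) {
    ctr <- colMeans(P)
    d <- sqrt(rowSums(sweep(P, 2L, ctr)^2))
    s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
    T <- rbind(c(s, 0, -s * ctr[1L]), c(0, s, -s * ctr[2L]), c(0, 0, 1))
    list(T = T, P = transformPoints(planarTransform("projective", T), P))
  }
  na <- normalise(A); nb <- normalise(B)
  M <- matrix(0, 2L * nrow(A), 9L)
  for (i in seq_len(nrow(A))) {
    x <- na$P[i, 1L]; y <- na$P[i, 2L]
    u <- nb$P[i, 1L]; v <- nb$P[i, 2L]
    M[2L * i - 1L, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    M[2L * i, ] <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  sv <- svd(M, nu = 0, nv = 9L)
  # rank deficiency beyond the 1D homography null space => degenerate layout
  if (length(sv$d) < 8L || sv$d[8L] < 1e-8 * sv$d[1L])
    .err("degenerate point configuration (collinear points?)",
         "dynoct_degenerate")
  H <- matrix(sv$v[, 9L], 3L, 3L, byrow = TRUE)
  H <- solve(nb$T) %*% H %*% na$T
  tr <- planarTransform("projective", H)
  proj <- transformPoints(tr, A)
  attr(tr, "rms") <- sqrt(mean(rowSums((proj - B)^2)))
  tr
}

.minmax <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(if (rng[2L] > 0) x / rng[2L] else x * 0)
  (x - rng[1L]) / diff(rng)
}

#' Overlay fluorescence in red on a greyscale dynamic-amplitude image
#'
#' The dynamic value channel is inserted into all three RGB channels and the
#' registered fluorescence image is added to the red channel only, so the
#' dynamic image appears in greyscale with fluorescence superimposed in red.
#' Both inputs are min-max normalised; the fluorescence image is warped onto
#' the value-channel grid through the calibrated camera-to-camera transform.
#'
#' @param value greyscale dynamic-amplitude matrix.
#' @param fluorescence single-channel fluorescence matrix.
#' @param transform \linkS4class{PlanarTransform} mapping value-channel
#'   coordinates onto fluorescence coordinates.
#' @param alpha fluorescence gain added into the red channel (default 1).
#' @return (y, x, 3) RGB array in [0, 1] with R = clip(value + alpha * fluo),
#'   G = B = value.
#' @export
buildOverlay <- function(value, fluorescence, transform, alpha = 1) {
  stopifnot(is(transform, "PlanarTransform"))
  if (abs(det(transform@matrix)) < 1e-12)
    .err("transform is not invertible", "dynoct_bad_args")
  v <- .minmax(as.matrix(value))
  fReg <- warpImage(as.matrix(fluorescence), transform,
                    outputDim = dim(v), direction = "backward")
  fReg <- .minmax(fReg)
  R <- pmin(v + alpha * fReg, 1)
  array(c(R, v, v), dim = c(dim(v), 3L))
}

#' Read point correspondences from CSV
#'
#' @param path CSV file with columns \code{x_a, y_a, x_b, y_b}.
#' @return list with matrices \code{a} and \code{b}.
#' @export
readCorrespondences <- function(path) {
  d <- utils::read.csv(path)
  need <- c("x_a", "y_a", "x_b", "y_b")
  if (!all(need %in% names(d)))
    .err("correspondence file needs columns x_a, y_a, x_b, y_b",
         "dynoct_bad_args")
  list(a = cbind(d$x_a, d$y_a), b = cbind(d$x_b, d$y_b))
}
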