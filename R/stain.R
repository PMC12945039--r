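## Stain separation: Beer-Lambert optical densities, H-DAB colour
## deconvolution and the 0-255 DAB pseudo-intensity convention
## (255 = unstained white, ~25 = dense brown at OD 1).

#' Construct a stain basis
#'
#' @param vectors 3x3 numeric matrix; rows are the hematoxylin, DAB and
#'   residual OD direction vectors (any positive scale; rows are normalised
#'   to unit length).
#' @return a [StainBasis-class].
#' @export
#' @examples
#' stainBasis(diag(3))
stainBasis <- function(vectors) {
  v <- as.matrix(vectors)
  if (!identical(dim(v), c(3L, 3L)))
    stop("stain basis must be a 3x3 matrix")
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm == 0)) stop("stain vectors must be non-zero")
  v <- v / nrm
  dimnames(v) <- list(c("hematoxylin", "dab", "residual"), c("r", "g", "b"))
  new("StainBasis", vectors = v)
}

#' Default H-DAB stain vectors
#'
#' The Ruifrok-Johansen hematoxylin and DAB OD vectors, with the residual
#' channel built per channel as sqrt(1 - H_c^2 - D_c^2) and normalised --
#' the standard completion used by colour-deconvolution implementations when
#' only two stains are specified.
#'
#' @return a [StainBasis-class].
#' @export
#' @examples
#' hdabBasis()
hdabBasis <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.268, 0.570, 0.776)
  r <- sqrt(pmax(0, 1 - h^2 - d^2))
  stainBasis(rbind(h, d, r))
}

#' Convert RGB intensities to optical densities
#'
#' Per-channel Beer-Lambert transform
#' \code{OD_c = -log10((I_c + 1) / (background_c + 1))}, clamped below at 0.
#' The +1 offset bounds the OD at pixel value 0 without special-casing.
#'
#' @param image integer array \code{[height, width, 3]} with values 0-255.
#' @param background per-channel white reference, values in (0, 255].
#' @return numeric array \code{[height, width, 3]} of optical densities.
#' @export
#' @examples
#' px <- array(c(255, 128, 0), dim = c(1, 1, 3))
#' rgbToOD(px)
rgbToOD <- function(image, background = c(255, 255, 255)) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("image must be a height x width x 3 array")
  if (length(background) != 3L || any(background <= 0) ||
      any(background > 255))
    stop("background values must lie in (0, 255]")
  if (any(image < 0 | image > 255)) stop("image values must lie in [0, 255]")
  od <- array(0, dim = dim(image))
  for (c in 1:3)
    od[, , c] <- pmax(0, -log10((image[, , c] + 1) / (background[c] + 1)))
  od
}

#' Separate an OD image into per-stain maps
#'
#' Per-pixel least-squares projection of the 3-vector of optical densities
#' onto the stain basis; negative coefficients are clamped to zero.
#'
#' @param od numeric array \code{[height, width, 3]} from [rgbToOD()].
#' @param basis a [StainBasis-class].
#' @return named list of matrices \code{hematoxylin}, \code{dab},
#'   \code{residual}, each \code{[height, width]}, non-negative.
#' @export
#' @examples
#' b <- hdabBasis()
#' od <- array(0.5 * stainVectors(b)["hematoxylin", ], dim = c(1, 1, 3))
#' separateStains(od, b)
separateStains <- function(od, basis = hdabBasis()) {
  stopifnot(is(basis, "StainBasis"))
  validObject(basis)
  m <- basis@vectors
  if (.condNumber(m) >= 1e6)
    stop("degenerate stain basis: condition number >= 1e6")
  d <- dim(od)
  if (length(d) != 3L || d[3] != 3L)
    stop("od must be a height x width x 3 array")
  ## least squares per pixel: coef = od . M' (M M')^-1, accumulated channel
  ## by channel to keep the peak memory at one plane per stain
  proj <- t(m) %*% solve(m %*% t(m))    # 3x3; column i projects stain i
  plane <- function(c) {
    p <- od[, , c, drop = FALSE]
    dim(p) <- d[1:2]
    p
  }
  out <- vector("list", 3L)
  for (i in 1:3) {
    acc <- plane(1) * proj[1, i]
    acc <- acc + plane(2) * proj[2, i]
    acc <- acc + plane(3) * proj[3, i]
    acc[acc < 0] <- 0
    out[[i]] <- acc
  }
  names(out) <- c("hematoxylin", "dab", "residual")
  out
}

#' DAB pseudo-intensity map
#'
#' Maps DAB optical density to the 0-255 pseudo-intensity convention:
#' \code{255 * 10^(-OD)}, clamped to [0, 255] and kept real-valued (no
#' rounding) until per-nucleus averaging. OD 0 maps to 255 (unstained);
#' OD 1 maps to 25.5, the "dark brown" floor of the convention.
#'
#' @param dab non-negative matrix of DAB optical densities.
#' @return matrix of pseudo-intensities in [0, 255]; lower = more DAB.
#' @export
#' @examples
#' dabPseudoIntensity(matrix(c(0, 1), 1))
dabPseudoIntensity <- function(dab) {
  if (any(dab < 0)) stop("DAB optical densities must be non-negative")
  out <- 255 * 10^(-dab)
  out[out > 255] <- 255
  out[out < 0] <- 0
  out
}
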