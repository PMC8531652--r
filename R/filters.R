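#' Kernel size for Gaussian derivative filters
#'
#' The support of each 1D Gaussian-derivative kernel grows with the scale
#' and the derivative order as
#' `sigma * (3 + 0.25*order - 2.5*(order-6) / ((order-6)^2 + (order-9)^2))`,
#' rounded up to the nearest odd integer so kernels stay centered.
#'
#' @param sigma Gaussian scale in px (> 0).
#' @param order derivative order (>= 0) of the 1D kernel.
#' @param round if `FALSE`, return the raw (un-rounded) size.
#' @return odd integer kernel size in px (or the raw value).
#' @export
gaussian_filter_size <- function(sigma, order, round = TRUE) {
  stopifnot(sigma > 0, order >= 0)
  raw <- sigma * (3 + 0.25 * order -
                    2.5 * (order - 6) / ((order - 6)^2 + (order - 9)^2))
  if (!round) return(raw)
  s <- ceiling(raw)
  if (s %% 2 == 0) s <- s + 1
  as.integer(max(3L, s))
}

# 1D Gaussian (order 0), first- or second-derivative kernel, sampled on
# -h..h and normalized so that (under correlation) a smoothing kernel sums
# to 1, a first-derivative kernel maps the ramp f(x)=x to 1, and a
# second-derivative kernel maps f(x)=x^2/2 to 1.
gaussian_kernel_1d <- function(sigma, order, size = gaussian_filter_size(sigma, order)) {
  h <- (size - 1) / 2
  xs <- seq(-h, h)
  g <- exp(-xs^2 / (2 * sigma^2))
  if (order == 0) {
    k <- g / sum(g)
  } else if (order == 1) {
    k <- xs * g
    k <- k / sum(xs * k)
  } else if (order == 2) {
    k <- (xs^2 / sigma^4 - 1 / sigma^2) * g
    k <- k - g * sum(k) / sum(g)       # zero DC response
    k <- k / sum(xs^2 / 2 * k)
  } else {
    stop("derivative orders above 2 are not used by the feature bank")
  }
  k
}

# kernels for the three axes; the z kernel is shrunk (with a flag) when its
# half-width would exceed the stack's z extent minus one, so reflective
# padding stays well defined
axis_kernels <- function(sigma, orders, dims) {
  truncated <- FALSE
  build <- function(order, n) {
    size <- gaussian_filter_size(sigma, order)
    max_size <- 2L * (n - 1L) + 1L
    if (size > max_size && n > 1L) {
      truncated <<- TRUE
      size <- if (max_size %% 2 == 0) max_size - 1L else max_size
    }
    if (n == 1L) {
      if (order > 0) return(NULL)   # no z extent: skip axis entirely
      return(1)
    }
    gaussian_kernel_1d(sigma, order, size)
  }
  list(ky = build(orders[1], dims[1]), kx = build(orders[2], dims[2]),
       kz = build(orders[3], dims[3]), truncated = truncated)
}

# separable 3D convolution (correlation) with reflective boundary
conv3d_sep <- function(vol, ky = NULL, kx = NULL, kz = NULL) {
  if (!is.null(ky) && length(ky) > 1) vol <- conv3d_axis(vol, ky, 0L)
  if (!is.null(kx) && length(kx) > 1) vol <- conv3d_axis(vol, kx, 1L)
  if (!is.null(kz) && length(kz) > 1) vol <- conv3d_axis(vol, kz, 2L)
  vol
}

# Gaussian smoothing of a 3D array, per-axis sigmas (0 = skip axis)
gaussian_smooth3d <- function(vol, sigma = c(1, 1, 1)) {
  dims <- dim(vol)
  ks <- lapply(1:3, function(a) {
    if (sigma[a] <= 0 || dims[a] == 1L) return(NULL)
    size <- gaussian_filter_size(sigma[a], 0)
    max_size <- 2L * (dims[a] - 1L) + 1L
    if (size > max_size) size <- if (max_size %% 2 == 0) max_size - 1L else max_size
    gaussian_kernel_1d(sigma[a], 0, size)
  })
  conv3d_sep(vol, ks[[1]], ks[[2]], ks[[3]])
}

# Gaussian derivative of a volume; orders = c(order_y, order_x, order_z)
gaussian_derivative3d <- function(vol, sigma, orders) {
  ks <- axis_kernels(sigma, orders, dim(vol))
  if ((is.null(ks$kz) && orders[3] > 0)) {
    # single-slice stack cannot support a z derivative: return zeros
    return(array(0, dim = dim(vol)))
  }
  structure(conv3d_sep(vol, ks$ky, ks$kx, ks$kz), truncated = ks$truncated)
}

# reflective-padding 2D convolution for non-separable kernels (LGF); uses
# EBImage's FFT convolution on a reflect-padded copy
conv2d_reflect <- function(mat, kernel) {
  h <- (dim(kernel) - 1) / 2
  ny <- nrow(mat); nx <- ncol(mat)
  ri <- c(rev(seq_len(min(h[1], ny))), seq_len(ny),
          ny + 1 - rev(seq_len(min(h[1], ny))))
  ci <- c(rev(seq_len(min(h[2], nx))), seq_len(nx),
          nx + 1 - rev(seq_len(min(h[2], nx))))
  padded <- mat[ri, ci, drop = FALSE]
  out <- EBImage::filter2(padded, kernel, boundary = "circular")
  r0 <- min(h[1], ny); c0 <- min(h[2], nx)
  out[(r0 + 1):(r0 + ny), (c0 + 1):(c0 + nx), drop = FALSE]
}

# generalized Laguerre polynomial L_p (alpha = 0) via the standard recurrence
laguerre_poly <- function(p, x) {
  if (p == 0) return(rep(1, length(x)) * (x * 0 + 1))
  lm2 <- 1 + 0 * x
  lm1 <- 1 - x
  if (p == 1) return(lm1)
  for (k in 2:p) {
    lk <- ((2 * k - 1 - x) * lm1 - (k - 1) * lm2) / k
    lm2 <- lm1
    lm1 <- lk
  }
  lm1
}

#' Laguerre-Gauss filter kernel
#'
#' Blob-sensitive radially weighted kernels with Gaussian envelope, indexed
#' by radial order `p` and azimuthal order `l`. The implemented closed form
#' on a pixel at polar coordinates `(rho, theta)` with `u = rho * s` is
#'
#' `exp(-u^2/q) * u^(l/q) * (cos(l*(theta + 2*pi*r/max(2l, 1))) * L_p(u * atan(u)))^(3-q)`
#'
#' with `L_p` the Laguerre polynomial of order `p`. For the reference
#' parameters (`s = 0.5`, `q = 2`, `r = 0`) the outer exponent is 1 and the
#' kernel is real; `l = 0` kernels are rotationally symmetric. `r`
#' parameterizes additional rotated copies of the anisotropic (`l > 0`)
#' kernels; since pycnotic nuclei are point symmetric, rotations add little
#' and the reference bank fixes `r = 0` (enforced when `strict = TRUE`).
#'
#' @param p radial order (0, 1, 2 in the reference bank).
#' @param l azimuthal order (0, 1, 2 in the reference bank).
#' @param s radial scale factor (default 0.5).
#' @param q envelope divisor (default 2; the only value for which the outer
#'   exponent `3 - q` keeps sign-changing angular terms real).
#' @param r rotation index (default 0).
#' @param size odd kernel width in px (default 21, covering the Gaussian
#'   envelope to below 1e-5 at `s = 0.5`).
#' @param strict reject non-reference `r` values.
#' @return a `size` x `size` numeric kernel.
#' @export
lgf_kernel <- function(p, l, s = 0.5, q = 2, r = 0, size = 21, strict = FALSE) {
  stopifnot(p >= 0, l >= 0, size %% 2 == 1)
  if (strict && r != 0)
    stop("strict mode: the reference bank uses r = 0 only")
  h <- (size - 1) / 2
  x <- matrix(seq(-h, h), size, size, byrow = TRUE)
  y <- matrix(seq(-h, h), size, size)
  rho <- sqrt(x^2 + y^2)
  theta <- atan2(y, x)
  u <- rho * s
  env <- exp(-u^2 / q) * u^(l / q)
  base <- cos(l * (theta + 2 * pi * r / max(2 * l, 1))) *
    laguerre_poly(p, u * atan(u))
  expo <- 3 - q
  if (abs(expo - round(expo)) > 1e-9 && any(base < 0))
    stop("non-integer outer exponent with a sign-changing angular term")
  env * base^round(expo)
}

#' Structure tensor of a stack, per z-slice
#'
#' Per-pixel 2x2 gradient outer product, Gaussian smoothed: gradients are
#' Gaussian derivatives at `sigma_grad`, the products are smoothed with a
#' Gaussian of `sigma_tensor` (both in-plane; each z-slice is treated as an
#' independent image, matching the planar definition of orientation
#' coherency).
#'
#' @param stack an [image_stack()] (normalized) or 3D array.
#' @param sigma_grad gradient scale in px.
#' @param sigma_tensor integration scale in px.
#' @return list of arrays `jxx`, `jxy`, `jyy`.
#' @export
structure_tensor <- function(stack, sigma_grad = 1, sigma_tensor = 3) {
  a <- if (inherits(stack, "image_stack")) stack$data else stack
  gx <- gaussian_derivative3d(a, sigma_grad, c(0, 1, 0))
  gy <- gaussian_derivative3d(a, sigma_grad, c(1, 0, 0))
  smooth2d <- function(v) {
    k <- gaussian_kernel_1d(sigma_tensor, 0)
    conv3d_sep(v, ky = k, kx = k)
  }
  list(jxx = smooth2d(gx * gx), jxy = smooth2d(gx * gy),
       jyy = smooth2d(gy * gy))
}

#' Orientation coherency image
#'
#' For each pixel, the eigenvalue contrast of the structure tensor,
#' `C = ((lambda1 - lambda2) / (lambda1 + lambda2))^2`: 0 for isotropic
#' neighborhoods, 1 for perfectly oriented (1D) structure. Where the
#' eigenvalue sum (the tensor trace) falls below `tol` the orientation is
#' undefined and `C` is set to 0.
#'
#' @param stack an [image_stack()] (normalized) or 3D array.
#' @param sigma_grad,sigma_tensor see [structure_tensor()].
#' @param tol trace tolerance below which `C = 0`.
#' @return 3D array of coherency values in `[0, 1]`.
#' @export
coherency_image <- function(stack, sigma_grad = 1, sigma_tensor = 3,
                            tol = 1e-12) {
  st <- structure_tensor(stack, sigma_grad, sigma_tensor)
  tr <- st$jxx + st$jyy
  # lambda1 - lambda2 = 2 * sqrt(((jxx-jyy)/2)^2 + jxy^2)
  gap <- 2 * sqrt(((st$jxx - st$jyy) / 2)^2 + st$jxy^2)
  C <- array(0, dim = dim(tr))
  ok <- tr > tol
  C[ok] <- (gap[ok] / tr[ok])^2
  C[C > 1] <- 1   # guard against roundoff at the boundary
  C
}

# disc structuring element of the given diameter on the smallest odd grid
disc_brush <- function(size) {
  h <- floor(size / 2)
  w <- 2L * h + 1L
  x <- matrix(seq(-h, h), w, w, byrow = TRUE)
  y <- matrix(seq(-h, h), w, w)
  (x^2 + y^2 <= (size / 2)^2) * 1
}

#' White top-hat transform, per z-slice
#'
#' Image minus its grayscale opening with a disc structuring element;
#' isolates bright structures smaller than the disc. `size` is the disc
#' diameter in px (the element lives on the smallest odd grid covering it).
#'
#' @param stack an [image_stack()] or 3D array.
#' @param size disc diameter in px.
#' @return 3D array of the same shape.
#' @export
tophat_filter <- function(stack, size) {
  a <- if (inherits(stack, "image_stack")) stack$data else stack
  brush <- disc_brush(size)
  out <- a
  for (k in seq_len(dim(a)[3])) {
    sl <- a[, , k]
    out[, , k] <- sl - EBImage::opening(sl, brush)
  }
  out
}

#' Local entropy filter, per z-slice
#'
#' Shannon entropy (bits) of the intensity histogram in a square
#' neighborhood, computed on a copy quantized to `nlevels` gray levels
#' (windows are clipped at the image border). Flat regions give 0,
#' textured regions approach `log2(nlevels)`.
#'
#' @param stack an [image_stack()] (normalized to `[0, 1]`) or 3D array.
#' @param size odd square window width in px.
#' @param nlevels number of quantization levels (default 64).
#' @return 3D array of the same shape.
#' @export
entropy_filter <- function(stack, size, nlevels = 64L) {
  a <- if (inherits(stack, "image_stack")) stack$data else stack
  q <- pmin(floor(pmax(a, 0) * nlevels), nlevels - 1L)
  storage.mode(q) <- "integer"
  out <- array(0, dim = dim(a))
  for (k in seq_len(dim(a)[3])) {
    out[, , k] <- local_entropy2d(q[, , k, drop = TRUE], as.integer(size),
                                  as.integer(nlevels))
  }
  out
}
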