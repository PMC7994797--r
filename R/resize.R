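#' Bilinear resampling of a 2D slice
#'
#' Half-pixel-center convention: output pixel i samples the input at
#' coordinate `(i - 0.5) * in/out - 0.5` (0-based), clamped to the image,
#' and blends the two nearest samples per axis with linear weights. Constant
#' images are preserved exactly. Implemented as two 1D interpolation-matrix
#' products, so it is exact and deterministic.
#'
#' @param m numeric matrix.
#' @param out_h,out_w output dimensions.
#' @return `out_h` x `out_w` numeric matrix.
#' @export
resize_bilinear <- function(m, out_h, out_w) {
  stopifnot(is.matrix(m), out_h >= 1L, out_w >= 1L)
  Ry <- .interp_matrix(nrow(m), out_h)
  Rx <- .interp_matrix(ncol(m), out_w)
  Ry %*% m %*% t(Rx)
}

# out x in linear interpolation operator with half-pixel centers
.interp_matrix <- function(n_in, n_out) {
  R <- matrix(0, n_out, n_in)
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5  # 0-based coords
  src <- pmin(pmax(src, 0), n_in - 1)
  i0 <- floor(src)
  frac <- src - i0
  i1 <- pmin(i0 + 1, n_in - 1)
  for (i in seq_len(n_out)) {
    R[i, i0[i] + 1L] <- R[i, i0[i] + 1L] + (1 - frac[i])
    R[i, i1[i] + 1L] <- R[i, i1[i] + 1L] + frac[i]
  }
  R
}

#' Preprocess a PET/CT exam into the canonical 2-channel volume
#'
#' PET slices (native 128 x 128) are upsampled and CT slices (native
#' 512 x 512) downsampled to a common `size` x `size` grid with bilinear
#' interpolation, then stacked into a single volume with channel 1 = PET and
#' channel 2 = CT. Intensities pass through unchanged.
#'
#' @param pet numeric array `h x w x l` (PET, any in-plane size).
#' @param ct numeric array `h x w x l` (CT, same slice count as PET).
#' @param size output in-plane edge length (default 224).
#' @return an object of class `scan_volume`: list with `data`, an array of
#'   dim `c(2, size, size, l)`.
#' @export
preprocess_scan <- function(pet, ct, size = 224L) {
  stopifnot(length(dim(pet)) == 3L, length(dim(ct)) == 3L)
  if (dim(pet)[3L] != dim(ct)[3L]) {
    stop(sprintf("slice-count mismatch: PET has %d slices, CT has %d",
                 dim(pet)[3L], dim(ct)[3L]))
  }
  if (!all(is.finite(pet)) || !all(is.finite(ct))) {
    stop("non-finite values in input volumes")
  }
  l <- dim(pet)[3L]
  out <- array(0, dim = c(2L, size, size, l))
  for (s in seq_len(l)) {
    out[1L, , , s] <- resize_bilinear(pet[, , s], size, size)
    out[2L, , , s] <- resize_bilinear(ct[, , s], size, size)
  }
  scan_volume(out)
}

#' Construct a scan volume
#' @param data numeric array of dim `c(2, H, W, l)`; channel 1 PET,
#'   channel 2 CT.
#' @return object of class `scan_volume`.
#' @export
scan_volume <- function(data) {
  stopifnot(length(dim(data)) == 4L, dim(data)[1L] == 2L,
            all(is.finite(data)))
  structure(list(data = data), class = "scan_volume")
}

#' @export
print.scan_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<scan_volume> 2 x %d x %d x %d (PET, CT)\n", d[2], d[3], d[4]))
  invisible(x)
}

#' Random crop / resize / brightness-jitter augmentation
#'
#' The training augmentation: a random axis-aligned crop covering a
#' `crop_frac` share of each in-plane axis (the same crop location for every
#' slice), bilinear resize back to the original in-plane size, then one
#' brightness factor applied to the whole sequence. The jitter magnitude is
#' gamma ~ Uniform(0, `gamma_max`); brightness is multiplied by `1 + gamma`
#' or `1 - gamma` with equal probability (the adjustment direction is
#' randomized per sequence).
#'
#' @param scan a `scan_volume` at its canonical in-plane size.
#' @param crop_frac linear crop fraction; the default 200/224 reproduces a
#'   200 x 200 crop of a 224 x 224 slice.
#' @param gamma_max upper bound of the brightness jitter (default 0.25).
#' @param seed optional integer seed for reproducible draws.
#' @return an augmented `scan_volume` of identical shape.
#' @export
augment <- function(scan, crop_frac = 200 / 224, gamma_max = 0.25,
                    seed = NULL) {
  stopifnot(inherits(scan, "scan_volume"))
  if (!is.null(seed)) set.seed(seed)
  d <- dim(scan$data)
  H <- d[2L]; W <- d[3L]; l <- d[4L]
  ch <- max(1L, round(crop_frac * H))
  cw <- max(1L, round(crop_frac * W))
  oy <- sample.int(H - ch + 1L, 1L)
  ox <- sample.int(W - cw + 1L, 1L)
  gamma <- stats::runif(1L, 0, gamma_max)
  sign <- sample(c(-1, 1), 1L)
  factor <- 1 + sign * gamma

  out <- array(0, dim = d)
  Ry <- .interp_matrix(ch, H)
  Rx <- .interp_matrix(cw, W)
  for (s in seq_len(l)) {
    for (cc in 1:2) {
      crop <- scan$data[cc, oy:(oy + ch - 1L), ox:(ox + cw - 1L), s]
      out[cc, , , s] <- Ry %*% crop %*% t(Rx)
    }
  }
  scan_volume(out * factor)
}
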