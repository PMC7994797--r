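#' Guided-backpropagation saliency for one region
#'
#' Computes the gradient of the region head's prediction with respect to the
#' input scan under the guided-backpropagation rule — negative gradients are
#' zeroed at every rectifier unit during the backward pass — then post-
#' processes it into a normalized saliency volume: absolute value, maximum
#' over the two input channels, subtract the minimum and divide by the
#' maximum (an all-constant gradient yields an all-zero map). In
#' `"3d-clipped"` mode values below the clipping threshold beta are zeroed;
#' `"2d-unclipped"` mode keeps the full map (beta equal to the minimum, i.e.
#' no clipping).
#'
#' @param model a trained `multitask_model`.
#' @param scan a `scan_volume`.
#' @param region region id with a task head in the model.
#' @param mode `"3d-clipped"` or `"2d-unclipped"`.
#' @param beta clipping threshold in \[0, 1\]; defaults to the 95th
#'   percentile of the normalized map in clipped mode.
#' @return object of class `saliency_volume`: list with `values` (array
#'   H x W x l in \[0, 1\]), `beta`, `clipped` (flag), `region_id`.
#' @export
compute_saliency <- function(model, scan, region,
                             mode = c("3d-clipped", "2d-unclipped"),
                             beta = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "multitask_model"), inherits(scan, "scan_volume"))
  if (!region %in% model$regions) stop("unknown region: ", region)
  if (is.null(model$history)) {
    warning("model appears untrained; saliency reflects random weights")
  }
  pooled <- .pool_volume(scan, model$encoder)
  params <- .flatten_model(model)
  fwd <- .scan_forward(params[c("W1", "b1", "W2", "b2")], pooled$V,
                       cache = TRUE)
  A <- fwd$A
  head <- model$heads[[region]]
  s <- as.numeric(A %*% head$w)
  alpha <- .softmax(s)
  a <- as.numeric(crossprod(A, alpha))
  yhat <- .sigmoid(sum(head$u * a) + head$b)

  # backward from the prediction, guided rule at each ReLU
  dlogit <- yhat * (1 - yhat)
  da <- dlogit * head$u
  dalpha <- as.numeric(A %*% da)
  ds <- alpha * (dalpha - sum(alpha * dalpha))
  dA <- outer(alpha, da) + outer(ds, head$w)
  dA <- dA * (A > 0) * (dA > 0)
  dH1 <- dA %*% t(params$W2)
  dH1 <- dH1 * (fwd$H1 > 0) * (dH1 > 0)
  dV <- dH1 %*% t(params$W1)

  # push pooled-voxel gradients back to the input grid (mean pooling spreads
  # gradient uniformly over each block); data channels only
  d <- pooled$in_dim
  grad <- array(0, dim = d)
  for (cc in 1:2) {
    grad[cc, , , ] <- dV[pooled$group, cc] / pooled$counts[pooled$group]
  }
  sal <- pmax(abs(grad[1L, , , , drop = FALSE]),
              abs(grad[2L, , , , drop = FALSE]))
  sal <- array(sal, dim = d[2:4])
  rng <- range(sal)
  sal <- if (rng[2L] > rng[1L]) (sal - rng[1L]) / max(sal - rng[1L]) else
    array(0, dim = dim(sal))
  if (mode == "3d-clipped") {
    if (is.null(beta)) beta <- as.numeric(stats::quantile(sal, 0.95))
    sal[sal < beta] <- 0
    clipped <- TRUE
  } else {
    beta <- min(sal)
    clipped <- FALSE
  }
  structure(list(values = sal, beta = beta, clipped = clipped,
                 region_id = region),
            class = "saliency_volume")
}

#' @export
print.saliency_volume <- function(x, ...) {
  cat(sprintf("<saliency_volume> region %s, %s (beta = %.3f)\n",
              x$region_id, if (x$clipped) "clipped" else "unclipped", x$beta))
  invisible(x)
}

#' Project attention weights onto the scan grid
#'
#' Nearest-neighbor upsampling of the attention distribution from the
#' encoding grid to the scan grid: every scan voxel takes the weight of the
#' encoding voxel whose receptive block contains it, and the overlay is
#' normalized so its maximum is 1. Total overlay mass stays proportional to
#' total attention mass.
#'
#' @param alpha attention weight array over the encoding grid (from
#'   [attend()]); must sum to 1.
#' @param scan_dim integer vector `c(H, W, l)` of the target scan grid.
#' @return numeric array `H x W x l` with values in \[0, 1\].
#' @export
project_attention <- function(alpha, scan_dim) {
  stopifnot(length(dim(alpha)) == 3L, length(scan_dim) == 3L)
  if (abs(sum(alpha) - 1) > 1e-6) stop("attention weights must sum to 1")
  g <- dim(alpha)
  ih <- ceiling(seq_len(scan_dim[1L]) / ceiling(scan_dim[1L] / g[1L]))
  iw <- ceiling(seq_len(scan_dim[2L]) / ceiling(scan_dim[2L] / g[2L]))
  il <- ceiling(seq_len(scan_dim[3L]) / ceiling(scan_dim[3L] / g[3L]))
  ih <- pmin(ih, g[1L]); iw <- pmin(iw, g[2L]); il <- pmin(il, g[3L])
  overlay <- alpha[ih, iw, il, drop = FALSE]
  overlay <- array(overlay, dim = scan_dim)
  overlay / max(overlay)
}

#' Fraction of attention mass inside a region mask
#'
#' Convenience for the localization check: projects alpha to the scan grid
#' and reports the share of (unnormalized) overlay mass falling inside the
#' boolean mask, to be compared against the mask's volume fraction.
#'
#' @param alpha attention array over the encoding grid.
#' @param mask boolean array over the scan grid.
#' @return list with `mass_fraction` and `volume_fraction`.
#' @export
attention_mass_in_mask <- function(alpha, mask) {
  overlay <- project_attention(alpha, dim(mask))
  list(mass_fraction = sum(overlay[mask]) / sum(overlay),
       volume_fraction = mean(mask))
}
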