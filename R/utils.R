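#' @importFrom stats rnorm runif quantile sd var pnorm qnorm optim kmeans aggregate rbinom
#' @importFrom utils head tail read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Label connected components in a binary 2D or 3D mask
#'
#' Breadth-first labeling with full neighborhood connectivity: 8-connectivity
#' for matrices, 26-connectivity for 3D arrays. Used for the largest-object
#' selection steps of lesion and breast segmentation.
#'
#' @param mask logical (or 0/1) matrix or 3D array.
#' @return Integer array of the same shape; 0 = background, components are
#'   numbered 1, 2, ... in discovery order (first-encountered voxel in
#'   column-major order).
#' @keywords internal
label_components <- function(mask) {
  dm <- dim(mask)
  stopifnot(length(dm) %in% c(2L, 3L))
  if (length(dm) == 2L) dm <- c(dm, 1L)
  fg <- which(as.logical(mask))
  labels <- integer(prod(dm))
  if (length(fg) == 0L) {
    out <- array(labels, dim(mask))
    return(out)
  }
  d1 <- dm[1]; d2 <- dm[2]; d3 <- dm[3]
  # precompute neighbor offsets in linear index space, with coordinate deltas
  deltas <- as.matrix(expand.grid(d1 = -1:1, d2 = -1:1, d3 = if (d3 > 1) -1:1 else 0L))
  deltas <- deltas[rowSums(abs(deltas)) > 0, , drop = FALSE]
  is_fg <- logical(prod(dm)); is_fg[fg] <- TRUE
  # coordinates of every voxel are recovered on demand from linear indices
  cur_label <- 0L
  for (seed in fg) {
    if (labels[seed] != 0L) next
    cur_label <- cur_label + 1L
    labels[seed] <- cur_label
    frontier <- seed
    while (length(frontier) > 0L) {
      i0 <- frontier - 1L
      c1 <- i0 %% d1
      c2 <- (i0 %/% d1) %% d2
      c3 <- i0 %/% (d1 * d2)
      nb <- integer(0)
      for (r in seq_len(nrow(deltas))) {
        n1 <- c1 + deltas[r, 1]; n2 <- c2 + deltas[r, 2]; n3 <- c3 + deltas[r, 3]
        ok <- n1 >= 0 & n1 < d1 & n2 >= 0 & n2 < d2 & n3 >= 0 & n3 < d3
        if (any(ok)) nb <- c(nb, (n3[ok] * d2 + n2[ok]) * d1 + n1[ok] + 1L)
      }
      nb <- unique(nb)
      nb <- nb[is_fg[nb] & labels[nb] == 0L]
      labels[nb] <- cur_label
      frontier <- nb
    }
  }
  array(labels, dim(mask))
}

#' Keep the largest connected component of a binary mask
#' @param mask logical matrix or 3D array.
#' @return logical array of same shape; all-FALSE if the input is empty.
#' @keywords internal
largest_component <- function(mask) {
  lab <- label_components(mask)
  if (max(lab) == 0L) return(array(FALSE, dim(mask)))
  counts <- tabulate(lab[lab > 0L])
  keep <- which.max(counts)  # ties: lowest label = first discovered
  array(lab == keep, dim(mask))
}

#' Fill holes slice-wise in a 2D mask or 3D mask stack
#' @keywords internal
fill_holes_2d <- function(mask) {
  if (length(dim(mask)) == 2L) {
    return(EBImage::fillHull(mask * 1L) > 0)
  }
  out <- mask
  for (s in seq_len(dim(mask)[1])) {
    out[s, , ] <- EBImage::fillHull(mask[s, , ] * 1L) > 0
  }
  out
}

# separable Gaussian smoothing along one array dimension via a banded matrix
smooth_along <- function(a, axis, sigma) {
  if (sigma <= 0) return(a)
  dm <- dim(a)
  n <- dm[axis]
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- k / sum(k)
  # dense n x n smoothing matrix with renormalized truncated rows
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - half):(i + half)
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- k[ok] / sum(k[ok])
  }
  perm <- c(axis, setdiff(seq_along(dm), axis))
  ap <- aperm(a, perm)
  m <- matrix(ap, n, prod(dm[-axis]))
  m <- K %*% m
  ap <- array(m, dm[perm])
  aperm(ap, order(perm))
}

#' Separable 3D Gaussian smoothing
#' @param a numeric 3D array.
#' @param sigma scalar or length-3 vector of standard deviations in voxels.
#' @keywords internal
gaussian_smooth3 <- function(a, sigma) {
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  for (ax in 1:3) a <- smooth_along(a, ax, sigma[ax])
  a
}

#' Dice overlap coefficient between two binary masks
#'
#' @param a,b logical (or 0/1) arrays of identical shape.
#' @return Dice coefficient in \[0, 1\]; 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

# derive a bounded child seed from a parent seed (keeps inside 32-bit range)
derive_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + i * 104729) %% 2147483647
}
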