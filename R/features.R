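#' Partition an image into full blocks
#'
#' Splits an `M x N` image into raster-ordered `F x G` tiles. Only full-size
#' blocks are kept: the block count is `Z = floor(M/F) * floor(N/G)` and any
#' partial edge remainder is discarded, so every per-block formula sees
#' exactly `F * G` pixels.
#'
#' @param image Grayscale matrix.
#' @param block `c(F, G)` block dimensions in pixels (default 16 x 16).
#' @return List of `F x G` matrices in raster (row-major) order.
#' @export
partition_blocks <- function(image, block = c(16, 16)) {
  assert_gray(image)
  f <- as.integer(block[1]); g <- as.integer(block[2])
  if (nrow(image) < f || ncol(image) < g) {
    stop(sprintf("image (%d x %d) smaller than one %d x %d block",
                 nrow(image), ncol(image), f, g), call. = FALSE)
  }
  nbr <- nrow(image) %/% f
  nbc <- ncol(image) %/% g
  out <- vector("list", nbr * nbc)
  k <- 0L
  for (br in seq_len(nbr)) {
    rs <- ((br - 1L) * f + 1L):(br * f)
    for (bc in seq_len(nbc)) {
      cs <- ((bc - 1L) * g + 1L):(bc * g)
      k <- k + 1L
      out[[k]] <- image[rs, cs, drop = FALSE]
    }
  }
  out
}

#' Shannon entropy of a block
#'
#' `-sum(p_i * log2(p_i))` over the grey-level histogram of the block, with
#' empty levels contributing zero. Measured in bits; bounded by
#' `log2(n_levels)` (8 bits for 256 levels).
#'
#' @param block Matrix (or vector) of grey levels in `[0, n_levels - 1]`.
#' @param n_levels Number of grey levels (default 256).
#' @return Entropy in bits.
#' @export
block_entropy <- function(block, n_levels = 256) {
  v <- as.vector(block)
  stopifnot(length(v) > 0)
  counts <- tabulate(v + 1L, nbins = n_levels)
  p <- counts[counts > 0] / length(v)
  -sum(p * log2(p))
}

#' Per-block statistics
#'
#' Computes the eight block statistics used by the pipeline: entropy (bits),
#' mean, population variance (divisor `F * G`), standard deviation, range
#' (max - min), minimum, maximum, and root mean square. The default RMS is
#' `sqrt(mean(p^2))` over the block pixels; `rms_mode = "row_col"` instead
#' averages the squared row and column means (a directional variant that is
#' not rotation-invariant).
#'
#' @param block `F x G` matrix of grey levels.
#' @param rms_mode `"pixel"` (default) or `"row_col"`.
#' @return One-row tibble in canonical column order
#'   (entropy, mean, variance, sd, range, minimum, maximum, rms).
#' @export
block_stats <- function(block, rms_mode = c("pixel", "row_col")) {
  rms_mode <- match.arg(rms_mode)
  v <- as.numeric(block)
  mu <- mean(v)
  va <- mean((v - mu)^2)
  mn <- min(v); mx <- max(v)
  rms <- if (rms_mode == "pixel") {
    sqrt(mean(v^2))
  } else {
    rm2 <- rowMeans(block)^2
    cm2 <- colMeans(block)^2
    sqrt(mean(c(rm2, cm2)))
  }
  tibble::tibble(
    entropy = block_entropy(block),
    mean = mu, variance = va, sd = sqrt(va),
    range = mx - mn, minimum = mn, maximum = mx, rms = rms)
}

#' Extract the 8-component feature vector of an image
#'
#' Partitions the image into `F x G` blocks ([partition_blocks()]), computes
#' the per-block statistics ([block_stats()]), and averages each statistic
#' over the `Z` blocks. The result is the per-image feature vector in
#' canonical order: entropy, mean, variance, sd, range, minimum, maximum, rms.
#'
#' By construction `range = maximum - minimum` holds exactly at the image
#' level (the block mean is linear), `sd <= sqrt(variance)` (Jensen), and
#' the entropy feature lies in `[0, 8]` bits.
#'
#' @param image Grayscale matrix, at least one block in size.
#' @param block `c(F, G)` block dimensions (default `c(16, 16)`).
#' @param rms_mode Passed to [block_stats()].
#' @return One-row tibble with the 8 canonical feature columns.
#' @export
extract_features <- function(image, block = c(16, 16),
                             rms_mode = c("pixel", "row_col")) {
  rms_mode <- match.arg(rms_mode)
  assert_gray(image)
  f <- as.integer(block[1]); g <- as.integer(block[2])
  if (nrow(image) < f || ncol(image) < g) {
    stop(sprintf("image (%d x %d) smaller than one %d x %d block",
                 nrow(image), ncol(image), f, g), call. = FALSE)
  }
  nbr <- nrow(image) %/% f
  nbc <- ncol(image) %/% g
  crop <- image[seq_len(nbr * f), seq_len(nbc * g), drop = FALSE]
  # reshape to an (F*G) x Z matrix, one column per raster-ordered block
  a <- array(as.numeric(crop), dim = c(f, nbr, g, nbc))
  bm <- matrix(aperm(a, c(1, 3, 4, 2)), nrow = f * g)   # blocks in col-major
  # raster (row-major) block order to match partition_blocks()
  ord <- as.vector(t(matrix(seq_len(nbr * nbc), nrow = nbc)))
  bm <- bm[, ord, drop = FALSE]

  mu <- colMeans(bm)
  va <- colMeans(bm^2) - mu^2
  va[va < 0] <- 0
  mn <- apply(bm, 2, min)
  mx <- apply(bm, 2, max)
  ent <- apply(bm, 2, function(v) {
    counts <- tabulate(v + 1L, nbins = 256L)
    p <- counts[counts > 0] / length(v)
    -sum(p * log2(p))
  })
  rms <- if (rms_mode == "pixel") {
    sqrt(colMeans(bm^2))
  } else {
    vapply(seq_len(ncol(bm)), function(z) {
      b <- matrix(bm[, z], nrow = f)
      sqrt(mean(c(rowMeans(b)^2, colMeans(b)^2)))
    }, numeric(1))
  }
  tibble::tibble(
    entropy = mean(ent), mean = mean(mu), variance = mean(va),
    sd = mean(sqrt(va)), range = mean(mx - mn),
    minimum = mean(mn), maximum = mean(mx), rms = mean(rms))
}
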