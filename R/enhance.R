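#' Contrast-limited adaptive histogram equalization
#'
#' Implements the classic five-step CLAHE procedure: divide the image into
#' contextual regions (tiles), build each region's 256-bin histogram, clip it
#' at `clip` times the region pixel count, redistribute the clipped excess
#' uniformly (iterated until the residual is below one count, so histogram
#' mass is conserved exactly), map intensities through the cumulative
#' histogram, and bilinearly interpolate each pixel between the mappings of
#' the four neighbouring tile centres (clamped at the borders, which removes
#' tile seams).
#'
#' With `tiles = c(1, 1)` and `clip = 1` the procedure reduces exactly to
#' plain global histogram equalization with the CDF mapping
#' `m(v) = round(255 * cdf(v) / n)`.
#'
#' @param image Grayscale matrix in `[0, 255]`.
#' @param tiles `c(rows, cols)` grid of contextual regions (default 8 x 8).
#' @param clip Clip limit as a fraction of the region pixel count, in
#'   `(0, 1]` (default 0.01).
#' @return Enhanced image, same shape, integer grey levels in `[0, 255]`.
#' @export
clahe <- function(image, tiles = c(8, 8), clip = 0.01) {
  assert_gray(image)
  tr <- as.integer(tiles[1]); tc <- as.integer(tiles[2])
  if (tr < 1 || tc < 1) stop("tiles must be >= 1 in both dimensions", call. = FALSE)
  if (!(clip > 0 && clip <= 1)) stop("clip must be in (0, 1]", call. = FALSE)
  h <- nrow(image); w <- ncol(image)
  if (h < tr || w < tc) {
    stop(sprintf("tile grid %d x %d exceeds image %d x %d", tr, tc, h, w),
         call. = FALSE)
  }

  # tile row/col boundaries (near-equal partition)
  rb <- floor(seq(0, h, length.out = tr + 1))
  cb <- floor(seq(0, w, length.out = tc + 1))

  # per-tile clipped-CDF mappings: maps[i, j, ] is the 256-entry lookup
  maps <- array(0, dim = c(tr, tc, 256))
  ctr_r <- numeric(tr); ctr_c <- numeric(tc)
  for (i in seq_len(tr)) {
    rs <- (rb[i] + 1):rb[i + 1]
    ctr_r[i] <- mean(range(rs))
    for (j in seq_len(tc)) {
      cs <- (cb[j] + 1):cb[j + 1]
      if (i == 1) ctr_c[j] <- mean(range(cs))
      tile <- image[rs, cs]
      hist <- tabulate(as.integer(tile) + 1L, nbins = 256L)
      hist <- clip_histogram(hist, clip * length(tile))
      cdf <- cumsum(hist)
      maps[i, j, ] <- round(255 * cdf / length(tile))
    }
  }

  if (tr == 1 && tc == 1) {
    out <- matrix(maps[1, 1, as.integer(image) + 1L], h, w)
    storage.mode(out) <- "integer"
    return(out)
  }

  # bilinear interpolation between the 4 neighbouring tile mappings
  ri <- findInterval(seq_len(h), ctr_r)          # lower tile row index (0..tr)
  ri0 <- pmax(ri, 1L); ri1 <- pmin(ri + 1L, tr)
  wr <- ifelse(ri0 == ri1, 0,
               (seq_len(h) - ctr_r[ri0]) / (ctr_r[ri1] - ctr_r[ri0]))
  wr[ri == 0] <- 0                                # above first centre: clamp
  ci <- findInterval(seq_len(w), ctr_c)
  ci0 <- pmax(ci, 1L); ci1 <- pmin(ci + 1L, tc)
  wc <- ifelse(ci0 == ci1, 0,
               (seq_len(w) - ctr_c[ci0]) / (ctr_c[ci1] - ctr_c[ci0]))
  wc[ci == 0] <- 0

  lvl <- as.integer(image) + 1L                   # 1..256 lookup index
  out <- matrix(0, h, w)
  # accumulate the four corner contributions with vectorized lookups
  idx <- function(rid, cid) {
    # linear index into maps[rid, cid, lvl] for every pixel
    rmat <- matrix(rid, h, w)
    cmat <- matrix(cid, h, w, byrow = TRUE)
    rmat + (cmat - 1L) * tr + (matrix(lvl, h, w) - 1L) * (tr * tc)
  }
  wrm <- matrix(wr, h, w); wcm <- matrix(wc, h, w, byrow = TRUE)
  out <- (1 - wrm) * (1 - wcm) * maps[idx(ri0, ci0)] +
         (1 - wrm) * wcm       * maps[idx(ri0, ci1)] +
         wrm       * (1 - wcm) * maps[idx(ri1, ci0)] +
         wrm       * wcm       * maps[idx(ri1, ci1)]
  out <- clip_gray(out)
  storage.mode(out) <- "integer"
  out
}

# Clip a histogram at `limit` counts per bin and redistribute the excess
# uniformly over all bins, iterating until the residual is under one count.
# Total mass is conserved exactly (the final sub-one residual is assigned to
# the lowest unclipped bins, one count each).
clip_histogram <- function(hist, limit) {
  n <- sum(hist)
  limit <- max(limit, 1)
  for (iter in 1:64) {
    excess <- sum(pmax(hist - limit, 0))
    if (excess < 1) break
    hist <- pmin(hist, limit)
    hist <- hist + excess / length(hist)
  }
  # settle the sub-one residual in integer counts
  hist <- floor(hist)
  deficit <- n - sum(hist)
  if (deficit > 0) {
    ord <- order(hist)[seq_len(deficit)]
    hist[ord] <- hist[ord] + 1
  }
  hist
}
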