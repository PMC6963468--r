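#' Normalize MLO orientation
#'
#' Ensures the breast tissue lies on the left half of the frame, mirroring
#' right-sided views so one segmentation procedure serves both lateralities.
#' The decision compares foreground pixel counts (intensity at or above
#' `threshold`) between the left and right image halves; ties keep the image
#' as is. Applying the operation twice is idempotent.
#'
#' @param image Grayscale matrix with at least one foreground pixel.
#' @param threshold Foreground threshold (default 18).
#' @return List with `image` (left-oriented) and `flipped` (logical).
#' @export
orient <- function(image, threshold = 18) {
  assert_gray(image)
  fg <- image >= threshold
  if (!any(fg)) stop("empty image: no pixel at or above the threshold", call. = FALSE)
  half <- ncol(image) %/% 2
  left <- sum(fg[, seq_len(half)])
  right <- sum(fg[, (ncol(image) - half + 1):ncol(image)])
  flipped <- right > left
  if (flipped) image <- image[, rev(seq_len(ncol(image))), drop = FALSE]
  list(image = image, flipped = flipped)
}

#' Suppress radiopaque artifacts
#'
#' Binarizes the image at a global `threshold`, applies a morphological
#' opening (disk radius `max(1, round(min(H, W) / 200))`), keeps the largest
#' 8-connected component as the breast mask, and zeroes every pixel outside
#' it — removing labels and any other bright objects disconnected from the
#' breast. No pixel value is ever increased.
#'
#' @param image Grayscale matrix with at least one foreground pixel.
#' @param threshold Global binarization threshold (default 18).
#' @return List with `image` (masked), `mask` (logical breast mask) and
#'   `threshold`.
#' @export
suppress_artifacts <- function(image, threshold = 18) {
  assert_gray(image)
  fg <- image >= threshold
  if (!any(fg)) stop("empty image: no pixel at or above the threshold", call. = FALSE)
  r <- max(1L, round(min(dim(image)) / 200))
  kern <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  opened <- EBImage::opening(fg * 1, kern) > 0.5
  if (!any(opened)) opened <- fg  # degenerate: structure smaller than the disk
  mask <- largest_component(opened, connectivity = 8)
  out <- image
  out[!mask] <- 0L
  storage.mode(out) <- "integer"
  list(image = out, mask = mask, threshold = threshold)
}

#' Seeded region growing
#'
#' Grows an 8-connected region outward from the seed pixels: the frontier is
#' processed in FIFO order with row-major neighbour enumeration, and a
#' candidate pixel is accepted when its intensity differs from the running
#' regional mean by at most `tolerance`. Growth is restricted to foreground
#' pixels (at or above `threshold`), so the region is always a subset of the
#' thresholded foreground and contains every seed. The fixed frontier
#' ordering makes the result deterministic.
#'
#' @param image Grayscale matrix.
#' @param seeds Integer matrix or data frame with columns `row`, `col`
#'   (1-based), or a list of `c(row, col)` pairs.
#' @param tolerance Maximum absolute deviation from the running region mean.
#' @param threshold Foreground threshold bounding the growth (default 18).
#' @return Logical region mask.
#' @export
srg <- function(image, seeds, tolerance, threshold = 18) {
  assert_gray(image)
  seeds <- as_seed_matrix(seeds)
  h <- nrow(image); w <- ncol(image)
  if (any(seeds[, 1] < 1 | seeds[, 1] > h | seeds[, 2] < 1 | seeds[, 2] > w)) {
    stop("seed outside image bounds", call. = FALSE)
  }
  fg <- image >= threshold
  region <- matrix(FALSE, h, w)
  queued <- matrix(FALSE, h, w)

  # FIFO queue of linear indices
  qcap <- 1024L
  queue <- integer(qcap)
  qhead <- 1L; qtail <- 0L
  push <- function(idx) {
    if (qtail + 1L > qcap) {
      qcap <<- qcap * 2L
      queue <<- c(queue, integer(qcap %/% 2L))
    }
    qtail <<- qtail + 1L
    queue[qtail] <<- idx
  }
  seed_idx <- (seeds[, 2] - 1L) * h + seeds[, 1]
  for (s in seed_idx) if (!queued[s]) { queued[s] <- TRUE; push(s) }

  # seeds are always members; the running mean starts from them
  rsum <- 0; rcount <- 0L
  # row-major neighbour enumeration: (-1,-1) (-1,0) (-1,+1) (0,-1) (0,+1) ...
  ndr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  ndc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  while (qhead <= qtail) {
    idx <- queue[qhead]; qhead <- qhead + 1L
    r0 <- ((idx - 1L) %% h) + 1L
    c0 <- ((idx - 1L) %/% h) + 1L
    is_seed <- idx %in% seed_idx
    val <- as.numeric(image[idx])
    if (!is_seed) {
      if (!fg[idx]) next
      if (rcount > 0 && abs(val - rsum / rcount) > tolerance) next
    }
    region[idx] <- TRUE
    rsum <- rsum + val; rcount <- rcount + 1L
    rn <- r0 + ndr; cn <- c0 + ndc
    ok <- rn >= 1L & rn <= h & cn >= 1L & cn <= w
    nidx <- (cn[ok] - 1L) * h + rn[ok]
    for (ni in nidx) if (!queued[ni]) { queued[ni] <- TRUE; push(ni) }
  }
  region
}

as_seed_matrix <- function(seeds) {
  if (is.data.frame(seeds)) seeds <- cbind(seeds$row, seeds$col)
  if (is.list(seeds) && !is.matrix(seeds)) seeds <- do.call(rbind, seeds)
  if (is.vector(seeds) && length(seeds) == 2) seeds <- matrix(seeds, 1)
  seeds <- matrix(as.integer(seeds), ncol = 2)
  if (nrow(seeds) < 1) stop("seed set is empty", call. = FALSE)
  seeds
}

#' Remove the pectoral muscle
#'
#' On a left-oriented, artifact-suppressed image, places a seed at the first
#' breast pixel scanned row-by-row inside the top-left quarter window
#' (25% x 25% of the frame), grows the pectoral region with [srg()], and
#' blacks it out. The pectoral muscle of an MLO view is the dense triangle
#' touching the top corner, so the grown region always touches the top rows.
#' If the region exceeds half the breast area the growth has escaped into
#' parenchyma: a segmentation-failure warning is raised and the region is
#' still returned for inspection, but the image is left unmasked.
#'
#' @param image Left-oriented grayscale matrix (after [suppress_artifacts()]).
#' @param mask Logical breast mask from [suppress_artifacts()].
#' @param tolerance SRG homogeneity tolerance (default 32, about twice the
#'   phantom parenchyma sd).
#' @param threshold Foreground threshold passed to [srg()].
#' @return List with `image` (pectoral blacked out unless `failed`),
#'   `pectoral_mask`, `seed` (`c(row, col)`), and `failed` (logical).
#' @export
remove_pectoral <- function(image, mask, tolerance = 32, threshold = 18) {
  assert_gray(image)
  stopifnot(identical(dim(mask), dim(image)))
  h <- nrow(image); w <- ncol(image)
  rmax <- max(1L, floor(h * 0.25)); cmax <- max(1L, floor(w * 0.25))
  win <- mask[seq_len(rmax), seq_len(cmax), drop = FALSE]
  if (!any(win)) {
    stop("no breast pixel in the top-left quarter window; is the image oriented?",
         call. = FALSE)
  }
  # topmost, then leftmost breast pixel in the window
  hits <- which(win, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  seed <- hits[1, ]
  pect <- srg(image, matrix(seed, 1), tolerance = tolerance, threshold = threshold)
  failed <- sum(pect) > 0.5 * sum(mask)
  out <- image
  if (failed) {
    # degenerate seed (e.g. no pectoral present): the growth is parenchyma,
    # not muscle -- report the region but do not black out half the breast
    warning("pectoral region exceeds 50% of the breast area; segmentation failed, image left unmasked",
            call. = FALSE)
  } else {
    out[pect] <- 0L
  }
  storage.mode(out) <- "integer"
  list(image = out, pectoral_mask = pect,
       seed = c(row = seed[[1]], col = seed[[2]]), failed = failed)
}

#' Full segmentation pipeline
#'
#' Fixed order: orient (breast to the left), suppress artifacts at the global
#' threshold, then remove the pectoral muscle by seeded region growing.
#' Optionally applies [clahe()] before segmentation.
#'
#' @param image Grayscale matrix.
#' @param threshold Global foreground threshold (default 18).
#' @param tolerance SRG tolerance (default 32).
#' @param enhance Apply CLAHE first (default FALSE).
#' @param tiles,clip CLAHE parameters when `enhance = TRUE`.
#' @return List with the final `image`, `breast_mask`, `pectoral_mask`,
#'   `flipped`, and `seed`.
#' @export
segment_breast <- function(image, threshold = 18, tolerance = 32,
                           enhance = FALSE, tiles = c(8, 8), clip = 0.01) {
  if (enhance) image <- clahe(image, tiles = tiles, clip = clip)
  o <- orient(image, threshold)
  s <- suppress_artifacts(o$image, threshold)
  p <- remove_pectoral(s$image, s$mask, tolerance = tolerance, threshold = threshold)
  list(image = p$image, breast_mask = s$mask, pectoral_mask = p$pectoral_mask,
       flipped = o$flipped, seed = p$seed)
}
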