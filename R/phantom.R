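#' Specify a synthetic MLO mammogram phantom
#'
#' Builds the parameter set for [generate_phantom()]. The phantom emulates a
#' mediolateral-oblique (MLO) view: a half-elliptical breast silhouette
#' attached to one lateral edge, filled with Gaussian parenchyma texture; a
#' filled pectoral triangle at the top corner of that side, with density close
#' to the dense-tissue intensity; optional disconnected radiopaque label
#' rectangles near the opposite edge; and an optional circular mass lesion
#' that raises local intensity and texture. Ground-truth masks for every
#' structure are returned alongside the image so segmentation and feature
#' extraction can be validated without clinical data.
#'
#' Intensity defaults: parenchyma `N(100, 16)`, pectoral `N(155, 4)` (within
#' 15 grey levels of the dense-tissue intensity `breast_mean + 3 * breast_sd`),
#' background `N(8, 2)` clipped below the global artifact threshold 18, labels
#' at grey level 200+. The default lesion shifts intensity by `3 * breast_sd`
#' and texture sd by +10, a conspicuous but not saturating mass.
#'
#' @param size `c(rows, cols)`; both at least 32.
#' @param side Which lateral edge the breast touches: `"left"` or `"right"`.
#' @param breast_mean,breast_sd Parenchyma intensity mean and sd.
#' @param pectoral_mean,pectoral_sd Pectoral-triangle intensity mean and sd.
#' @param pectoral_frac Fraction of the top edge covered by the pectoral
#'   triangle (0 disables it).
#' @param n_labels Number of disconnected bright label artifacts.
#' @param lesion `NULL` for a normal phantom, or a list with elements
#'   `center` (fractional `c(row, col)` in the un-mirrored frame), `radius`
#'   (fraction of `rows`), `intensity_shift`, `sd_shift`.
#' @param background_level,background_sd Background intensity mean and sd;
#'   background pixels are clipped below 18.
#' @param seed Integer RNG seed; the phantom is deterministic given the spec.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(size = c(256, 256),
                         side = c("left", "right"),
                         breast_mean = 100, breast_sd = 16,
                         pectoral_mean = 155, pectoral_sd = 4,
                         pectoral_frac = 0.3,
                         n_labels = 1,
                         lesion = NULL,
                         background_level = 8, background_sd = 2,
                         seed = 1L) {
  side <- match.arg(side)
  stopifnot(length(size) == 2, all(size >= 32))
  if (!(background_level < 18 && 18 <= breast_mean)) {
    stop("need background_level < 18 <= breast_mean", call. = FALSE)
  }
  dense <- breast_mean + 3 * breast_sd
  if (abs(pectoral_mean - dense) > 15) {
    stop(sprintf(
      "pectoral_mean (%g) must lie within 15 grey levels of the dense-tissue intensity (%g)",
      pectoral_mean, dense), call. = FALSE)
  }
  if (pectoral_frac < 0 || pectoral_frac > 0.45) {
    stop("pectoral_frac must be in [0, 0.45]", call. = FALSE)
  }
  if (!is.null(lesion)) {
    lesion <- utils::modifyList(
      list(center = c(0.52, 0.32), radius = 0.15,
           intensity_shift = 3 * breast_sd, sd_shift = 10),
      lesion)
  }
  structure(
    list(size = as.integer(size), side = side,
         breast_mean = breast_mean, breast_sd = breast_sd,
         pectoral_mean = pectoral_mean, pectoral_sd = pectoral_sd,
         pectoral_frac = pectoral_frac, n_labels = as.integer(n_labels),
         lesion = lesion,
         background_level = background_level, background_sd = background_sd,
         seed = as.integer(seed)),
    class = "phantom_spec")
}

# Breast silhouette: all pixels between the chest-wall edge and a half
# ellipse bulging into the field; touches the top corner on `side` so the
# pectoral triangle can sit inside it.
breast_silhouette <- function(h, w) {
  r <- matrix(seq_len(h), h, w)
  c0 <- matrix(seq_len(w) - 1L, h, w, byrow = TRUE)
  cy <- 0.45 * h; ry <- 0.55 * h; rx <- 0.62 * w
  half_width <- rx * sqrt(pmax(0, 1 - ((r - cy) / ry)^2))
  c0 < half_width
}

#' Generate a synthetic MLO phantom
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom` list: `image` (integer matrix), logical masks
#'   `breast_mask`, `pectoral_mask`, `label_mask`, `lesion_mask`, and
#'   `class_label` (1 iff a lesion is present).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$size[1]; w <- spec$size[2]

  breast <- breast_silhouette(h, w)
  rr <- matrix(seq_len(h) - 1L, h, w)
  cc <- matrix(seq_len(w) - 1L, h, w, byrow = TRUE)

  pect <- matrix(FALSE, h, w)
  if (spec$pectoral_frac > 0) {
    wt <- spec$pectoral_frac * w
    ht <- 1.8 * wt
    pect <- (cc / wt + rr / ht < 1) & breast
  }

  lesion_mask <- matrix(FALSE, h, w)
  if (!is.null(spec$lesion)) {
    ctr <- spec$lesion$center * c(h, w)
    rad <- spec$lesion$radius * h
    lesion_mask <- ((rr + 1 - ctr[1])^2 + (cc + 1 - ctr[2])^2) <= rad^2
    if (any(lesion_mask & !(breast & !pect))) {
      stop("lesion extends outside the breast parenchyma", call. = FALSE)
    }
    if (!any(lesion_mask)) stop("lesion radius too small to cover a pixel", call. = FALSE)
  }

  img <- matrix(0, h, w)
  label_mask <- matrix(FALSE, h, w)
  withr::with_seed(spec$seed, {
    bg <- rnorm(h * w, spec$background_level, spec$background_sd)
    img[] <- pmin(pmax(bg, 0), 17)  # background stays below the threshold 18
    img[breast] <- rnorm(sum(breast), spec$breast_mean, spec$breast_sd)
    if (any(pect)) {
      img[pect] <- rnorm(sum(pect), spec$pectoral_mean, spec$pectoral_sd)
    }
    if (any(lesion_mask)) {
      img[lesion_mask] <- rnorm(sum(lesion_mask),
                                spec$breast_mean + spec$lesion$intensity_shift,
                                spec$breast_sd + spec$lesion$sd_shift)
    }
    if (spec$n_labels > 0) {
      # bright rectangles in the far non-breast strip, disconnected from the
      # breast (silhouette never exceeds 0.62 * w columns)
      lh <- max(4L, round(0.05 * h)); lw <- max(4L, round(0.06 * w))
      for (i in seq_len(spec$n_labels)) {
        r0 <- sample.int(h - lh - 2L, 1L) + 1L
        c0 <- sample.int(max(1L, round(0.10 * w) - lw), 1L) + round(0.86 * w)
        c1 <- min(w, c0 + lw - 1L)
        label_mask[r0:(r0 + lh - 1L), c0:c1] <- TRUE
      }
      img[label_mask] <- pmax(200, rnorm(sum(label_mask), 235, 5))
    }
  })
  img <- clip_gray(img)

  if (spec$side == "right") {
    flip <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
    img <- flip(img); breast <- flip(breast); pect <- flip(pect)
    label_mask <- flip(label_mask); lesion_mask <- flip(lesion_mask)
  }
  storage.mode(img) <- "integer"

  structure(
    list(image = img, breast_mask = breast, pectoral_mask = pect,
         label_mask = label_mask, lesion_mask = lesion_mask,
         class_label = as.integer(!is.null(spec$lesion)),
         spec = spec),
    class = "phantom")
}

#' Generate a labeled phantom cohort
#'
#' Emits `n_normal` lesion-free phantoms followed by `n_abnormal` phantoms
#' carrying a lesion. Per-phantom acquisition parameters are jittered around
#' `base_spec` (breast mean +/-4, breast sd +/-1, pectoral mean +/-3,
#' pectoral fraction +/-0.04, lesion centre +/-0.03 fractional) to emulate
#' patient-to-patient variation; everything is reproducible under `seed`.
#'
#' @param n_normal,n_abnormal Non-negative phantom counts per class.
#' @param base_spec A [phantom_spec()] giving the cohort centre; its `lesion`
#'   slot (or the [phantom_spec()] default lesion) is applied to the abnormal
#'   class only.
#' @param seed Integer seed for the jitter and the per-phantom textures.
#' @return List of `phantom` objects, normals first.
#' @export
generate_cohort <- function(n_normal, n_abnormal,
                            base_spec = phantom_spec(), seed = 1L) {
  stopifnot(n_normal >= 0, n_abnormal >= 0)
  n <- n_normal + n_abnormal
  if (n == 0) return(list())
  base_lesion <- base_spec$lesion %||%
    phantom_spec(size = base_spec$size, lesion = list())$lesion
  # pectoral jitter rides on the jittered dense-tissue intensity so the
  # density-similarity invariant holds for every cohort member
  pect_offset <- base_spec$pectoral_mean -
    (base_spec$breast_mean + 3 * base_spec$breast_sd)
  jit <- withr::with_seed(seed, {
    breast_mean <- base_spec$breast_mean + runif(n, -4, 4)
    breast_sd <- base_spec$breast_sd + runif(n, -1, 1)
    tibble::tibble(
      breast_mean = breast_mean,
      breast_sd = breast_sd,
      pectoral_mean = breast_mean + 3 * breast_sd + pect_offset + runif(n, -3, 3),
      pectoral_frac = pmax(0.05, base_spec$pectoral_frac + runif(n, -0.04, 0.04)),
      dctr_r = runif(n, -0.03, 0.03),
      dctr_c = runif(n, -0.03, 0.03)
    )
  })
  purrr::map(seq_len(n), function(i) {
    abnormal <- i > n_normal
    lesion <- NULL
    if (abnormal) {
      lesion <- base_lesion
      lesion$center <- lesion$center + c(jit$dctr_r[i], jit$dctr_c[i])
      lesion$intensity_shift <- 3 * jit$breast_sd[i]
    }
    sp <- phantom_spec(
      size = base_spec$size, side = base_spec$side,
      breast_mean = jit$breast_mean[i], breast_sd = jit$breast_sd[i],
      pectoral_mean = jit$pectoral_mean[i], pectoral_sd = base_spec$pectoral_sd,
      pectoral_frac = jit$pectoral_frac[i], n_labels = base_spec$n_labels,
      lesion = lesion,
      background_level = base_spec$background_level,
      background_sd = base_spec$background_sd,
      seed = derive_seed(seed, i))
    generate_phantom(sp)
  })
}

#' Extract the feature table of a phantom cohort
#'
#' Convenience wrapper: runs [extract_features()] on every phantom image and
#' binds the rows with an `id` column and the ground-truth `label`.
#'
#' @param cohort List of `phantom` objects from [generate_cohort()].
#' @param ... Passed to [extract_features()].
#' @return Tibble with `id`, the 8 canonical features, and `label`.
#' @export
cohort_features <- function(cohort, ...) {
  purrr::map_dfr(seq_along(cohort), function(i) {
    dplyr::bind_cols(
      tibble::tibble(id = i),
      extract_features(cohort[[i]]$image, ...),
      tibble::tibble(label = cohort[[i]]$class_label))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d x %d, side %s, class %s\n",
              nrow(x$image), ncol(x$image), x$spec$side,
              if (x$class_label == 1) "abnormal" else "normal"))
  invisible(x)
}
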