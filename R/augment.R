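#' Define an augmentation plan
#'
#' A plan is a set of quarter-turn rotations, optionally followed by a
#' horizontal (left-right) mirror of every rotated copy. The augmentation
#' factor is `|rotations| * (2 if flip else 1)`: the full
#' rotate-then-flip plan turns one image into eight.
#'
#' @param rotations Subset of `c(0, 90, 180, 270)` degrees.
#' @param flip Also emit the horizontally mirrored copy of each rotation.
#' @return An `augment_plan` object.
#' @export
augment_plan <- function(rotations = c(0, 90, 180, 270), flip = FALSE) {
  rotations <- sort(unique(as.integer(rotations)))
  if (!all(rotations %in% c(0L, 90L, 180L, 270L))) {
    stop("rotations must be multiples of 90 degrees in {0, 90, 180, 270}",
         call. = FALSE)
  }
  if (length(rotations) == 0) stop("plan needs at least one rotation", call. = FALSE)
  structure(list(rotations = rotations, flip = isTRUE(flip),
                 factor = length(rotations) * (1L + isTRUE(flip))),
            class = "augment_plan")
}

#' Rotate an image by a multiple of 90 degrees
#'
#' Exact (lossless) index permutation, counter-clockwise. Non-square images
#' swap dimensions under 90/270.
#'
#' @param image Matrix.
#' @param degrees One of 0, 90, 180, 270.
#' @return Rotated matrix.
#' @export
rotate90 <- function(image, degrees) {
  degrees <- as.integer(degrees) %% 360L
  switch(as.character(degrees),
    "0" = image,
    "90" = t(image)[rev(seq_len(ncol(image))), , drop = FALSE],
    "180" = image[rev(seq_len(nrow(image))), rev(seq_len(ncol(image))), drop = FALSE],
    "270" = t(image)[, rev(seq_len(nrow(image))), drop = FALSE],
    stop("degrees must be a multiple of 90", call. = FALSE))
}

#' Mirror an image horizontally
#'
#' Reverses the column order (left-right flip).
#'
#' @param image Matrix.
#' @return Flipped matrix.
#' @export
flip_horizontal <- function(image) {
  image[, rev(seq_len(ncol(image))), drop = FALSE]
}

#' Augment one image under a plan
#'
#' Emits the rotated copies in increasing angle order; with `flip = TRUE`
#' each rotation is followed by its horizontal mirror.
#'
#' @param image Grayscale matrix.
#' @param plan An [augment_plan()].
#' @return List of matrices of length `plan$factor`.
#' @export
augment_image <- function(image, plan) {
  stopifnot(inherits(plan, "augment_plan"))
  out <- list()
  for (deg in plan$rotations) {
    r <- rotate90(image, deg)
    out <- c(out, list(r))
    if (plan$flip) out <- c(out, list(flip_horizontal(r)))
  }
  out
}

#' Augment a labeled image cohort
#'
#' Applies a per-class augmentation plan to every image and preserves labels,
#' so each class count is multiplied by its plan factor.
#'
#' @param images List of grayscale matrices.
#' @param labels Vector of labels (0 = normal, 1 = abnormal), one per image.
#' @param plans Named list of [augment_plan()]s keyed by label (e.g.
#'   `list("0" = augment_plan(), "1" = augment_plan(flip = TRUE))`).
#' @return List with `images` (augmented list) and `labels`; per-class output
#'   counts equal input counts times the class factor, in input order.
#' @export
augment_cohort <- function(images, labels, plans) {
  stopifnot(length(images) == length(labels))
  labs <- as.character(labels)
  if (!all(labs %in% names(plans))) {
    stop("every class label needs a plan", call. = FALSE)
  }
  out_images <- list(); out_labels <- c()
  for (i in seq_along(images)) {
    aug <- augment_image(images[[i]], plans[[labs[i]]])
    out_images <- c(out_images, aug)
    out_labels <- c(out_labels, rep(labels[i], length(aug)))
  }
  list(images = out_images, labels = out_labels)
}

#' Augmented sample counts per class
#'
#' The counting arithmetic of plan-based augmentation: each class count is
#' multiplied by its plan factor (4 for the four rotations, 8 for rotations
#' plus flips).
#'
#' @param counts Named integer vector of per-class source counts.
#' @param plans Named list of [augment_plan()]s with the same names.
#' @return Tibble with `class`, `n_source`, `factor`, `n_augmented`.
#' @export
augment_counts <- function(counts, plans) {
  stopifnot(all(names(counts) %in% names(plans)))
  fac <- vapply(names(counts), function(k) plans[[k]]$factor, integer(1))
  tibble::tibble(
    class = names(counts),
    n_source = unname(as.integer(counts)),
    factor = unname(fac),
    n_augmented = unname(as.integer(counts) * fac))
}
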