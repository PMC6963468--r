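test_that("orientation leaves left views alone and mirrors right views", {
  ph <- generate_phantom(small_spec(seed = 2))
  o <- orient(ph$image)
  expect_false(o$flipped)
  expect_identical(o$image, ph$image)

  mirrored <- flip_horizontal(ph$image)
  o2 <- orient(mirrored)
  expect_true(o2$flipped)
  expect_identical(o2$image, ph$image)
  # idempotence
  o3 <- orient(o2$image)
  expect_false(o3$flipped)
})

test_that("orientation decision matches the half-count oracle", {
  for (i in 1:20) {
    side <- if (i %% 2 == 0) "left" else "right"
    ph <- generate_phantom(small_spec(seed = 100 + i, side = side))
    fg <- ph$image >= 18
    half <- ncol(fg) %/% 2
    oracle_flip <- sum(fg[, (ncol(fg) - half + 1):ncol(fg)]) >
      sum(fg[, seq_len(half)])
    expect_identical(orient(ph$image)$flipped, oracle_flip)
  }
})

test_that("artifact suppression removes every label pixel, keeps the breast", {
  ph <- generate_phantom(small_spec(seed = 9, n_labels = 2))
  s <- suppress_artifacts(ph$image)
  expect_true(all(s$image[ph$label_mask] == 0))
  # breast pixels survive up to the opening's boundary erosion
  expect_gt(sum(s$mask & ph$breast_mask) / sum(ph$breast_mask), 0.95)
  # mask is one 8-connected component
  expect_equal(max(label_components(s$mask)), 1)
  # suppression never increases a pixel
  expect_true(all(s$image <= ph$image))
  # background of level < 18 is fully zeroed
  expect_true(all(s$image[!ph$breast_mask & !ph$label_mask] == 0))
})

test_that("a single-component image keeps its opened threshold mask", {
  ph <- generate_phantom(small_spec(seed = 10, n_labels = 0))
  s <- suppress_artifacts(ph$image)
  fg <- ph$image >= 18
  r <- max(1L, round(min(dim(fg)) / 200))
  opened <- EBImage::opening(fg * 1, EBImage::makeBrush(2L * r + 1L, "disc")) > 0.5
  expect_identical(s$mask, largest_component_ref(opened))
})

test_that("SRG recovers homogeneous regions exactly", {
  img <- matrix(100L, 40, 40)
  img[10:20, 10:25] <- 200L
  region <- srg(img, c(15, 15), tolerance = 0)
  truth <- img == 200L
  expect_identical(region, truth)
  # saturating tolerance grows to the whole connected foreground component
  region2 <- srg(img, c(15, 15), tolerance = 255)
  expect_identical(region2, img >= 18)
})

test_that("SRG at tolerance zero equals the flood-fill oracle", {
  for (i in 1:10) {
    ph <- generate_phantom(small_spec(seed = 200 + i))
    seed_rc <- c(5L, 5L)
    expect_identical(srg(ph$image, seed_rc, tolerance = 0, threshold = 0),
                     flood_fill_oracle(ph$image, seed_rc))
  }
})

test_that("SRG region is 8-connected, contains the seeds, stays in foreground", {
  ph <- generate_phantom(small_spec(seed = 21))
  region <- srg(ph$image, c(30, 10), tolerance = 32)
  expect_true(region[30, 10])
  expect_equal(max(label_components(region)), 1)
  expect_true(all(ph$image[region] >= 18))
  expect_error(srg(ph$image, c(0, 5), tolerance = 1), "bounds")
})

test_that("pectoral removal hits the ground-truth triangle", {
  for (i in 1:3) {
    ph <- generate_phantom(small_spec(seed = 300 + i))
    s <- suppress_artifacts(ph$image)
    p <- remove_pectoral(s$image, s$mask)
    expect_gte(dice_coef(p$pectoral_mask, ph$pectoral_mask), 0.90)
    expect_true(any(p$pectoral_mask[1, ]))
    # masking identity outside the removed region
    expect_identical(p$image[!p$pectoral_mask], s$image[!p$pectoral_mask])
    expect_true(all(p$image[p$pectoral_mask] == 0))
  }
})

test_that("without a pectoral triangle only a small corner patch is removed", {
  ph <- generate_phantom(small_spec(seed = 17, pectoral_frac = 0))
  s <- suppress_artifacts(ph$image)
  expect_warning(p <- remove_pectoral(s$image, s$mask), "failed")
  expect_true(p$failed)
  # blacked-out area stays below the small-cap bound
  blacked <- s$image > 0 & p$image == 0
  expect_lt(sum(blacked) / sum(s$mask), 0.05)
})
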