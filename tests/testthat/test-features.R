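test_that("block partition keeps only full raster-ordered blocks", {
  withr::with_seed(1, img <- matrix(sample(0:255, 100 * 100, TRUE), 100, 100))
  blocks <- partition_blocks(img)
  expect_length(blocks, 36)                 # 6 x 6 full blocks, rest discarded
  expect_true(all(vapply(blocks, function(b) all(dim(b) == 16), logical(1))))
  # a 1024x1024 frame yields 64 x 64 = 4096 blocks
  expect_length(partition_blocks(matrix(0L, 1024, 1024)), 4096)
  expect_error(partition_blocks(matrix(0L, 8, 8)), "smaller")
})

test_that("concatenating the blocks of an exact tiling reconstructs the image", {
  withr::with_seed(2, img <- matrix(sample(0:255, 32 * 32, TRUE), 32, 32))
  blocks <- partition_blocks(img)
  rebuilt <- rbind(cbind(blocks[[1]], blocks[[2]]),
                   cbind(blocks[[3]], blocks[[4]]))
  expect_identical(rebuilt, img)
})

test_that("block entropy matches the direct histogram-sum oracle", {
  expect_equal(block_entropy(matrix(7L, 16, 16)), 0)
  expect_equal(block_entropy(matrix(0:255, 16, 16)), 8)   # all levels once
  withr::with_seed(3, {
    for (i in 1:100) {
      b <- matrix(sample(0:255, 256, TRUE), 16, 16)
      expect_equal(block_entropy(b), entropy_oracle(b), tolerance = 1e-12)
    }
  })
})

test_that("block statistics follow the population-divisor formulas", {
  cs <- block_stats(matrix(9L, 4, 4))
  expect_equal(as.numeric(cs),
               c(0, 9, 0, 0, 0, 9, 9, 9))

  b <- matrix(c(0L, 0L, 0L, 255L), 2, 2)
  s <- block_stats(b)
  expect_equal(s$mean, 63.75)
  expect_equal(s$variance, (3 * 63.75^2 + 191.25^2) / 4)   # population divisor
  expect_equal(s$variance, mean(b^2) - mean(b)^2)
  expect_equal(s$range, 255)
  expect_equal(s$sd, sqrt(s$variance))

  withr::with_seed(4, {
    for (i in 1:20) {
      b <- matrix(sample(0:255, 64, TRUE), 8, 8)
      expect_gte(block_stats(b)$rms, block_stats(b)$mean)  # power-mean bound
    }
  })
})

test_that("a constant image has the degenerate feature vector (0,c,0,0,0,c,c,c)", {
  fx <- extract_features(matrix(37L, 48, 48))
  expect_identical(names(fx), feature_names())
  expect_equal(as.numeric(fx), c(0, 37, 0, 0, 0, 37, 37, 37))
})

test_that("aggregated features obey the analytic identities", {
  ph <- generate_phantom(small_spec(seed = 11, lesion = list()))
  fx <- extract_features(ph$image)
  expect_length(as.numeric(fx), 8)
  expect_equal(fx$range, fx$maximum - fx$minimum)
  expect_lte(fx$sd, sqrt(fx$variance))
  expect_true(fx$entropy >= 0 && fx$entropy <= 8)
  expect_true(fx$minimum <= fx$mean && fx$mean <= fx$maximum)
  # mean feature equals the global mean when the blocks tile the image
  expect_equal(fx$mean, mean(ph$image[1:96, 1:96]))
})

test_that("all 8 default features are invariant under quarter-turn rotations", {
  for (i in 1:10) {
    ph <- generate_phantom(small_spec(seed = 400 + i,
                                      lesion = if (i %% 2) list() else NULL))
    ref <- extract_features(ph$image)
    for (deg in c(90, 180, 270)) {
      rot <- extract_features(rotate90(ph$image, deg))
      expect_equal(as.numeric(rot), as.numeric(ref), tolerance = 1e-10)
    }
  }
})

test_that("the directional row-column RMS variant differs and is exposed", {
  withr::with_seed(12, img <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64))
  px <- extract_features(img)$rms
  rc <- extract_features(img, rms_mode = "row_col")$rms
  expect_false(isTRUE(all.equal(px, rc)))
  # the directional variant averages squared row and column means per block
  b <- partition_blocks(img)[[1]]
  expect_equal(block_stats(b, rms_mode = "row_col")$rms,
               sqrt(mean(c(rowMeans(b)^2, colMeans(b)^2))))
})
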