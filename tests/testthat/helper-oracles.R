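# Independent oracles and small fixtures used across the suite. Every oracle
# is a direct, brute-force restatement of the quantity it checks, kept free
# of the package's own code paths.

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Plain global histogram equalization by direct CDF mapping.
he_oracle <- function(image) {
  n <- length(image)
  cdf <- cumsum(tabulate(as.integer(image) + 1L, nbins = 256L))
  out <- matrix(round(255 * cdf[as.integer(image) + 1L] / n),
                nrow(image), ncol(image))
  storage.mode(out) <- "integer"
  out
}

# Breadth-first flood fill over pixels exactly equal to the seed intensity,
# 8-connected; queue held as parallel row/col vectors with a head pointer.
flood_fill_oracle <- function(image, seed_rc) {
  h <- nrow(image); w <- ncol(image)
  target <- image[seed_rc[1], seed_rc[2]]
  visited <- matrix(FALSE, h, w)
  qr <- integer(h * w); qc <- integer(h * w)
  qr[1] <- seed_rc[1]; qc[1] <- seed_rc[2]
  head <- 1L; tail <- 1L
  visited[seed_rc[1], seed_rc[2]] <- TRUE
  while (head <= tail) {
    pr <- qr[head]; pc <- qc[head]; head <- head + 1L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r <- pr + dr; c <- pc + dc
      if (r < 1 || r > h || c < 1 || c > w) next
      if (!visited[r, c] && image[r, c] == target) {
        visited[r, c] <- TRUE
        tail <- tail + 1L
        qr[tail] <- r; qc[tail] <- c
      }
    }
  }
  visited
}

# Largest 8-connected component by repeated flood fill (independent of the
# package's label-propagation implementation).
largest_component_ref <- function(mask) {
  comp <- matrix(0L, nrow(mask), ncol(mask))
  next_id <- 0L
  for (idx in which(mask)) {
    r <- ((idx - 1L) %% nrow(mask)) + 1L
    c <- ((idx - 1L) %/% nrow(mask)) + 1L
    if (comp[r, c] == 0L) {
      next_id <- next_id + 1L
      fill <- flood_fill_oracle(1L * mask, c(r, c))
      comp[fill] <- next_id
    }
  }
  if (next_id == 0L) return(mask & FALSE)
  counts <- tabulate(comp[comp > 0])
  comp == which.max(counts)
}

# Direct per-histogram entropy sum.
entropy_oracle <- function(block) {
  v <- as.vector(block)
  pr <- as.numeric(table(v)) / length(v)
  -sum(pr * log2(pr))
}

# Brute-force k-NN with the same contract: min-max scaling learned from the
# training data, distance ties by training index, majority with
# nearer-neighbour tie-break falling to class 0.
knn_oracle <- function(X_train, y_train, X_query, k) {
  mins <- apply(X_train, 2, min)
  rng <- apply(X_train, 2, max) - mins
  rng[rng == 0] <- 1
  st <- sweep(sweep(X_train, 2, mins), 2, rng, "/")
  sq <- sweep(sweep(X_query, 2, mins), 2, rng, "/")
  apply(sq, 1, function(q) {
    d <- sqrt(rowSums(sweep(st, 2, q)^2))
    nb <- order(d, seq_along(d))[seq_len(k)]
    p1 <- mean(y_train[nb] == 1)
    if (p1 > 0.5) return(1L)
    if (p1 < 0.5) return(0L)
    d0 <- suppressWarnings(min(d[nb][y_train[nb] == 0]))
    d1 <- suppressWarnings(min(d[nb][y_train[nb] == 1]))
    if (d1 < d0) 1L else 0L
  })
}

# All-pairs Mann-Whitney AUC.
auc_oracle <- function(scores, y) {
  s1 <- scores[y == 1]; s0 <- scores[y == 0]
  mean(outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Exhaustive wrapper-FS optimum over all nonempty subsets of d features.
exhaustive_best <- function(data, kind, cv_folds, seed, label_col = "label") {
  feats <- setdiff(names(data), label_col)
  d <- length(feats)
  best_obj <- -Inf; best_sub <- NULL
  for (m in seq_len(2^d - 1)) {
    sub <- feats[bitwAnd(m, 2^(seq_len(d) - 1)) > 0]
    obj <- subset_objective(data, sub, kind = kind, cv_folds = cv_folds,
                            seed = seed, label_col = label_col)
    if (obj > best_obj) { best_obj <- obj; best_sub <- sub }
  }
  list(objective = best_obj, subset = sort(best_sub))
}

# Small labeled dataset: one informative feature plus pure-noise columns.
make_informative_dataset <- function(n = 100, n_noise = 7, shift = 2,
                                     seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), each = n / 2)
    df <- tibble::tibble(informative = rnorm(n, mean = shift * y))
    for (j in seq_len(n_noise)) {
      df[[paste0("noise", j)]] <- rnorm(n)
    }
    df$label <- y
    df[sample.int(n), ]
  })
}

# Small phantom spec used where full-size images are unnecessary.
small_spec <- function(seed = 1, ...) {
  phantom_spec(size = c(96, 96), seed = seed, ...)
}

# Mirror a ground-truth mask when the orientation step mirrored the image.
flip_if <- function(mask, flipped) {
  if (flipped) mask[, rev(seq_len(ncol(mask)))] else mask
}
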