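#' Read an 8-bit grayscale image
#'
#' Reads a PGM (P2 ASCII or P5 binary) or PNG file into an integer matrix of
#' grey levels in `[0, 255]`, row-major with origin at the top-left. Colour
#' PNGs are converted to luminance (Rec. 601 weights); 16-bit inputs are
#' rejected so that the round-trip with [write_gray()] stays bit-exact.
#'
#' @param path Path to a `.pgm` or `.png` file.
#' @return Integer matrix (rows x cols) with values in `[0, 255]`.
#' @seealso [write_gray()]
#' @export
read_gray <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    pgm = read_pgm(path),
    png = read_png_gray(path),
    stop(sprintf("unsupported image format: .%s (use PGM or PNG)", ext),
         call. = FALSE)
  )
  storage.mode(img) <- "integer"
  img
}

#' Write an 8-bit grayscale image
#'
#' Writes an integer matrix of grey levels to PGM (P5, or P2 with
#' `ascii = TRUE`) or PNG. Round-trip with [read_gray()] is bit-exact.
#'
#' @param image Matrix with values in `[0, 255]`.
#' @param path Output path; format chosen by extension (`.pgm` or `.png`).
#' @param ascii For PGM, write plain-text P2 instead of binary P5.
#' @return `path`, invisibly.
#' @export
write_gray <- function(image, path, ascii = FALSE) {
  assert_gray(image)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    pgm = write_pgm(image, path, ascii = ascii),
    png = png::writePNG(image / 255, target = path),
    stop(sprintf("unsupported image format: .%s (use PGM or PNG)", ext),
         call. = FALSE)
  )
  invisible(path)
}

read_png_gray <- function(path) {
  a <- png::readPNG(path)
  if (max(a) > 1 + 1e-12) stop("PNG decode out of range", call. = FALSE)
  # readPNG scales by 2^bits - 1; detect 16-bit content by non-8-bit levels
  v <- round(a * 65535)
  if (any(v %% 257 != 0)) {
    stop("unsupported bit depth: 16-bit PNG; only 8-bit grayscale is supported",
         call. = FALSE)
  }
  if (length(dim(a)) == 3L) {
    nch <- dim(a)[3]
    if (nch >= 3L) {
      a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    } else {
      a <- a[, , 1]
    }
  }
  clip_gray(a * 255)
}

# Minimal PGM (P2/P5) reader; maxval > 255 is a format error.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tokens <- character(0)
  # Header: magic, width, height, maxval -- whitespace separated, '#' comments
  buf <- character(0)
  read_token <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0) stop("truncated PGM header", call. = FALSE)
      if (ch == "#") { # comment to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0 || ch == "\n") break
        }
        next
      }
      if (grepl("^[ \t\r\n]$", ch)) {
        if (length(buf)) break else next
      }
      buf <<- c(buf, ch)
    }
    tok <- paste(buf, collapse = "")
    buf <<- character(0)
    tok
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P5")) {
    stop(sprintf("not a PGM file (magic %s)", magic), call. = FALSE)
  }
  width <- as.integer(read_token())
  height <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (is.na(width) || is.na(height) || is.na(maxval)) {
    stop("malformed PGM header", call. = FALSE)
  }
  if (maxval > 255) {
    stop(sprintf(
      "unsupported bit depth: PGM maxval %d exceeds 255 (8-bit only; 16-bit inputs must be rescaled)",
      maxval), call. = FALSE)
  }
  n <- width * height
  if (magic == "P5") {
    raw_px <- readBin(con, "raw", n = n)
    if (length(raw_px) < n) stop("truncated PGM pixel data", call. = FALSE)
    px <- as.integer(raw_px)
  } else {
    txt <- readChar(con, file.info(path)$size, useBytes = TRUE)
    px <- as.integer(strsplit(trimws(txt), "[ \t\r\n]+")[[1]])
    if (length(px) < n || anyNA(px)) stop("truncated PGM pixel data", call. = FALSE)
    px <- px[seq_len(n)]
  }
  # PGM stores rows top-to-bottom, row-major
  matrix(px, nrow = height, ncol = width, byrow = TRUE)
}

write_pgm <- function(image, path, ascii = FALSE) {
  h <- nrow(image); w <- ncol(image)
  px <- as.integer(t(image)) # row-major
  if (ascii) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P2\n%d %d\n255\n", w, h), con, eos = NULL)
    rows <- apply(matrix(px, ncol = w, byrow = TRUE), 1, paste, collapse = " ")
    writeChar(paste0(paste(rows, collapse = "\n"), "\n"), con, eos = NULL)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", w, h), con, eos = NULL)
    writeBin(as.raw(px), con)
  }
  invisible(path)
}

#' Write a feature table to CSV
#'
#' Writes per-image feature rows (the 8 canonical features plus a `label`
#' column and any identifier columns) at full precision. Read-back with
#' [read_features()] reproduces the numbers to within 1e-12 relative error
#' and preserves row order.
#'
#' @param features Data frame holding the 8 canonical feature columns
#'   (see [feature_names()]) and a `label` column.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  features <- tibble::as_tibble(features)
  missing <- setdiff(FEATURE_NAMES, names(features))
  if (length(missing)) {
    stop(sprintf("feature table is missing columns: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  ord <- c(setdiff(names(features), c(FEATURE_NAMES, "label")),
           FEATURE_NAMES,
           intersect("label", names(features)))
  readr::write_csv(features[ord], path)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path CSV written by [write_features()] (or with the same schema).
#' @return Tibble with the canonical feature columns and any extra columns.
#' @export
read_features <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(FEATURE_NAMES, names(out))
  if (length(missing)) {
    stop(sprintf("feature CSV is missing columns: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  out
}
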