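#' Label connected components of a binary mask
#'
#' 8-connected (default) or 4-connected component labelling by iterative
#' minimum-label propagation: every foreground pixel starts with its own
#' label and repeatedly takes the minimum over its neighbourhood until a
#' fixed point, then labels are renumbered 1..k in first-pixel order
#' (column-major, matching R matrix indexing).
#'
#' @param mask Logical (or 0/1) matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix; 0 is background, components numbered from 1.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  m <- mask != 0
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  lab[m] <- seq_len(sum(m))
  lab[m] <- seq_len(h * w)[m]          # unique seed label per pixel
  big <- .Machine$integer.max
  repeat {
    cur <- ifelse(m, lab, big)
    nb <- cur
    shift <- function(x, dr, dc) {
      out <- matrix(big, h, w)
      rs <- max(1, 1 + dr):min(h, h + dr)
      cs <- max(1, 1 + dc):min(w, w + dc)
      out[rs, cs] <- x[rs - dr, cs - dc, drop = FALSE]
      out
    }
    offs <- if (connectivity == 8) {
      list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
           c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
    } else {
      list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
    }
    for (o in offs) nb <- pmin(nb, shift(cur, o[1], o[2]))
    nb[!m] <- 0L
    newlab <- pmin(ifelse(m, lab, 0L), ifelse(m, nb, 0L))
    if (identical(newlab, lab)) break
    lab <- newlab
  }
  # renumber in order of first occurrence
  ids <- unique(lab[lab > 0])
  lab[lab > 0] <- match(lab[lab > 0], ids)
  storage.mode(lab) <- "integer"
  lab
}

# Largest component (by pixel count) of a binary mask, as a logical matrix.
largest_component <- function(mask, connectivity = 8) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(matrix(FALSE, nrow(mask), ncol(mask)))
  counts <- tabulate(lab[lab > 0])
  lab == which.max(counts)
}
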