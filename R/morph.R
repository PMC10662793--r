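# Binary morphology and connected components for 2D and 3D masks.
# Written in-array (shift/combine) so the same code serves matrices and
# volumes; structuring elements are Euclidean disks/balls.

ball_offsets <- function(radius, d) {
  r <- max(0L, as.integer(floor(radius)))
  g <- as.matrix(do.call(expand.grid, rep(list(-r:r), d)))
  dimnames(g) <- NULL
  g[rowSums(g^2) <= radius^2, , drop = FALSE]
}

binary_dilate <- function(mask, radius) {
  offs <- ball_offsets(radius, length(dim(mask)))
  out <- array(FALSE, dim(mask))
  for (r in seq_len(nrow(offs)))
    out <- out | shift_array(mask, offs[r, ], fill = FALSE)
  out
}

binary_erode <- function(mask, radius) {
  offs <- ball_offsets(radius, length(dim(mask)))
  out <- array(TRUE, dim(mask))
  for (r in seq_len(nrow(offs)))
    out <- out & shift_array(mask, offs[r, ], fill = FALSE)
  out
}

## Closing (dilation then erosion).  Out-of-image cells count as
## background for the erosion, so near the border closing may not be
## extensive; callers that need mask-growth-only semantics should union
## with the input.
binary_close <- function(mask, radius) binary_erode(binary_dilate(mask, radius), radius)

## Fill holes: background cells not face-connected (4/6) to the image
## border become foreground.
fill_holes <- function(mask) {
  dm <- dim(mask); d <- length(dm)
  bg <- !mask
  offs <- face_offsets(d)
  reach <- array(FALSE, dm)
  border <- which(bg & border_mask(dm))
  if (length(border) == 0L) return(mask)
  reach[border] <- TRUE
  frontier <- index_to_coords(border, dm)
  while (nrow(frontier) > 0L) {
    cand <- expand_coords(frontier, offs, dm)
    if (nrow(cand) == 0L) break
    lin <- coords_to_index(cand, dm)
    keep <- bg[lin] & !reach[lin]
    lin <- lin[keep]
    if (length(lin) == 0L) break
    reach[lin] <- TRUE
    frontier <- cand[keep, , drop = FALSE]
  }
  mask | (bg & !reach)
}

border_mask <- function(dm) {
  m <- array(FALSE, dm)
  for (k in seq_along(dm)) {
    idx <- rep(list(quote(expr = )), length(dm))
    idx[[k]] <- c(1L, dm[k])
    m <- do.call(`[<-`, c(list(m), idx, list(value = TRUE)))
  }
  m
}

## Label connected components (full 8/26 connectivity).  Returns an
## integer array: 0 = background, 1..n component ids.
label_components <- function(mask, connectivity = c("full", "face")) {
  connectivity <- match.arg(connectivity)
  dm <- dim(mask); d <- length(dm)
  offs <- if (connectivity == "full") neighbor_offsets(d) else face_offsets(d)
  labels <- array(0L, dm)
  todo <- which(mask)
  lab <- 0L
  for (start in todo) {
    if (labels[start] > 0L) next
    lab <- lab + 1L
    labels[start] <- lab
    frontier <- index_to_coords(start, dm)
    while (nrow(frontier) > 0L) {
      cand <- expand_coords(frontier, offs, dm)
      if (nrow(cand) == 0L) break
      lin <- coords_to_index(cand, dm)
      keep <- mask[lin] & labels[lin] == 0L
      lin <- lin[keep]
      if (length(lin) == 0L) break
      labels[lin] <- lab
      frontier <- cand[keep, , drop = FALSE]
    }
  }
  labels
}
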