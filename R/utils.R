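# Internal helpers shared across modules.  All point coordinates in the
# package are 1-based array indices in the storage order of the image
# array (row, column[, slice] for arrays built here; whatever order the
# source file uses for NIfTI volumes).

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

## Evaluate expr under a fixed RNG state, restoring the caller's state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647L))
  force(expr)
}

## Deterministic per-stage substream seed derived from a master seed, so
## that toggling one stochastic stage does not shift another's draws.
substream_seed <- function(master, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(master) * 48271 + h) %% 2147483647)
}

## All 3^d - 1 unit offsets: 8-neighbourhood in 2D, 26 in 3D.
neighbor_offsets <- function(d) {
  g <- as.matrix(do.call(expand.grid, rep(list(-1:1), d)))
  dimnames(g) <- NULL
  g[rowSums(g != 0L) > 0L, , drop = FALSE]
}

## Face-connected offsets (4 / 6), used for background flood in hole filling.
face_offsets <- function(d) {
  o <- matrix(0L, 2L * d, d)
  for (i in seq_len(d)) { o[2L * i - 1L, i] <- -1L; o[2L * i, i] <- 1L }
  o
}

## coords: n x d integer matrix -> linear indices into an array of dim dm.
coords_to_index <- function(coords, dm) {
  d <- length(dm)
  idx <- coords[, 1L]
  mult <- 1
  for (k in seq_len(d - 1L)) {
    mult <- mult * dm[k]
    idx <- idx + (coords[, k + 1L] - 1L) * mult
  }
  as.integer(idx)
}

index_to_coords <- function(idx, dm) arrayInd(idx, .dim = dm)

## Expand a frontier (n x d coords) by a neighbourhood; returns unique
## in-bounds candidate coords.  No wrap-around: bounds checked per axis.
expand_coords <- function(coords, offsets, dm) {
  n <- nrow(coords); k <- nrow(offsets); d <- ncol(coords)
  cand <- coords[rep(seq_len(n), each = k), , drop = FALSE] +
    offsets[rep(seq_len(k), times = n), , drop = FALSE]
  ok <- rep(TRUE, nrow(cand))
  for (a in seq_len(d)) ok <- ok & cand[, a] >= 1L & cand[, a] <= dm[a]
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0L) return(cand)
  cand[!duplicated(coords_to_index(cand, dm)), , drop = FALSE]
}

## Euclidean distance of each row of coords from a (possibly fractional) point.
dist_from_point <- function(coords, point, spacing = NULL) {
  d2 <- 0
  for (a in seq_len(ncol(coords))) {
    dd <- coords[, a] - point[a]
    if (!is.null(spacing)) dd <- dd * spacing[a]
    d2 <- d2 + dd * dd
  }
  sqrt(d2)
}

## Points of a mask with at least one neighbour outside the mask (or
## outside the image) under the full 8/26 neighbourhood.
mask_boundary_indices <- function(mask) {
  dm <- dim(mask)
  offs <- neighbor_offsets(length(dm))
  inner <- mask
  for (r in seq_len(nrow(offs))) {
    sh <- shift_array(mask, offs[r, ], fill = FALSE)
    inner <- inner & sh
  }
  which(mask & !inner)
}

## Shift a logical/numeric array by an integer offset, filling vacated
## cells with `fill`.  shift +1 along axis a moves content toward higher
## indices (out[i] = in[i - off]).
shift_array <- function(a, off, fill = FALSE) {
  dm <- dim(a)
  out <- array(fill, dm)
  src <- dst <- vector("list", length(dm))
  for (k in seq_along(dm)) {
    o <- off[k]
    if (o >= 0) { dst[[k]] <- seq_len(dm[k] - o) + o; src[[k]] <- seq_len(dm[k] - o) }
    else        { dst[[k]] <- seq_len(dm[k] + o);     src[[k]] <- seq_len(dm[k] + o) - o }
    if (length(dst[[k]]) == 0L) return(out)
  }
  block <- do.call(`[`, c(list(a), src, list(drop = FALSE)))
  do.call(`[<-`, c(list(out), dst, list(value = block)))
}
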