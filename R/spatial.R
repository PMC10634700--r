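#' All cell pairs within a radius (grid-binned search)
#'
#' Finds every unordered pair of points whose Euclidean centroid distance is
#' at most `radius` (inclusive). Points are binned on a square grid of cell
#' size `radius`, so only the 3x3 neighborhood of bins needs comparing;
#' distances are compared squared, never square-rooted, so the inclusive
#' boundary is exact. Results are identical to a full O(n^2) scan.
#'
#' @param x,y Numeric coordinate vectors (microns).
#' @param radius Inclusive distance threshold (> 0).
#' @return Integer matrix with columns `i`, `j` (`i < j`), one row per
#'   qualifying pair; zero rows when none qualify.
#' @export
radius_pairs <- function(x, y, radius) {
  stopifnot(length(x) == length(y), radius > 0)
  n <- length(x)
  empty <- matrix(integer(), 0L, 2L, dimnames = list(NULL, c("i", "j")))
  if (n < 2L) return(empty)
  r2 <- radius * radius

  bx <- floor(x / radius); by <- floor(y / radius)
  bx <- bx - min(bx); by <- by - min(by)
  ncb <- max(bx) + 3  # pad so the -1/+1 bin offsets can never collide
  key <- bx + by * ncb
  bins <- split(seq_len(n), key)
  keys <- as.numeric(names(bins))
  # half-set of neighbor offsets: (0,0) handled separately, then
  # (+1,0), (-1,+1), (0,+1), (+1,+1) so each bin pair is visited once
  offs <- c(1, ncb - 1, ncb, ncb + 1)

  out <- vector("list", 5L * length(bins))
  k <- 0L
  for (b in seq_along(bins)) {
    ib <- bins[[b]]
    if (length(ib) > 1L) {
      d2 <- outer(x[ib], x[ib], "-")^2 + outer(y[ib], y[ib], "-")^2
      w <- which(upper.tri(d2) & d2 <= r2, arr.ind = TRUE)
      if (nrow(w)) { k <- k + 1L; out[[k]] <- cbind(ib[w[, 1]], ib[w[, 2]]) }
    }
    for (o in offs) {
      nb <- match(keys[b] + o, keys)
      if (is.na(nb)) next
      jb <- bins[[nb]]
      d2 <- outer(x[ib], x[jb], "-")^2 + outer(y[ib], y[jb], "-")^2
      w <- which(d2 <= r2, arr.ind = TRUE)
      if (nrow(w)) { k <- k + 1L; out[[k]] <- cbind(ib[w[, 1]], jb[w[, 2]]) }
    }
  }
  if (!k) return(empty)
  p <- do.call(rbind, out[seq_len(k)])
  swap <- p[, 1] > p[, 2]
  p[swap, ] <- p[swap, 2:1]
  colnames(p) <- c("i", "j")
  p[order(p[, 1], p[, 2]), , drop = FALSE]
}
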