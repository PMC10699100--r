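#' Select high-signal square regions from the reference channel
#'
#' Candidates are the non-overlapping grid cells of side `size` (stride =
#' `size`, origin at the top-left pixel), ranked by descending mean
#' reference-channel intensity; ties are broken in row-major order (y, then
#' x). Ranking on the reference channel keeps selection blind to the tag
#' channel, so the regressed variable is not selected on. Grid cells
#' containing any saturated pixel are excluded from ranking by default,
#' since saturated means distort the regression. Selection is fully
#' deterministic for a given image.
#'
#' Coordinates are 0-based with a half-open extent
#' `[x0, x0 + size) x [y0, y0 + size)`, origin at the top-left.
#'
#' @param ref_channel Numeric or integer matrix (rows = y, columns = x).
#' @param n Number of regions to select (default 20).
#' @param size Region side length in pixels (default 30).
#' @param exclude_saturated Drop grid cells containing any pixel at the
#'   intensity ceiling.
#' @param ceiling Intensity ceiling used by the saturation guard.
#' @return A data frame of regions: `x0`, `y0`, `size`, `mean_ref`
#'   (selection score), ordered best-first.
#' @export
select_regions <- function(ref_channel, n = 20L, size = 30L,
                           exclude_saturated = TRUE, ceiling = 65535) {
  stopifnot(is.matrix(ref_channel))
  h <- nrow(ref_channel); w <- ncol(ref_channel)
  if (h < size || w < size)
    stop("image (", w, "x", h, ") is smaller than one ", size, "x", size,
         " region", call. = FALSE)
  if (n < 1L) stop("'n' must be >= 1", call. = FALSE)
  xs <- seq.int(0L, w - size, by = size)
  ys <- seq.int(0L, h - size, by = size)
  grid <- expand.grid(y0 = ys, x0 = xs, KEEP.OUT.ATTRS = FALSE)
  stats <- vapply(seq_len(nrow(grid)), function(i) {
    block <- ref_channel[(grid$y0[i] + 1L):(grid$y0[i] + size),
                         (grid$x0[i] + 1L):(grid$x0[i] + size)]
    c(mean(block), max(block))
  }, numeric(2))
  grid$mean_ref <- stats[1L, ]
  if (exclude_saturated) {
    keep <- stats[2L, ] < ceiling
    grid <- grid[keep, , drop = FALSE]
  }
  ord <- order(-grid$mean_ref, grid$y0, grid$x0)
  grid <- grid[ord, , drop = FALSE]
  if (nrow(grid) < n)
    warning("only ", nrow(grid), " candidate regions available (requested ",
            n, ")", call. = FALSE)
  out <- utils::head(grid, n)
  rownames(out) <- NULL
  data.frame(x0 = as.integer(out$x0), y0 = as.integer(out$y0),
             size = as.integer(size), mean_ref = out$mean_ref)
}

#' Measure per-region mean gray values in both channels
#'
#' Arithmetic mean pixel intensity over each region's half-open extent, per
#' channel.
#'
#' @param pair An `image_pair`.
#' @param regions Data frame with columns `x0`, `y0`, `size` (0-based
#'   top-left corner, side length), e.g. from [select_regions()].
#' @return A data frame with one row per region: `image_id`, `x0`, `y0`,
#'   `size`, `mean_ref`, `mean_tag`.
#' @export
measure_regions <- function(pair, regions) {
  stopifnot(inherits(pair, "image_pair"),
            all(c("x0", "y0", "size") %in% names(regions)))
  h <- nrow(pair$ref); w <- ncol(pair$ref)
  k <- nrow(regions)
  mean_ref <- numeric(k); mean_tag <- numeric(k)
  for (i in seq_len(k)) {
    x0 <- regions$x0[i]; y0 <- regions$y0[i]; s <- regions$size[i]
    if (x0 < 0L || y0 < 0L || x0 + s > w || y0 + s > h)
      stop("region (x0=", x0, ", y0=", y0, ", size=", s,
           ") exceeds image bounds ", w, "x", h, call. = FALSE)
    rows <- (y0 + 1L):(y0 + s); cols <- (x0 + 1L):(x0 + s)
    mean_ref[i] <- mean(pair$ref[rows, cols])
    mean_tag[i] <- mean(pair$tag[rows, cols])
  }
  data.frame(image_id = pair$image_id,
             x0 = as.integer(regions$x0), y0 = as.integer(regions$y0),
             size = as.integer(regions$size),
             mean_ref = mean_ref, mean_tag = mean_tag)
}
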