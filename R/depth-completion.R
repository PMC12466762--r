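# Hole filling of range images from the outer ring of a 5x5 window.

# The 16 offsets at Chebyshev distance exactly 2 from the center.
ring16_offsets <- function() {
  g <- expand.grid(dr = -2:2, dc = -2:2)
  g[pmax(abs(g$dr), abs(g$dc)) == 2L, , drop = FALSE]
}

#' Fill missing depth values from the 16-pixel peripheral ring
#'
#' Every missing pixel (value 0) whose 5x5 window's outer ring contains at
#' least one valid (> 0) pixel is replaced by the arithmetic mean of the
#' valid ring values. Fills within a pass are computed simultaneously from
#' the pre-pass map (Jacobi update), so results do not depend on scan
#' order; valid pixels are never modified. Passes repeat until no pixel
#' changes or `max_passes` is reached -- a single pass is the strict
#' ring-mean operator, while additional passes extend it into hole blobs
#' wider than the ring. At image borders the window is clipped and the mean
#' uses only ring positions inside the image.
#'
#' @param depth `depth_map` or numeric matrix (meters; 0 = missing).
#' @param max_passes Maximum number of Jacobi passes (default 5).
#' @return A `depth_map` with attributes `passes_used` and `unfilled`
#'   (count of still-missing pixels). Warns when holes remain.
#' @export
complete_depth <- function(depth, max_passes = 5L) {
  if (!inherits(depth, "depth_map")) depth <- depth_map(depth)
  stopifnot(is_scalar_number(max_passes), max_passes >= 1)
  d <- unclass(depth)
  offs <- ring16_offsets()
  passes <- 0L
  repeat {
    if (passes >= max_passes || !any(d == 0)) break
    valid <- d > 0
    acc <- matrix(0, nrow(d), ncol(d))
    cnt <- matrix(0, nrow(d), ncol(d))
    for (k in seq_len(nrow(offs))) {
      acc <- acc + shift_matrix(d, offs$dr[k], offs$dc[k])
      cnt <- cnt + shift_matrix(valid + 0, offs$dr[k], offs$dc[k])
    }
    fill <- !valid & cnt > 0
    if (!any(fill)) break
    d[fill] <- acc[fill] / cnt[fill]
    passes <- passes + 1L
  }
  unfilled <- sum(d == 0)
  if (unfilled > 0)
    warning(sprintf("%d depth pixels remain unfilled after %d pass(es)",
                    unfilled, passes))
  out <- depth_map(d)
  attr(out, "passes_used") <- passes
  attr(out, "unfilled") <- unfilled
  out
}

#' Hole statistics before and after completion
#'
#' @param before,after Depth maps of identical dimensions.
#' @return List with `missing_before`, `missing_after` and `fill_fraction`
#'   = (missing_before - missing_after) / missing_before, with 0/0 defined
#'   as 1.
#' @export
hole_statistics <- function(before, after) {
  if (!all(dim(before) == dim(after)))
    stop_bovi("depth maps have different dimensions", class = "depth_error")
  nb <- sum(unclass(before) == 0)
  na_ <- sum(unclass(after) == 0)
  if (na_ > nb)
    stop_bovi("completion increased the number of holes (", nb, " -> ", na_, ")",
              class = "depth_error")
  list(missing_before = nb, missing_after = na_,
       fill_fraction = if (nb == 0) 1 else (nb - na_) / nb)
}
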