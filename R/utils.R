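# Internal helpers shared across modules.

#' Run code with a temporary RNG seed, restoring global state afterwards
#' @noRd
with_seed_ <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  if (x < lower || x > upper || (!allow_zero && x == 0)) {
    stop(sprintf("`%s` = %g is outside the allowed range [%g, %g]",
                 name, x, lower, upper), call. = FALSE)
  }
  invisible(x)
}

as_binary_matrix <- function(x, name = "mask") {
  if (is.logical(x)) {
    m <- x
    storage.mode(m) <- "logical"
    return(m)
  }
  if (!is.numeric(x)) stop(sprintf("`%s` must be a logical or 0/1 numeric matrix", name), call. = FALSE)
  if (any(!x %in% c(0, 1))) stop(sprintf("`%s` must be binary (0/1)", name), call. = FALSE)
  x > 0
}

#' Dice similarity coefficient between two binary masks
#'
#' @param a,b logical matrices of identical dimension.
#' @return A number in \[0, 1\]; 1 when both masks are empty.
#' @export
dice <- function(a, b) {
  a <- as_binary_matrix(a, "a"); b <- as_binary_matrix(b, "b")
  stopifnot(identical(dim(a), dim(b)))
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

#' Symmetric Hausdorff distance between two binary masks, in pixels
#'
#' Computed from Euclidean distance maps; returns `Inf` if either mask is
#' empty while the other is not.
#' @param a,b logical matrices of identical dimension.
#' @export
hausdorff_px <- function(a, b) {
  a <- as_binary_matrix(a, "a"); b <- as_binary_matrix(b, "b")
  stopifnot(identical(dim(a), dim(b)))
  if (sum(a) == 0 && sum(b) == 0) return(0)
  if (sum(a) == 0 || sum(b) == 0) return(Inf)
  # distance of every pixel to the nearest pixel of b: foreground = !b
  d_to_b <- EBImage::distmap(matrix(as.numeric(!b), nrow(b), ncol(b)))
  d_to_a <- EBImage::distmap(matrix(as.numeric(!a), nrow(a), ncol(a)))
  max(max(d_to_b[a]), max(d_to_a[b]))
}

#' One-pixel boundary of a binary mask (8-connected closed curve)
#' @param mask logical matrix.
#' @return logical matrix marking mask pixels with at least one
#'   4-neighbour outside the mask.
#' @export
mask_boundary <- function(mask) {
  mask <- as_binary_matrix(mask)
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  er <- EBImage::erode(m, EBImage::makeBrush(3, shape = "box"))
  mask & !(er > 0.5)
}

#' Fill the interior of a closed border curve
#'
#' @param border logical matrix holding a closed curve.
#' @return logical matrix of the curve plus its interior.
#' @export
fill_closed_border <- function(border) {
  border <- as_binary_matrix(border, "border")
  f <- EBImage::fillHull(matrix(as.numeric(border), nrow(border), ncol(border)))
  f > 0.5
}

largest_component <- function(mask) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  if (max(lab) == 0) return(mask & FALSE)
  tab <- tabulate(lab[lab > 0])
  lab == which.max(tab)
}

# 4-neighbour boundary-edge count (discrete perimeter surrogate)
perimeter_edges <- function(mask) {
  m <- mask
  sum(m[-1, ] != m[-nrow(m), ]) + sum(m[, -1] != m[, -ncol(m)])
}

morph_close <- function(mask, radius) {
  if (radius < 1) return(mask)
  br <- EBImage::makeBrush(2 * round(radius) + 1, shape = "disc")
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  EBImage::closing(m, br) > 0.5
}

morph_erode <- function(mask, radius) {
  if (radius < 1) return(mask)
  br <- EBImage::makeBrush(2 * round(radius) + 1, shape = "disc")
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  EBImage::erode(m, br) > 0.5
}

signed_distance <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  inside <- EBImage::distmap(m)
  outside <- EBImage::distmap(1 - m)
  as.matrix(inside) - as.matrix(outside)
}
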