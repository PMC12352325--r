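#' Triangular fuzzy numbers on the [0, 100] universe of discourse
#'
#' A triangular fuzzy number (TFN) is the triple (lower, mode, upper) with
#' membership rising linearly from 0 at `lower` to 1 at `mode` and falling
#' back to 0 at `upper`. All TFNs in this package live on the common
#' universe of discourse \[0, 100\], which is what makes heterogeneous
#' ordinal answer scales comparable after fuzzification.
#'
#' `tfn()` is vectorized: it returns an object of class `"tfn"`, a numeric
#' matrix with one row per fuzzy number and columns `lower`, `mode`, `upper`.
#'
#' @param lower,mode,upper numeric vectors (recycled to a common length)
#'   with `0 <= lower <= mode <= upper <= 100`.
#' @return A `"tfn"` object (n x 3 numeric matrix).
#' @examples
#' tfn(0, 0, 30)
#' defuzzify(tfn(c(0, 27.5), c(0, 40), c(30, 52.5)))
#' @export
tfn <- function(lower, mode, upper) {
  n <- max(length(lower), length(mode), length(upper))
  m <- cbind(lower = rep_len(as.numeric(lower), n),
             mode  = rep_len(as.numeric(mode), n),
             upper = rep_len(as.numeric(upper), n))
  validate_tfn(m)
  structure(m, class = c("tfn", "matrix"))
}

validate_tfn <- function(m) {
  if (anyNA(m)) stop("TFN components must not be NA", call. = FALSE)
  if (any(m < 0 | m > 100))
    stop("TFN components must lie in the universe of discourse [0, 100]",
         call. = FALSE)
  if (any(m[, 1] > m[, 2] | m[, 2] > m[, 3]))
    stop("TFN requires lower <= mode <= upper", call. = FALSE)
  invisible(m)
}

#' @export
print.tfn <- function(x, ...) {
  cat("<tfn> ", nrow(x), " triangular fuzzy number",
      if (nrow(x) != 1) "s", " on [0, 100]\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

is_tfn <- function(x) inherits(x, "tfn")

#' Centroid defuzzification of triangular fuzzy numbers
#'
#' Collapses each TFN to the crisp value `(lower + mode + upper) / 3`, the
#' centroid of the triangular membership function. This is the conventional
#' defuzzifier for triangular shapes and the one used throughout the PASI
#' pipeline (ideal solutions and distances are computed on centroids unless
#' the fully fuzzy distance is requested).
#'
#' @param x a `"tfn"` object.
#' @return Numeric vector of centroids, one per fuzzy number.
#' @examples
#' defuzzify(tfn(0, 0, 30))      # 10
#' defuzzify(tfn(75, 100, 100))  # 91.67
#' @export
defuzzify <- function(x) {
  stopifnot(is_tfn(x))
  unname(rowMeans(unclass(x)))
}

#' Vertex distance between triangular fuzzy numbers
#'
#' The standard fuzzy-TOPSIS metric between two TFNs a and b:
#' `sqrt( ((a1-b1)^2 + (a2-b2)^2 + (a3-b3)^2) / 3 )`.
#' Symmetric, and zero exactly when the two TFNs coincide. Used by the
#' fully fuzzy distance mode of the PASI computation.
#'
#' @param a,b `"tfn"` objects of equal length (or one of length 1, recycled).
#' @return Numeric vector of distances.
#' @examples
#' vertex_distance(tfn(0, 0, 30), tfn(70, 100, 100))  # sqrt(6600)
#' @export
vertex_distance <- function(a, b) {
  stopifnot(is_tfn(a), is_tfn(b))
  a <- unclass(a); b <- unclass(b)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  if (nrow(a) != nrow(b)) stop("TFN vectors of incompatible length", call. = FALSE)
  sqrt(rowSums((a - b)^2) / 3)
}

# component-wise arithmetic mean of a set of TFNs (rows of `x`)
mean_tfn <- function(x) {
  stopifnot(is_tfn(x), nrow(x) >= 1L)
  cm <- colMeans(unclass(x))
  tfn(cm[1L], cm[2L], cm[3L])
}
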