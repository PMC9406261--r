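#' Quantise an intensity image to 256 grey levels
#'
#' Images whose values are already integers in [0, 255] are used directly.
#' Any other image is linearly rescaled by its own minimum and maximum to
#' [0, 255] and rounded to the nearest level. A constant image maps to a
#' single occupied bin (level 0) and is flagged degenerate downstream.
#' This fixed convention makes thresholds on floating-point intermediates
#' reproducible bit-exactly.
#'
#' @param image numeric matrix.
#' @return Integer matrix with values in 0--255.
#' @export
quantize256 <- function(image) {
  if (length(image) == 0L)
    stop("empty image")
  if (anyNA(image))
    stop("image contains NA")
  v <- as.vector(image)
  if (all(v == round(v)) && min(v) >= 0 && max(v) <= 255) {
    q <- matrix(as.integer(image), nrow(image), ncol(image))
    return(q)
  }
  lo <- min(v)
  hi <- max(v)
  if (hi == lo)
    return(matrix(0L, nrow(image), ncol(image)))
  matrix(as.integer(round((image - lo) / (hi - lo) * 255)),
         nrow(image), ncol(image))
}

#' Grey-level histogram over 256 bins
#'
#' @param image numeric matrix; quantised with [quantize256()] first.
#' @return Named list of class `Histogram256` with `counts` (length-256
#'   integer vector for levels 0--255), `total` (pixel count) and
#'   `degenerate` (`TRUE` when a single grey level is occupied).
#' @examples
#' h <- histogram256(matrix(c(0, 0, 255, 255), 2))
#' h$counts[c(1, 256)]
#' @export
histogram256 <- function(image) {
  q <- quantize256(image)
  counts <- tabulate(as.vector(q) + 1L, nbins = 256L)
  structure(list(counts = counts, total = sum(counts),
                 degenerate = sum(counts > 0L) == 1L),
            class = "Histogram256")
}

#' @export
print.Histogram256 <- function(x, ...) {
  occ <- which(x$counts > 0L) - 1L
  cat(sprintf("Histogram256: %d pixels over %d occupied levels [%d, %d]%s\n",
              x$total, length(occ), min(occ), max(occ),
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

## Shannon entropy function S(u) with S(0) = S(1) = 0.
fuzzyEntropyS <- function(u) {
  s <- numeric(length(u))
  i <- u > 0 & u < 1
  s[i] <- -u[i] * log(u[i]) - (1 - u[i]) * log(1 - u[i])
  s
}

#' Huang fuzzy-entropy automatic threshold
#'
#' Selects the grey-level threshold minimising Huang and Wang's measure of
#' image fuzziness. For a candidate threshold t, the image is split into a
#' dark class (levels <= t, mean mu0) and a bright class (levels > t, mean
#' mu1); each level g gets a fuzzy membership
#' `u(g) = 1 / (1 + |g - mu_class| / C)` with `C = gmax - gmin`, and the
#' fuzziness is the mean Shannon entropy
#' `E(t) = (1/N) * sum_g counts[g] * S(u(g))` with
#' `S(u) = -u log u - (1-u) log(1-u)`. Candidates run over
#' `[gmin, gmax - 1]` so both classes are non-empty; ties break toward the
#' smallest t. E(t) is zero exactly when every occupied level sits at its
#' class mean.
#'
#' @param x a `Histogram256` (from [histogram256()]) or a numeric matrix,
#'   which is histogrammed first.
#' @return A [ThresholdResult-class]: the minimising threshold, its
#'   fuzziness, and the full entropy curve.
#' @references Huang, L.-K. and Wang, M.-J. J. (1995) Image thresholding by
#'   minimizing the measures of fuzziness. Pattern Recognition 28(1), 41-51.
#' @examples
#' img <- matrix(c(rep(20, 50), rep(200, 14)), 8)
#' threshold(huangThreshold(img))
#' @export
setGeneric("huangThreshold", function(x) standardGeneric("huangThreshold"))

#' @rdname huangThreshold
#' @export
setMethod("huangThreshold", "matrix",
          function(x) huangThreshold(histogram256(x)))

huangThresholdHist <- function(hist) {
  counts <- hist$counts
  g <- 0:255
  occ <- which(counts > 0L) - 1L
  if (length(occ) < 2L)
    stop("degenerate histogram: no threshold exists")
  gmin <- min(occ)
  gmax <- max(occ)
  C <- gmax - gmin
  ## cumulative moments for class means
  w <- cumsum(counts)                    # pixels at levels <= t
  m <- cumsum(counts * g)                # sum of grey values <= t
  total <- hist$total
  msum <- m[256]
  candidates <- gmin:(gmax - 1L)
  entropy <- vapply(candidates, function(t) {
    i <- t + 1L
    mu0 <- m[i] / w[i]
    mu1 <- (msum - m[i]) / (total - w[i])
    mu <- ifelse(g <= t, mu0, mu1)
    u <- 1 / (1 + abs(g - mu) / C)
    sum(counts * fuzzyEntropyS(u)) / total
  }, numeric(1))
  best <- which.min(entropy)             # which.min takes the first minimum
  new("ThresholdResult", threshold = as.integer(candidates[best]),
      fuzziness = entropy[best], candidates = as.integer(candidates),
      entropy = entropy)
}

#' @rdname huangThreshold
#' @export
setMethod("huangThreshold", "ANY", function(x) {
  if (!inherits(x, "Histogram256"))
    stop("huangThreshold needs a Histogram256 or a numeric matrix")
  huangThresholdHist(x)
})

#' Apply a grey-level threshold to an image
#'
#' Foreground is the set of pixels whose [quantize256()]-binned grey level
#' is strictly greater than `t` — the same binning used by
#' [histogram256()], so the foreground count always equals the histogram
#' tail sum above t.
#'
#' @param image numeric matrix.
#' @param t grey level in [0, 255] (or a [ThresholdResult-class]).
#' @return Logical matrix: `TRUE` for foreground.
#' @export
applyThreshold <- function(image, t) {
  if (is(t, "ThresholdResult"))
    t <- t@threshold
  if (length(t) != 1L || is.na(t) || t < 0 || t > 255)
    stop("threshold must be a single grey level in [0, 255]")
  quantize256(image) > t
}
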