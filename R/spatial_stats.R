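#' @useDynLib guildnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Jenks natural-breaks classification
#'
#' Exact optimal 1-D classification (Fisher dynamic program): partitions the
#' values into `k` contiguous classes minimising the total within-class sum of
#' squared deviations. Ties in the optimum are broken toward the lowest
#' boundary. Rasters larger than `max_n` cells are classified from a
#' deterministic stride over the sorted values, then every value is assigned
#' to the nearest class by its breaks.
#'
#' @param values numeric vector (NAs dropped).
#' @param k number of classes (reduced with a warning if there are fewer
#'   distinct values).
#' @param max_n cap on the number of values entering the dynamic program.
#' @return object of class `jenks_breaks`: list with `k`, `breaks` (upper
#'   boundaries of classes 1..k-1, ascending), and `gvf` (goodness of variance
#'   fit in [0, 1]).
#' @export
jenks <- function(values, k, max_n = 10000) {
  stopifnot(k >= 1)
  x <- values[is.finite(values)]
  if (!length(x)) stop("jenks: no finite values")
  ux <- sort(unique(x))
  if (length(ux) < k) {
    warning(sprintf("jenks: only %d distinct values, reducing k from %d",
                    length(ux), k))
    k <- length(ux)
  }
  xs <- sort(x)
  if (length(xs) > max_n) {
    idx <- unique(round(seq(1, length(xs), length.out = max_n)))
    xs <- xs[idx]
  }
  starts <- .jenks_dp(xs, as.integer(k))
  # class j covers xs[starts[j] .. starts[j+1]-1]; breaks = upper boundaries
  breaks <- if (k > 1) xs[starts[-1] - 1L] else numeric(0)
  sdam <- sum((x - mean(x))^2)
  cls <- jenks_assign(x, breaks)
  sdcm <- sum(unlist(lapply(split(x, cls), function(g) (g - mean(g))^2)))
  gvf <- if (sdam > 0) 1 - sdcm / sdam else 1
  structure(list(k = k, breaks = breaks, gvf = gvf), class = "jenks_breaks")
}

#' Assign values to Jenks classes
#' @param values numeric vector.
#' @param breaks ascending upper class boundaries (from [jenks()]).
#' @return integer class index 1..(length(breaks)+1); `NA` stays `NA`.
#' @export
jenks_assign <- function(values, breaks) {
  if (inherits(breaks, "jenks_breaks")) breaks <- breaks$breaks
  cls <- rep(NA_integer_, length(values))
  ok <- is.finite(values)
  cls[ok] <- findInterval(values[ok], breaks, left.open = TRUE) + 1L
  cls
}

#' Weighted Gaussian kernel density on a raster grid
#'
#' Places the point weights in their containing cells and convolves with an
#' isotropic Gaussian kernel truncated at 4 standard deviations. The surface
#' integrates (cell area times density summed) to the total weight, up to
#' edge truncation. Linear in the weights.
#'
#' @param rg reference `raster_grid` (geometry only; values ignored).
#' @param x,y point coordinates (metres); points outside the grid are dropped.
#' @param weights per-point non-negative weights (default 1).
#' @param bandwidth Gaussian sigma in metres.
#' @return `raster_grid` of density (weight per square metre).
#' @export
kde_raster <- function(rg, x, y, weights = NULL, bandwidth) {
  stopifnot(bandwidth > 0)
  nr <- rg_nrow(rg); nc <- rg_ncol(rg)
  if (is.null(weights)) weights <- rep(1, length(x))
  stopifnot(length(weights) == length(x), length(x) == length(y))
  acc <- matrix(0, nr, nc)
  cells <- rg_cell_at(rg, x, y)
  ok <- !is.na(cells)
  if (any(ok)) {
    tab <- rowsum(weights[ok], cells[ok])
    acc[as.integer(rownames(tab))] <- tab[, 1]
  }
  sig <- bandwidth / rg$cellsize
  half <- max(1L, ceiling(4 * sig))
  k1 <- dnorm(seq(-half, half), sd = sig) / rg$cellsize # 1-D density per metre
  conv1 <- function(m, along_rows) {
    if (along_rows) m <- t(m)
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (o in seq(-half, half)) {
      src <- seq_len(n) + o
      okk <- src >= 1 & src <= n
      out[okk, ] <- out[okk, ] + k1[o + half + 1] * m[src[okk], ]
    }
    if (along_rows) t(out) else out
  }
  ones <- matrix(1, nr, nc)
  dens <- conv1(conv1(acc, FALSE), TRUE)
  # renormalise by the kernel mass retained on-grid so edge cells are not
  # systematically downweighted (and total mass is conserved)
  den <- conv1(conv1(ones, FALSE), TRUE) * rg$cellsize^2
  dens <- dens / den
  dens[is.na(rg$values)] <- NA
  rg_with_values(rg, dens)
}

#' Rank AUC of positive vs negative scores
#'
#' Mann-Whitney formulation with half credit for ties: the probability that a
#' random positive scores above a random negative.
#'
#' @param pos,neg numeric score vectors (both nonempty).
#' @return AUC in [0, 1].
#' @export
rank_auc <- function(pos, neg) {
  stopifnot(length(pos) > 0, length(neg) > 0)
  r <- rank(c(pos, neg))
  np <- length(pos); nn <- length(neg)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}
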