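#' Georeferenced raster grid
#'
#' A lightweight in-memory raster: a numeric matrix with an affine placement
#' (lower-left corner, square cells) on a local projected plane in metres.
#' Row 1 of the matrix is the northernmost row; `NA` cells are nodata. All
#' spatial layers in the package (covariates, suitability, resistance,
#' current density, priority) are carried by this class.
#'
#' @param values numeric matrix (row 1 = north).
#' @param xmin,ymin coordinates of the lower-left corner of the grid, metres.
#' @param cellsize cell edge length in metres.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, xmin = 0, ymin = 0, cellsize = 30) {
  stopifnot(is.matrix(values), cellsize > 0)
  storage.mode(values) <- "double"
  structure(
    list(values = values, xmin = xmin, ymin = ymin, cellsize = cellsize),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<raster_grid> %d x %d cells, %g m resolution, origin (%g, %g)\n",
    nrow(v), ncol(v), x$cellsize, x$xmin, x$ymin
  ))
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  cat(sprintf("  values: [%g, %g], %d nodata cells\n",
              rng[1], rng[2], sum(is.na(v))))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

rg_nrow <- function(rg) nrow(rg$values)
rg_ncol <- function(rg) ncol(rg$values)
rg_ymax <- function(rg) rg$ymin + rg_nrow(rg) * rg$cellsize

#' Cell-centre coordinates
#'
#' @param rg a `raster_grid`.
#' @param cells linear cell indices (column-major, as in R matrices); default
#'   all cells.
#' @return two-column matrix of x, y cell centres in metres.
#' @export
rg_xy <- function(rg, cells = seq_len(length(rg$values))) {
  nr <- rg_nrow(rg)
  row <- (cells - 1L) %% nr + 1L
  col <- (cells - 1L) %/% nr + 1L
  cbind(
    x = rg$xmin + (col - 0.5) * rg$cellsize,
    y = rg_ymax(rg) - (row - 0.5) * rg$cellsize
  )
}

#' Linear cell index containing each point
#'
#' Points outside the grid get `NA`.
#'
#' @param rg a `raster_grid`.
#' @param x,y point coordinates in metres.
#' @return integer vector of linear (column-major) cell indices.
#' @export
rg_cell_at <- function(rg, x, y) {
  nr <- rg_nrow(rg); nc <- rg_ncol(rg)
  col <- floor((x - rg$xmin) / rg$cellsize) + 1
  row <- floor((rg_ymax(rg) - y) / rg$cellsize) + 1
  # points exactly on the top/right edge belong to the outermost cell
  col[x == rg$xmin + nc * rg$cellsize] <- nc
  row[y == rg$ymin] <- nr
  bad <- col < 1 | col > nc | row < 1 | row > nr
  idx <- (col - 1) * nr + row
  idx[bad] <- NA
  as.integer(idx)
}

rg_same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$xmin, a$ymin, a$cellsize),
                     c(b$xmin, b$ymin, b$cellsize)))
}

stop_if_grid_mismatch <- function(a, b, what = "rasters") {
  if (!rg_same_grid(a, b)) {
    stop(sprintf(
      "%s are not on the same grid: %dx%d @%gm origin(%g,%g) vs %dx%d @%gm origin(%g,%g)",
      what, nrow(a$values), ncol(a$values), a$cellsize, a$xmin, a$ymin,
      nrow(b$values), ncol(b$values), b$cellsize, b$xmin, b$ymin
    ))
  }
  invisible(TRUE)
}

#' Replace the value matrix of a grid, keeping georeferencing
#' @param rg a `raster_grid`.
#' @param values replacement matrix of identical dimensions.
#' @export
rg_with_values <- function(rg, values) {
  stopifnot(identical(dim(values), dim(rg$values)))
  raster_grid(values, rg$xmin, rg$ymin, rg$cellsize)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format readable by all common GIS software.
#' `NA` cells are written as the nodata value.
#'
#' @param rg a `raster_grid`.
#' @param path output file path (conventionally `.asc`).
#' @param nodata numeric nodata sentinel.
#' @export
write_asc <- function(rg, path, nodata = -9999) {
  v <- rg$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", rg$xmin),
    sprintf("yllcorner %.10g", rg$ymin),
    sprintf("cellsize %.10g", rg$cellsize),
    sprintf("NODATA_value %g", nodata)
  ), con)
  write.table(format(v, digits = 17, trim = TRUE, scientific = TRUE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#' @param path file path.
#' @return a `raster_grid` with nodata as `NA`.
#' @export
read_asc <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- tolower(kv[, 1]); val <- as.numeric(kv[, 2])
  names(val) <- key
  nr <- as.integer(val["nrows"]); nc <- as.integer(val["ncols"])
  body <- scan(path, skip = 6, quiet = TRUE)
  if (length(body) != nr * nc) {
    stop(sprintf("malformed ASCII grid '%s': expected %d values, found %d",
                 path, nr * nc, length(body)))
  }
  v <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  v[v == val["nodata_value"]] <- NA
  raster_grid(v, xmin = unname(val["xllcorner"]),
              ymin = unname(val["yllcorner"]),
              cellsize = unname(val["cellsize"]))
}

#' Gaussian smoothing of a raster
#'
#' Separable Gaussian convolution truncated at 4 standard deviations, with
#' renormalisation at the edges and around nodata cells so smoothing does not
#' leak mass off the grid.
#'
#' @param rg a `raster_grid`.
#' @param sigma_cells kernel standard deviation in cells.
#' @return smoothed `raster_grid`.
#' @export
rg_smooth <- function(rg, sigma_cells = 5) {
  v <- rg$values
  na <- is.na(v)
  v0 <- v
  v0[na] <- 0
  w <- matrix(as.numeric(!na), nrow(v), ncol(v))
  half <- max(1L, ceiling(4 * sigma_cells))
  k <- dnorm(seq(-half, half), sd = sigma_cells)
  conv1 <- function(m, along_rows) {
    # pad with zeros and run the 1-D kernel along one dimension
    if (along_rows) m <- t(m)
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (o in seq(-half, half)) {
      src <- seq_len(n) + o
      ok <- src >= 1 & src <= n
      out[ok, ] <- out[ok, ] + k[o + half + 1] * m[src[ok], ]
    }
    if (along_rows) t(out) else out
  }
  num <- conv1(conv1(v0, FALSE), TRUE)
  den <- conv1(conv1(w, FALSE), TRUE)
  s <- num / den
  s[na] <- NA
  rg_with_values(rg, s)
}

#' Euclidean distance to a feature set
#'
#' Exact distance transform: for each cell, the distance in metres to the
#' nearest cell where `feature` is `TRUE` (0 on feature cells).
#'
#' @param rg a `raster_grid` defining the geometry.
#' @param feature logical matrix (same dim) marking feature cells.
#' @return `raster_grid` of distances in metres.
#' @export
rg_distance_to <- function(rg, feature) {
  stopifnot(identical(dim(feature), dim(rg$values)))
  if (!any(feature)) stop("distance transform needs at least one feature cell")
  # EBImage::distmap measures distance to the nearest zero (background) pixel
  img <- matrix(as.numeric(!feature), nrow(feature), ncol(feature))
  d <- EBImage::distmap(img, metric = "euclidean")
  rg_with_values(rg, as.matrix(d) * rg$cellsize)
}

#' Connected-component labelling of a binary raster
#'
#' Breadth-first labelling under 4- or 8-connectivity. Cells that are `FALSE`
#' or `NA` get label 0.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  m <- !is.na(mask) & mask
  lab <- matrix(0L, nr, nc)
  if (connectivity == 4) {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
    dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  }
  nxt <- 0L
  todo <- which(m)
  for (seed in todo) {
    if (lab[seed] != 0L) next
    nxt <- nxt + 1L
    queue <- seed
    lab[seed] <- nxt
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      row <- (cur - 1L) %% nr + 1L
      col <- (cur - 1L) %/% nr + 1L
      for (j in seq_along(dr)) {
        r2 <- row + dr[j]; c2 <- col + dc[j]
        ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
        if (!any(ok)) next
        idx <- (c2[ok] - 1L) * nr + r2[ok]
        idx <- idx[m[idx] & lab[idx] == 0L]
        if (length(idx)) {
          lab[idx] <- nxt
          queue <- c(queue, idx)
        }
      }
      queue <- unique(queue)
    }
  }
  lab
}

# ---- cell-boundary polygon tracing -----------------------------------------

#' Trace the boundary polygon(s) of a set of cells
#'
#' Returns rings traced along cell edges. The outer ring is counter-clockwise;
#' interior holes (if any) are clockwise. Used to export patches, pinch points
#' and overlap areas as standard well-known-text polygons.
#'
#' @param rg a `raster_grid` providing the geometry.
#' @param cells linear cell indices of one connected component.
#' @return list of rings; each ring a 2-column matrix of x,y vertices (closed).
#' @export
trace_boundary <- function(rg, cells) {
  nr <- rg_nrow(rg); nc <- rg_ncol(rg)
  inset <- logical(nr * nc)
  inset[cells] <- TRUE
  cs <- rg$cellsize
  ymax <- rg_ymax(rg)
  row <- (cells - 1L) %% nr + 1L
  col <- (cells - 1L) %/% nr + 1L
  # corner coordinates of a cell: x0 = left, y0 = bottom
  x0 <- rg$xmin + (col - 1L) * cs
  y0 <- ymax - row * cs
  inside <- function(r, c) {
    if (r < 1L || r > nr || c < 1L || c > nc) return(FALSE)
    inset[(c - 1L) * nr + r]
  }
  # collect directed boundary edges keeping the component on the left
  segs <- list()
  add <- function(xa, ya, xb, yb) segs[[length(segs) + 1L]] <<- c(xa, ya, xb, yb)
  for (i in seq_along(cells)) {
    r <- row[i]; c <- col[i]
    xa <- x0[i]; ya <- y0[i]
    if (!inside(r + 1L, c)) add(xa, ya, xa + cs, ya)              # bottom, eastwards
    if (!inside(r, c + 1L)) add(xa + cs, ya, xa + cs, ya + cs)    # right, northwards
    if (!inside(r - 1L, c)) add(xa + cs, ya + cs, xa, ya + cs)    # top, westwards
    if (!inside(r, c - 1L)) add(xa, ya + cs, xa, ya)              # left, southwards
  }
  segm <- do.call(rbind, segs)
  keyf <- function(x, y) paste(round(x / cs, 6), round(y / cs, 6))
  from <- keyf(segm[, 1], segm[, 2])
  # chain directed edges into closed rings; at pinch corners prefer the left turn
  bystart <- split(seq_len(nrow(segm)), from)
  used <- logical(nrow(segm))
  rings <- list()
  for (s in seq_len(nrow(segm))) {
    if (used[s]) next
    ring <- segm[s, 1:2]
    cur <- s
    repeat {
      used[cur] <- TRUE
      nx <- segm[cur, 3]; ny <- segm[cur, 4]
      ring <- rbind(ring, c(nx, ny))
      cand <- bystart[[keyf(nx, ny)]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      if (length(cand) > 1L) {
        # left-most turn relative to current direction keeps rings simple
        dx <- segm[cur, 3] - segm[cur, 1]; dy <- segm[cur, 4] - segm[cur, 2]
        crossv <- (segm[cand, 3] - segm[cand, 1]) * dy -
          (segm[cand, 4] - segm[cand, 2]) * dx
        cand <- cand[order(crossv)][1L]
      }
      cur <- cand[1L]
    }
    rings[[length(rings) + 1L]] <- unname(ring)
  }
  rings
}

ring_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

#' WKT polygon from traced rings
#' @param rings list of closed rings from [trace_boundary()].
#' @return a WKT `POLYGON` string (outer ring first, holes after).
#' @export
rings_to_wkt <- function(rings) {
  areas <- vapply(rings, ring_signed_area, numeric(1))
  ord <- order(-abs(areas))
  rings <- rings[ord]
  fmt <- vapply(rings, function(r) {
    paste0("(", paste(sprintf("%.3f %.3f", r[, 1], r[, 2]), collapse = ", "), ")")
  }, character(1))
  paste0("POLYGON (", paste(fmt, collapse = ", "), ")")
}

#' WKT linestring from a coordinate path
#' @param xy 2-column matrix of vertices.
#' @return a WKT `LINESTRING` string.
#' @export
path_to_wkt <- function(xy) {
  paste0("LINESTRING (",
         paste(sprintf("%.3f %.3f", xy[, 1], xy[, 2]), collapse = ", "), ")")
}
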