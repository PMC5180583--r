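# Artifact removal: pollen grains and debris are segmented inside each
# marked region by local-mean adaptive thresholding, labelled (8-connected),
# measured (area, boundary-trace perimeter, circularity), and deleted when
# small or near-circular. Deleted pixels are excluded from the entropy
# filter and from region statistics.

#' Convert an RGB image to 8-bit luminance
#'
#' Rec. 601 weighting: `0.299 R + 0.587 G + 0.114 B`, rounded to the
#' nearest integer.
#'
#' @param rgb numeric or integer array `height x width x 3` with values in
#'   \[0, 255\].
#' @return Integer `height x width` matrix in \[0, 255\].
#' @examples
#' toLuminance(array(c(255, 0, 0), c(1, 1, 3)))  # 76
#' @export
toLuminance <- function(rgb) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stop("'rgb' must be a height x width x 3 array")
  y <- 0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
  m <- matrix(as.integer(round(y)), dim(rgb)[1], dim(rgb)[2])
  m
}

# w x w box sums via an integral image (zero padding outside the matrix)
boxSum <- function(m, w) {
  p <- (w - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  padded <- matrix(0, nr + 2L * p, nc + 2L * p)
  padded[p + seq_len(nr), p + seq_len(nc)] <- m
  ii <- rbind(0, apply(padded, 2, cumsum))
  ii <- cbind(0, t(apply(ii, 1, cumsum)))
  r1 <- seq_len(nr); c1 <- seq_len(nc)
  ii[r1 + w, c1 + w, drop = FALSE] - ii[r1, c1 + w, drop = FALSE] -
    ii[r1 + w, c1, drop = FALSE] + ii[r1, c1, drop = FALSE]
}

# mean of gray over the in-region pixels of the w x w window at every pixel;
# pixels outside the marked region do not influence the threshold inside it
localMean <- function(gray, regionMask, w) {
  num <- boxSum(gray * regionMask, w)
  den <- boxSum(regionMask * 1, w)
  mu <- num / pmax(den, 1)
  mu[den == 0] <- NA_real_
  mu
}

#' Spatially adaptive (local-mean) thresholding
#'
#' Segments artifact candidates inside a region: a pixel is foreground iff
#' it lies inside `regionMask` and its value exceeds (`polarity = "bright"`)
#' or falls below (`polarity = "dark"`) `thresholdSensitivity` times the
#' mean gray value over the in-region pixels of its square
#' `thresholdWindow` neighbourhood; `polarity = "both"` takes the union.
#' Restricting the local mean to the marked region keeps image content
#' outside the region (e.g. the white card background) from setting the
#' threshold just inside its border.
#'
#' @param gray integer matrix in \[0, 255\] (see [toLuminance()]).
#' @param regionMask logical matrix delimiting the region to segment.
#' @param cfg a [PreprocessConfig-class].
#' @return Logical foreground-candidate matrix.
#' @export
adaptiveThreshold <- function(gray, regionMask, cfg = preprocessConfig()) {
  stopifnot(is(cfg, "PreprocessConfig"))
  if (!identical(dim(gray), dim(regionMask)))
    stop("'gray' and 'regionMask' dimensions differ")
  w <- cfg@thresholdWindow
  if (w > min(dim(gray)))
    stop("threshold window (", w, " px) larger than the image")
  mu <- localMean(gray, regionMask, w)
  s <- cfg@thresholdSensitivity
  fg <- switch(cfg@polarity,
               bright = gray > s * mu,
               dark   = gray < s * mu,
               both   = (gray > s * mu) | (gray < s * mu))
  fg[is.na(fg)] <- FALSE
  fg & regionMask
}

#' Label connected foreground objects
#'
#' 8-connected component labelling followed by per-object measurement:
#' area (pixel count), perimeter (closed Moore boundary trace, accumulated
#' centre-to-centre distance) and circularity
#' \eqn{S = 4\pi \cdot Area / Perimeter^2} (NA for single-pixel objects,
#' whose perimeter is 0).
#'
#' @param mask logical matrix of foreground candidates.
#' @return A [LabeledObjects-class].
#' @export
labelObjects <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  lab <- label8_cpp(mask)
  k <- max(lab)
  if (k == 0L) {
    return(new("LabeledObjects", labelImage = lab,
               objects = data.frame(object = integer(0), area = integer(0),
                                    perimeter = numeric(0),
                                    circularity = numeric(0))))
  }
  areas <- tabulate(lab[lab > 0L], nbins = k)
  perim <- numeric(k)
  rows <- row(lab); cols <- col(lab)
  for (o in seq_len(k)) {
    sel <- lab == o
    r <- range(rows[sel]); c <- range(cols[sel])
    sub <- lab[r[1]:r[2], c[1]:c[2], drop = FALSE] == o
    perim[o] <- tracePerimeter(sub)
  }
  circ <- ifelse(perim > 0, 4 * pi * areas / perim^2, NA_real_)
  new("LabeledObjects", labelImage = lab,
      objects = data.frame(object = seq_len(k), area = areas,
                           perimeter = perim, circularity = circ))
}

# Moore-neighbour boundary trace of a single-component mask; returns the
# accumulated centre-to-centre distance of the closed outer boundary walk
# (1 per axis step, sqrt(2) per diagonal step). Single pixel -> 0.
tracePerimeter <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  # clockwise Moore neighbourhood starting at W (dr, dc)
  dirs <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
                c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  at <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c]
  # start: first foreground pixel in row-major scan (its W and N are bg)
  start <- NULL
  for (r in seq_len(nr)) {
    hit <- which(mask[r, ])
    if (length(hit)) { start <- c(r, hit[1]); break }
  }
  p <- start
  b <- 1L  # direction of the backtrack pixel relative to p (index into dirs)
  path <- list(start)
  firstMove <- NULL
  maxSteps <- 4L * sum(mask) + 8L
  for (step in seq_len(maxSteps)) {
    found <- FALSE
    for (t in seq_len(8L)) {
      d <- (b - 1L + t - 1L) %% 8L + 1L  # clockwise from the backtrack
      q <- p + dirs[d, ]
      if (at(q[1], q[2])) {
        # new backtrack: the neighbour examined just before q
        bd <- (d - 2L) %% 8L + 1L
        bpix <- p + dirs[bd, ]
        p <- q
        # direction index of bpix relative to new p
        rel <- bpix - p
        b <- which(dirs[, 1] == rel[1] & dirs[, 2] == rel[2])
        found <- TRUE
        break
      }
    }
    if (!found) return(0)  # isolated single pixel
    path[[length(path) + 1L]] <- p
    k <- length(path)
    if (is.null(firstMove)) {
      firstMove <- c(path[[1]], path[[2]])
    } else if (identical(c(path[[k - 1L]], path[[k]]), firstMove) && k > 2L) {
      # pair (start, second) re-entered: closed cycle is path[1..k-1]
      pts <- do.call(rbind, path[seq_len(k - 1L)])
      d <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                           pts[-nrow(pts), , drop = FALSE])^2))
      return(sum(d))
    }
  }
  stop("boundary trace failed to close; is the mask a single component?")
}

#' Perimeter of a single binary object
#'
#' Closed Moore boundary trace of the outer border; the perimeter is the
#' accumulated distance from pixel centre to pixel centre along the border
#' (1 per horizontal/vertical step, sqrt(2) per diagonal step), rather than
#' a count of border pixels. A single-pixel object has perimeter 0.
#'
#' @param mask logical matrix holding exactly one 8-connected object.
#' @return Perimeter in pixels.
#' @examples
#' objectPerimeter(matrix(TRUE, 3, 3))  # 8
#' @export
objectPerimeter <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask), any(mask))
  if (max(label8_cpp(mask)) > 1L)
    stop("'mask' must hold a single 8-connected object")
  tracePerimeter(mask)
}

#' Circularity of an object
#'
#' \eqn{S = 4\pi \cdot Area / Perimeter^2}: 1 for a continuum circle,
#' larger for compact digitized blobs, much smaller for elongated objects.
#'
#' @param area object area in pixels.
#' @param perimeter object perimeter in pixels (must be > 0).
#' @return The circularity coefficient S.
#' @examples
#' circularity(9, 8)  # 3x3 square: 36 * pi / 64
#' @export
circularity <- function(area, perimeter) {
  if (any(perimeter <= 0))
    stop("circularity is undefined for perimeter 0; remove such objects ",
         "by area first")
  4 * pi * area / perimeter^2
}

#' Decide which objects to delete and build the exclusion mask
#'
#' An object is deleted iff its area is below `minArea` or it is
#' near-circular: \eqn{S \ge 1 -} `circTol` (pollen grains are round).
#' The circularity bound is one-sided: on a pixel grid the boundary walk
#' of a round blob is shorter than the continuum circumference, so
#' digitized disks carry S at and slightly above 1, while hairs and other
#' elongated structures sit far below. Pixels of deleted objects are set
#' `TRUE` in the returned exclusion mask. With `cfg@enabled == FALSE`
#' nothing is excluded.
#'
#' @param objs a [LabeledObjects-class].
#' @param cfg a [PreprocessConfig-class].
#' @return Logical exclusion matrix (`TRUE` = deleted) with attribute
#'   `"objects"`: the object table plus a `deleted` flag column.
#' @export
filterObjects <- function(objs, cfg = preprocessConfig()) {
  stopifnot(is(objs, "LabeledObjects"), is(cfg, "PreprocessConfig"))
  tab <- objs@objects
  if (!cfg@enabled || nrow(tab) == 0L) {
    excl <- matrix(FALSE, nrow(objs@labelImage), ncol(objs@labelImage))
    tab$deleted <- logical(nrow(tab))
    attr(excl, "objects") <- tab
    return(excl)
  }
  tab$deleted <- tab$area < cfg@minArea |
    (!is.na(tab$circularity) & tab$circularity >= 1 - cfg@circTol)
  excl <- matrix(objs@labelImage %in% tab$object[tab$deleted],
                 nrow(objs@labelImage), ncol(objs@labelImage))
  attr(excl, "objects") <- tab
  excl
}

#' Pre-process one region: segment and delete artifacts
#'
#' Composition of the artifact-removal stages for a single marked region:
#' luminance conversion, local-mean adaptive thresholding inside the
#' region, 8-connected labelling with perimeter/circularity measurement,
#' and deletion of small or near-circular objects.
#'
#' @param rgb `height x width x 3` array in \[0, 255\].
#' @param regionMask logical region membership matrix (see
#'   [rasterizeRoi()]).
#' @param cfg a [PreprocessConfig-class]; with `enabled = FALSE` the
#'   result is all-`FALSE` regardless of image content.
#' @return Logical exclusion mask (`TRUE` = deleted pixel), with the
#'   per-object table as attribute `"objects"`.
#' @export
preprocessRegion <- function(rgb, regionMask, cfg = preprocessConfig()) {
  stopifnot(is(cfg, "PreprocessConfig"))
  if (!identical(dim(rgb)[1:2], dim(regionMask)))
    stop("image and region mask dimensions differ")
  if (!cfg@enabled) {
    excl <- matrix(FALSE, nrow(regionMask), ncol(regionMask))
    attr(excl, "objects") <-
      data.frame(object = integer(0), area = integer(0),
                 perimeter = numeric(0), circularity = numeric(0),
                 deleted = logical(0))
    return(excl)
  }
  gray <- toLuminance(rgb)
  fg <- adaptiveThreshold(gray, regionMask, cfg)
  filterObjects(labelObjects(fg), cfg)
}
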