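# The hairiness measurement: per-channel local Shannon entropy over a
# disk-shaped radius of influence, multiplicative channel combination, and
# per-region summary statistics.

#' Disk structuring element offsets
#'
#' The exact Euclidean disk of lattice displacements
#' \eqn{\{(di, dj): di^2 + dj^2 \le r^2\}}. At the default radius of
#' influence r = 7 this holds 149 offsets.
#'
#' @param r integer radius of influence in pixels (>= 0).
#' @return A [StructuringElement-class].
#' @examples
#' nrow(seOffsets(diskOffsets(1)))  # 5: the von Neumann cross
#' nrow(seOffsets(diskOffsets(7)))  # 149
#' @export
diskOffsets <- function(r = 7L) {
  if (length(r) != 1L || !is.finite(r) || r < 0 || r != floor(r))
    stop("'r' must be a single non-negative integer")
  r <- as.integer(r)
  g <- expand.grid(di = -r:r, dj = -r:r)
  g <- g[g$di^2 + g$dj^2 <= r^2, , drop = FALSE]
  offs <- as.matrix(g)
  dimnames(offs) <- NULL
  storage.mode(offs) <- "integer"
  new("StructuringElement", radius = r, offsets = offs)
}

# coerce a channel to an integer matrix in [0, 255]; 16-bit inputs are
# min-max rescaled with a warning
asChannel256 <- function(channel) {
  m <- as.matrix(channel)
  if (any(!is.finite(m))) stop("channel holds non-finite values")
  if (max(m) > 255) {
    warning("channel values exceed 255; min-max rescaling to 8 bits",
            call. = FALSE)
    m <- (m - min(m)) / max(max(m) - min(m), 1) * 255
  }
  m <- round(m)
  storage.mode(m) <- "integer"
  m
}

#' Local Shannon entropy of one channel
#'
#' For every pixel, the 256-bin histogram of the 8-bit channel values over
#' its structuring-element neighbourhood (mirror padding at the image
#' border) is normalized to a probability vector and its Shannon entropy
#' \eqn{H = -\sum p \log_2 p} (with \eqn{0 \log_2 0 := 0}) is returned, in
#' bits. Pixels flagged in `excl` are dropped from every histogram; an
#' excluded centre pixel (or one whose whole neighbourhood is excluded)
#' gets entropy 0.
#'
#' @param channel integer matrix in \[0, 255\].
#' @param se a [StructuringElement-class] (default disk of radius 7).
#' @param excl optional logical exclusion matrix (`TRUE` = deleted).
#' @return Numeric matrix of entropies, bounded by
#'   \eqn{\log_2(\min(256, |SE|))}.
#' @examples
#' h <- localEntropy(matrix(128L, 16, 16))
#' all(h == 0)  # constant image carries no local information
#' @export
localEntropy <- function(channel, se = diskOffsets(7L), excl = NULL) {
  stopifnot(is(se, "StructuringElement"))
  m <- asChannel256(channel)
  if (is.null(excl)) excl <- matrix(FALSE, nrow(m), ncol(m))
  if (!identical(dim(m), dim(excl)))
    stop("channel and exclusion mask dimensions differ")
  local_entropy_cpp(m, se@offsets, excl)
}

#' Combine channel entropy layers
#'
#' The combined entropy image is the per-pixel product of the three
#' channel entropy layers, \eqn{E_S = E_R \cdot E_G \cdot E_B}. Excluded
#' pixels are invalid and carry \eqn{E_S = 0}.
#'
#' @param er,eg,eb numeric entropy matrices of equal dimension (bits).
#' @param excl optional logical exclusion matrix.
#' @return An [EntropyImage-class].
#' @export
combineChannels <- function(er, eg, eb, excl = NULL) {
  if (!identical(dim(er), dim(eg)) || !identical(dim(er), dim(eb)))
    stop("channel entropy layer dimensions differ")
  if (is.null(excl)) excl <- matrix(FALSE, nrow(er), ncol(er))
  if (!identical(dim(er), dim(excl)))
    stop("exclusion mask dimensions differ from the entropy layers")
  es <- er * eg * eb
  es[excl] <- 0
  new("EntropyImage", es = es, valid = !excl)
}

#' Summarize combined entropy within one region
#'
#' Mean and sample standard deviation (n - 1 denominator) of \eqn{E_S}
#' over the pixels that are inside the region and valid (not deleted by
#' pre-processing).
#'
#' @param ei an [EntropyImage-class].
#' @param regionMask logical region membership matrix.
#' @param imageId image file stem for the output row.
#' @param label region label for the output row.
#' @return One-row data.frame: `image_id`, `region`, `mean_es`, `sd_es`,
#'   `n_valid`.
#' @export
regionSummary <- function(ei, regionMask, imageId, label) {
  stopifnot(is(ei, "EntropyImage"))
  if (!identical(dim(ei@es), dim(regionMask)))
    stop("entropy image and region mask dimensions differ")
  sel <- regionMask & ei@valid
  n <- sum(sel)
  if (n < 1L)
    stop("region '", label, "' has no valid pixels")
  v <- ei@es[sel]
  data.frame(image_id = as.character(imageId),
             region = as.character(label),
             mean_es = mean(v),
             sd_es = if (n > 1L) sd(v) else 0,
             n_valid = n,
             stringsAsFactors = FALSE)
}

# bounding box of a mask, dilated by `pad` px and clamped to the image
dilatedBBox <- function(mask, pad) {
  r <- range(row(mask)[mask]); c <- range(col(mask)[mask])
  list(r = max(1L, r[1] - pad):min(nrow(mask), r[2] + pad),
       c = max(1L, c[1] - pad):min(ncol(mask), c[2] + pad))
}

#' Measure hairiness of every region of one image
#'
#' The full imaging pipeline for one photograph: each region is rasterized,
#' pre-processing deletes pollen-like artifacts inside it (unless
#' disabled), local entropy is computed per colour channel over the
#' region's bounding box dilated by the radius of influence (values equal
#' the whole-image computation for in-region pixels), channels are
#' combined multiplicatively, and the mean and standard deviation of
#' \eqn{E_S} over valid in-region pixels are reported.
#'
#' @param rgb `height x width x 3` array in \[0, 255\], or a file path
#'   readable by [readImageRGB()].
#' @param roiset a [RoISet-class] matching the image dimensions.
#' @param cfg a [PreprocessConfig-class].
#' @param r radius of influence in pixels (default 7).
#' @return data.frame with one row per region (see [regionSummary()]),
#'   plus an `n_excluded` column counting deleted pixels per region.
#' @examples
#' spec <- makeSpecimen(list(face = 0.5, thorax_dorsal = 0.1), seed = 1,
#'                      patchSize = c(48, 48))
#' measureImage(spec$rgb, spec$roiset)
#' @export
measureImage <- function(rgb, roiset, cfg = preprocessConfig(), r = 7L) {
  if (is.character(rgb)) rgb <- readImageRGB(rgb)
  stopifnot(is(roiset, "RoISet"))
  dims <- dim(rgb)
  if (dims[1] != roiset@imageHeight || dims[2] != roiset@imageWidth)
    stop(sprintf("image is %d x %d px but RoISet '%s' records %d x %d",
                 dims[2], dims[1], roiset@imageId, roiset@imageWidth,
                 roiset@imageHeight))
  se <- diskOffsets(r)
  pad <- max(as.integer(r), (cfg@thresholdWindow - 1L) %/% 2L)
  out <- vector("list", length(roiset@regions))
  for (i in seq_along(roiset@regions)) {
    roi <- roiset@regions[[i]]
    mask <- rasterizeRoi(roi, dims[2], dims[1])
    if (!any(mask))
      stop("region '", roi@label, "' rasterizes to zero pixels")
    bb <- dilatedBBox(mask, pad)
    sub <- rgb[bb$r, bb$c, , drop = FALSE]
    subMask <- mask[bb$r, bb$c, drop = FALSE]
    excl <- preprocessRegion(sub, subMask, cfg)
    layers <- lapply(1:3, function(ch)
      localEntropy(sub[, , ch], se, excl))
    ei <- combineChannels(layers[[1]], layers[[2]], layers[[3]], excl)
    row <- regionSummary(ei, subMask, roiset@imageId, roi@label)
    row$n_excluded <- sum(excl & subMask)
    out[[i]] <- row
  }
  do.call(rbind, out)
}

#' Read an image file as an 8-bit RGB array
#'
#' JPEG/PNG/TIFF are read via EBImage; grayscale images are replicated to
#' three identical channels; an alpha channel, if present, is dropped.
#'
#' @param path image file path.
#' @return Integer `height x width x 3` array with values in \[0, 255\].
#' @export
readImageRGB <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  a <- if (length(d) == 2L) {
    array(img, c(d[1], d[2], 3L))
  } else {
    img[, , 1:min(3L, d[3]), drop = FALSE]
  }
  if (dim(a)[3] == 1L) a <- array(a[, , 1], c(d[1], d[2], 3L))
  if (dim(a)[3] == 2L) a <- array(a[, , 1], c(d[1], d[2], 3L))  # gray+alpha
  out <- aperm(a, c(2, 1, 3))  # EBImage stores x, y; we use row = y
  out <- round(out * 255)
  storage.mode(out) <- "integer"
  out
}

#' Write a wide summary CSV, one row per image
#'
#' Columns: `image_id`, then `<label>_mean`, `<label>_sd`,
#' `<label>_n_valid` for every region label present in `rows` (canonical
#' labels first, in canonical order). Regions absent on an image give
#' empty cells.
#'
#' @param rows data.frame of region summaries as produced by
#'   [measureImage()] (rows from several images may be concatenated).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSummariesCsv <- function(rows, path) {
  stopifnot(all(c("image_id", "region", "mean_es", "sd_es", "n_valid")
                %in% names(rows)))
  labs <- unique(rows$region)
  labs <- c(intersect(canonicalRegions(), labs),
            sort(setdiff(labs, canonicalRegions())))
  ids <- unique(rows$image_id)
  wide <- data.frame(image_id = ids, stringsAsFactors = FALSE)
  for (lb in labs) {
    for (stat in c("mean", "sd", "n_valid")) {
      col <- paste0(lb, "_", stat)
      src <- c(mean = "mean_es", sd = "sd_es", n_valid = "n_valid")[[stat]]
      wide[[col]] <- vapply(ids, function(id) {
        hit <- rows$region == lb & rows$image_id == id
        if (any(hit)) rows[[src]][which(hit)[1]] else NA_real_
      }, numeric(1))
    }
  }
  utils::write.csv(wide, path, row.names = FALSE, na = "")
  invisible(path)
}
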