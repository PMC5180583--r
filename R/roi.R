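# Region-of-interest persistence, validation and rasterization.
#
# RoI sidecar schema (one JSON file per image, named <image_id>.rois.json):
# {"image_id": str, "image_width": int, "image_height": int,
#  "regions": [{"label": str, "vertices": [[x, y], ...]}]}

#' Load a region-of-interest set from a JSON sidecar file
#'
#' @param path path to a `<image_id>.rois.json` file.
#' @return A validated [RoISet-class]; region labels are normalized to
#'   lower_snake_case. Validation findings (out-of-bounds vertices, more
#'   than four regions, duplicate labels) are raised as warnings.
#' @seealso [saveRoiSet()], [validateRoiSet()]
#' @examples
#' rs <- RoISet("ex", 32, 32,
#'              list(PolygonRoI("face", rbind(c(1, 1), c(10, 1), c(1, 10)))))
#' f <- file.path(tempdir(), "ex.rois.json")
#' saveRoiSet(rs, f)
#' identical(roiVertices(regions(loadRoiSet(f))[[1]]),
#'           roiVertices(regions(rs)[[1]]))
#' @export
loadRoiSet <- function(path) {
  if (!file.exists(path)) stop("RoI file does not exist: ", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("malformed RoI JSON in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  for (key in c("image_id", "image_width", "image_height", "regions"))
    if (is.null(doc[[key]]))
      stop("malformed RoI JSON in '", path, "': missing key '", key, "'")
  regs <- lapply(doc$regions, function(r) {
    if (is.null(r$label))
      stop("malformed RoI JSON in '", path, "': region missing key 'label'")
    if (is.null(r$vertices) || length(r$vertices) < 3L)
      stop("region '", r$label, "' has fewer than 3 vertices")
    v <- do.call(rbind, lapply(r$vertices, function(p) {
      if (length(p) != 2L)
        stop("region '", r$label, "': each vertex must be an [x, y] pair")
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))
    }))
    PolygonRoI(r$label, v)
  })
  RoISet(doc$image_id, doc$image_width, doc$image_height, regs)
}

#' Save a region-of-interest set as a JSON sidecar file
#'
#' Writes the documented JSON schema; `loadRoiSet(saveRoiSet(rs))` is the
#' identity (vertex coordinates round-trip bit-identically). A warning is
#' issued when the set holds more than four regions, the number the
#' original interactive workflow anticipated; more are allowed.
#'
#' @param rs a [RoISet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
saveRoiSet <- function(rs, path) {
  stopifnot(is(rs, "RoISet"))
  validObject(rs)
  if (length(rs@regions) > 4L)
    warning("RoISet '", rs@imageId, "' holds ", length(rs@regions),
            " regions; typical workflows mark up to four", call. = FALSE)
  doc <- list(
    image_id = rs@imageId,
    image_width = rs@imageWidth,
    image_height = rs@imageHeight,
    regions = lapply(rs@regions, function(r) list(
      label = r@label,
      vertices = lapply(seq_len(nrow(r@vertices)),
                        function(i) as.numeric(r@vertices[i, ]))
    ))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rasterize a polygon onto a pixel grid
#'
#' A pixel belongs to the region iff its centre lies strictly inside the
#' polygon under the even-odd rule; centres exactly on the boundary count
#' as outside. With the top-left origin convention, the centre of matrix
#' cell `[r, c]` (1-based) is `(x, y) = (c - 0.5, r - 0.5)`.
#'
#' @param roi a [PolygonRoI-class].
#' @param width,height pixel dimensions of the target grid.
#' @return Logical `height` x `width` matrix (`TRUE` = inside).
#' @examples
#' m <- rasterizeRoi(PolygonRoI("t", rbind(c(0, 0), c(4, 0), c(0, 4))), 4, 4)
#' sum(m)  # 6 pixel centres satisfy x + y < 4
#' @export
rasterizeRoi <- function(roi, width, height) {
  stopifnot(is(roi, "PolygonRoI"))
  validObject(roi)
  width <- as.integer(width); height <- as.integer(height)
  v <- roi@vertices
  n <- nrow(v)
  xs <- seq_len(width) - 0.5
  ys <- seq_len(height) - 0.5
  crossings <- matrix(0L, height, width)
  onEdge <- matrix(FALSE, height, width)
  eps <- 1e-9
  for (e in seq_len(n)) {
    x1 <- v[e, 1]; y1 <- v[e, 2]
    x2 <- v[e %% n + 1L, 1]; y2 <- v[e %% n + 1L, 2]
    # horizontal-ray crossing count (even-odd rule)
    straddle <- (y1 > ys) != (y2 > ys)
    if (any(straddle)) {
      xint <- x1 + (ys[straddle] - y1) * (x2 - x1) / (y2 - y1)
      crossings[straddle, ] <- crossings[straddle, ] +
        outer(xint, xs, function(a, b) as.integer(b < a))
    }
    # exact-boundary centres -> outside
    ex <- x2 - x1; ey <- y2 - y1
    len2 <- ex * ex + ey * ey
    t <- (outer(-y1 + ys, rep(ey, width)) +
            matrix((xs - x1) * ex, height, width, byrow = TRUE)) / len2
    px <- matrix(xs, height, width, byrow = TRUE)
    py <- matrix(ys, height, width)
    tc <- pmin(pmax(t, 0), 1)
    d2 <- (px - (x1 + tc * ex))^2 + (py - (y1 + tc * ey))^2
    onEdge <- onEdge | (d2 < eps)
  }
  (crossings %% 2L == 1L) & !onEdge
}

#' Validate a region-of-interest set against image dimensions
#'
#' Checks that all vertices fall within the image bounds (with a 0.5 px
#' clamping tolerance), that at most four regions are marked, and that
#' region labels are unique. Never modifies `rs`.
#'
#' @param rs a [RoISet-class].
#' @param imageWidth,imageHeight image dimensions in pixels; default the
#'   dimensions recorded in `rs`.
#' @return Character vector of warning messages (empty when all checks
#'   pass).
#' @export
validateRoiSet <- function(rs, imageWidth = NULL, imageHeight = NULL) {
  stopifnot(is(rs, "RoISet"))
  w <- if (is.null(imageWidth)) rs@imageWidth else as.numeric(imageWidth)
  h <- if (is.null(imageHeight)) rs@imageHeight else as.numeric(imageHeight)
  out <- character(0)
  tol <- 0.5
  for (r in rs@regions) {
    v <- r@vertices
    if (any(v[, 1] < -tol | v[, 1] > w + tol |
            v[, 2] < -tol | v[, 2] > h + tol))
      out <- c(out, sprintf(
        "region '%s' has vertices outside the %g x %g image bounds",
        r@label, w, h))
  }
  if (length(rs@regions) > 4L)
    out <- c(out, sprintf("%d regions marked; typical workflows use up to 4",
                          length(rs@regions)))
  labs <- vapply(rs@regions, roiLabel, character(1))
  dup <- unique(labs[duplicated(labs)])
  if (length(dup))
    out <- c(out, sprintf("duplicate region label(s): %s",
                          paste(dup, collapse = ", ")))
  out
}
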