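# Synthetic specimens and trait tables with known ground truth. The
# generator emulates the photographic situation the imaging pipeline is
# built for: an amber, mid-tone cuticle carrying darker hairs (anti-aliased
# strokes 3.5-4.5 px wide, the hair thickness range typical at the imaging
# scale), bright near-circular pollen contaminants, and species-level trait
# tables in which a known predictor subset drives the response.

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Hair texture parameters
#'
#' @param hairDensity target areal coverage fraction of hair strokes in
#'   \[0, 1\] (sum of stroke areas over patch area; strokes may overlap).
#' @param hairWidth range (min, max) of stroke widths in px; default
#'   3.5-4.5, the typical imaged hair thickness.
#' @param hairLength range of stroke lengths in px.
#' @param baseColor,hairColor RGB triples in \[0, 255\]; defaults emulate
#'   amber cuticle with darker hairs.
#' @param hairToneJitter half-range (gray levels) of the uniform
#'   per-stroke brightness variation around `hairColor`; hairs in real
#'   photographs differ in lightness with depth and inclination.
#' @param noiseSd standard deviation of additive Gaussian pixel noise
#'   (gray levels, per channel).
#' @param seed integer RNG seed; every generator here is a pure function
#'   of its parameters and seed.
#' @return List of class `"textureParams"`.
#' @export
textureParams <- function(hairDensity = 0.5, hairWidth = c(3.5, 4.5),
                          hairLength = c(15, 35),
                          baseColor = c(150, 110, 70),
                          hairColor = c(70, 50, 35),
                          hairToneJitter = 25, noiseSd = 4, seed = 1L) {
  stopifnot(hairDensity >= 0, all(hairWidth > 0), all(hairLength > 0),
            noiseSd >= 0, hairToneJitter >= 0,
            length(baseColor) == 3L, length(hairColor) == 3L)
  structure(list(hairDensity = hairDensity, hairWidth = sort(hairWidth),
                 hairLength = sort(hairLength), baseColor = baseColor,
                 hairColor = hairColor, hairToneJitter = hairToneJitter,
                 noiseSd = noiseSd, seed = as.integer(seed)),
            class = "textureParams")
}

# pixel-centre coverage of an anti-aliased capsule (stroke) or disk within
# its bounding box; NULL when the capsule misses the image
capsuleCoverage <- function(h, w, x1, y1, x2, y2, halfw) {
  r0 <- max(1L, floor(min(y1, y2) - halfw - 1))
  r1 <- min(h, ceiling(max(y1, y2) + halfw + 2))
  c0 <- max(1L, floor(min(x1, x2) - halfw - 1))
  c1 <- min(w, ceiling(max(x1, x2) + halfw + 2))
  if (r0 > r1 || c0 > c1) return(NULL)
  rows <- r0:r1; cols <- c0:c1
  px <- matrix(cols - 0.5, length(rows), length(cols), byrow = TRUE)
  py <- matrix(rows - 0.5, length(rows), length(cols))
  ex <- x2 - x1; ey <- y2 - y1
  len2 <- ex * ex + ey * ey
  t <- if (len2 > 0) pmin(pmax(((px - x1) * ex + (py - y1) * ey) / len2, 0), 1)
       else 0
  d <- sqrt((px - (x1 + t * ex))^2 + (py - (y1 + t * ey))^2)
  list(rows = rows, cols = cols,
       cov = pmin(pmax(halfw + 0.5 - d, 0), 1))
}

#' Generate a hairy texture patch
#'
#' A constant base-colour field overlaid with a Poisson number of straight
#' anti-aliased hair strokes of random position, orientation, length and
#' width, plus additive Gaussian noise clipped to 8 bits. The expected
#' stroke count is `hairDensity * width * height / meanStrokeArea`.
#'
#' @param width,height patch dimensions in px.
#' @param params a [textureParams()].
#' @return Integer `height x width x 3` array in \[0, 255\], fully
#'   determined by `params` (including its seed).
#' @examples
#' p <- makeHairyPatch(48, 48, textureParams(hairDensity = 0, noiseSd = 0))
#' length(unique(as.vector(p)))  # 3: one constant value per channel
#' @export
makeHairyPatch <- function(width, height, params = textureParams()) {
  stopifnot(inherits(params, "textureParams"))
  withSeed(params$seed, {
    img <- array(0, c(height, width, 3L))
    for (ch in 1:3) img[, , ch] <- params$baseColor[ch]
    meanArea <- mean(params$hairWidth) * mean(params$hairLength)
    lambda <- params$hairDensity * width * height / meanArea
    n <- if (lambda > 0) rpois(1L, lambda) else 0L
    for (i in seq_len(n)) {
      cx <- runif(1, 0, width); cy <- runif(1, 0, height)
      ang <- runif(1, 0, pi)
      len <- runif(1, params$hairLength[1], params$hairLength[2])
      hw <- runif(1, params$hairWidth[1], params$hairWidth[2]) / 2
      tone <- runif(1, -params$hairToneJitter, params$hairToneJitter)
      dx <- cos(ang) * len / 2; dy <- sin(ang) * len / 2
      cap <- capsuleCoverage(height, width, cx - dx, cy - dy,
                             cx + dx, cy + dy, hw)
      if (is.null(cap)) next
      for (ch in 1:3) {
        col <- params$hairColor[ch] + tone
        img[cap$rows, cap$cols, ch] <-
          img[cap$rows, cap$cols, ch] * (1 - cap$cov) + col * cap$cov
      }
    }
    if (params$noiseSd > 0)
      img <- img + rnorm(length(img), sd = params$noiseSd)
    img <- round(pmin(pmax(img, 0), 255))
    storage.mode(img) <- "integer"
    img
  })
}

#' Inject pollen-like circular contaminants
#'
#' Draws `n` filled anti-aliased disks of bright pollen colour at uniform
#' random positions (kept clear of the image border and of each other, so
#' each contaminant is an isolated near-circular object) and returns the
#' ground-truth circle list.
#'
#' @param rgb `height x width x 3` array in \[0, 255\].
#' @param n number of disks.
#' @param radiusRange (min, max) disk radius in px (radii must be >= 2);
#'   the default 3-4.5 px reflects the size uniformity of pollen of a
#'   single plant species at typical imaging scales.
#' @param color RGB triple; default bright pollen yellow.
#' @param seed integer RNG seed.
#' @param regionMask optional logical matrix; centres are drawn inside it.
#' @return List: `rgb` (contaminated image) and `circles`, a data.frame
#'   of (`x`, `y`, `radius`) exactly as drawn (0-based continuous
#'   coordinates, as for RoI vertices).
#' @export
addPollenArtifacts <- function(rgb, n, radiusRange = c(3, 4.5),
                               color = c(250, 230, 110), seed = 1L,
                               regionMask = NULL) {
  stopifnot(all(radiusRange >= 2), length(dim(rgb)) == 3L)
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  if (n == 0L)
    return(list(rgb = rgb, circles = data.frame(x = numeric(0),
                                                y = numeric(0),
                                                radius = numeric(0))))
  withSeed(seed, {
    rmax <- max(radiusRange)
    minSep <- 2 * rmax + 3
    xs <- numeric(0); ys <- numeric(0); rs <- numeric(0)
    tries <- 0L
    while (length(xs) < n && tries < 2000L) {
      tries <- tries + 1L
      x <- runif(1, rmax + 2, w - rmax - 2)
      y <- runif(1, rmax + 2, h - rmax - 2)
      if (!is.null(regionMask) &&
          !regionMask[pmin(pmax(ceiling(y), 1), h),
                      pmin(pmax(ceiling(x), 1), w)]) next
      if (length(xs) && min(sqrt((xs - x)^2 + (ys - y)^2)) < minSep) next
      xs <- c(xs, x); ys <- c(ys, y)
      rs <- c(rs, runif(1, radiusRange[1], radiusRange[2]))
    }
    if (length(xs) < n)
      stop("could not place ", n, " non-overlapping contaminants")
    for (i in seq_len(n)) {
      cap <- capsuleCoverage(h, w, xs[i], ys[i], xs[i], ys[i], rs[i])
      for (ch in 1:3)
        rgb[cap$rows, cap$cols, ch] <-
          rgb[cap$rows, cap$cols, ch] * (1 - cap$cov) + color[ch] * cap$cov
    }
    rgb <- round(pmin(pmax(rgb, 0), 255))
    storage.mode(rgb) <- "integer"
    list(rgb = rgb, circles = data.frame(x = xs, y = ys, radius = rs))
  })
}

#' Compose a synthetic specimen image with marked regions
#'
#' Lays out one hairy rectangular patch per requested region on a plain
#' white background (regions kept >= 16 px from the image border and from
#' each other) and returns the image together with its [RoISet-class] and
#' the per-region true hair densities.
#'
#' @param regions named list or vector mapping region labels to hair
#'   coverage densities, e.g. `list(face = 0.5, thorax_dorsal = 0.1)`.
#' @param seed integer master seed; per-region stroke fields derive their
#'   seeds from it.
#' @param patchSize (width, height) of each region patch in px.
#' @param params a [textureParams()] whose density and seed are
#'   overridden per region.
#' @return List: `rgb` (integer array), `roiset`, `truth` (data.frame of
#'   `region`, `density`).
#' @export
makeSpecimen <- function(regions, seed = 1L, patchSize = c(96, 96),
                         params = textureParams()) {
  labels <- names(regions)
  dens <- as.numeric(unlist(regions))
  if (is.null(labels) || any(!nzchar(labels)))
    stop("'regions' must be a named list: label -> hair density")
  k <- length(dens)
  stopifnot(k >= 1L)
  margin <- 16L; gap <- 12L
  pw <- as.integer(patchSize[1]); ph <- as.integer(patchSize[2])
  ncols <- min(4L, k)
  nrows <- ceiling(k / ncols)
  w <- 2L * margin + ncols * pw + (ncols - 1L) * gap
  h <- 2L * margin + nrows * ph + (nrows - 1L) * gap
  rgb <- array(245L, c(h, w, 3L))
  rois <- vector("list", k)
  for (i in seq_len(k)) {
    gc0 <- (i - 1L) %% ncols
    gr0 <- (i - 1L) %/% ncols
    x0 <- margin + gc0 * (pw + gap)  # 0-based continuous coords
    y0 <- margin + gr0 * (ph + gap)
    p <- params
    p$hairDensity <- dens[i]
    p$seed <- as.integer((seed * 131L + i * 7919L) %% .Machine$integer.max)
    patch <- makeHairyPatch(pw, ph, p)
    rgb[(y0 + 1L):(y0 + ph), (x0 + 1L):(x0 + pw), ] <- patch
    rois[[i]] <- PolygonRoI(labels[i],
                            rbind(c(x0, y0), c(x0 + pw, y0),
                                  c(x0 + pw, y0 + ph), c(x0, y0 + ph)))
  }
  rs <- RoISet(paste0("synthetic_specimen_", seed), w, h, rois,
               quiet = TRUE)
  list(rgb = rgb, roiset = rs,
       truth = data.frame(region = normalizeLabel(labels), density = dens,
                          stringsAsFactors = FALSE))
}

#' Synthetic trait-table configuration
#'
#' @param nSpecies number of species rows (>= size of the true subset
#'   plus 3).
#' @param trueTerms predictor columns that truly drive the response.
#' @param coefs coefficient per true term (recycled).
#' @param intercept response intercept.
#' @param targetR2 population R-squared used to calibrate the residual
#'   standard deviation when `residSd` is `NULL`.
#' @param residSd residual standard deviation; overrides `targetR2`.
#' @param predictorCor exchangeable correlation among region entropies.
#' @param responseName name of the generated response column.
#' @param seed integer RNG seed.
#' @return List of class `"syntheticTraitConfig"`.
#' @export
syntheticTraitConfig <- function(nSpecies = 10L,
                                 trueTerms = c("face", "thorax_dorsal"),
                                 coefs = 2, intercept = 5,
                                 targetR2 = 0.95, residSd = NULL,
                                 predictorCor = 0.3,
                                 responseName = "svd", seed = 1L) {
  coefs <- rep_len(coefs, length(trueTerms))
  if (nSpecies < length(trueTerms) + 3L)
    stop("'nSpecies' must be at least length(trueTerms) + 3")
  if (predictorCor < 0 || predictorCor >= 1)
    stop("'predictorCor' must lie in [0, 1)")
  structure(list(nSpecies = as.integer(nSpecies), trueTerms = trueTerms,
                 coefs = coefs, intercept = intercept, targetR2 = targetR2,
                 residSd = residSd, predictorCor = predictorCor,
                 responseName = responseName, seed = as.integer(seed)),
            class = "syntheticTraitConfig")
}

#' Generate a species-level trait table with known truth
#'
#' Region entropy predictors are drawn from a multivariate normal with
#' exchangeable correlation (means and spreads on the scale of measured
#' combined-entropy region means); `body_length` is drawn independently.
#' The response is `intercept + sum(coefs * true predictors)` plus
#' Gaussian residuals whose standard deviation is calibrated so the
#' population R-squared of the true model equals `targetR2` (unless
#' `residSd` is given directly).
#'
#' @param cfg a [syntheticTraitConfig()].
#' @return List: `table` (data.frame: `species`, the eight canonical
#'   region columns, `body_length`, and the response) and `truth` (the
#'   generating parameters, including the calibrated `residSd`).
#' @export
makeTraitTable <- function(cfg = syntheticTraitConfig()) {
  stopifnot(inherits(cfg, "syntheticTraitConfig"))
  regions <- canonicalRegions()
  stopifnot(all(cfg$trueTerms %in% c(regions, "body_length")))
  mu <- setNames(rep(60, length(regions)), regions)
  sdv <- setNames(rep(15, length(regions)), regions)
  rho <- cfg$predictorCor
  Sigma <- outer(sdv, sdv) * (rho + diag(1 - rho, length(regions)))
  withSeed(cfg$seed, {
    X <- MASS::mvrnorm(cfg$nSpecies, mu = mu, Sigma = Sigma)
    bodyLength <- rnorm(cfg$nSpecies, mean = 10, sd = 2.5)
    tab <- data.frame(species = sprintf("species_%02d", seq_len(cfg$nSpecies)),
                      X, body_length = bodyLength, check.names = FALSE,
                      stringsAsFactors = FALSE)
    full <- cbind(Sigma, body_length = 0)
    full <- rbind(full, body_length = 0)
    full["body_length", "body_length"] <- 2.5^2
    cv <- full[cfg$trueTerms, cfg$trueTerms, drop = FALSE]
    signalVar <- drop(t(cfg$coefs) %*% cv %*% cfg$coefs)
    residSd <- if (!is.null(cfg$residSd)) cfg$residSd
               else sqrt(signalVar * (1 - cfg$targetR2) / cfg$targetR2)
    Xt <- as.matrix(tab[, cfg$trueTerms, drop = FALSE])
    y <- cfg$intercept + drop(Xt %*% cfg$coefs)
    if (residSd > 0) y <- y + rnorm(cfg$nSpecies, sd = residSd)
    tab[[cfg$responseName]] <- y
    truth <- list(trueTerms = cfg$trueTerms, coefs = cfg$coefs,
                  intercept = cfg$intercept, residSd = residSd,
                  targetR2 = cfg$targetR2)
    list(table = tab, truth = truth)
  })
}

#' Write a synthetic fixture bundle to disk
#'
#' Renders one of the named presets into a directory: PNG image(s), RoI
#' JSON sidecar(s), a ground-truth JSON, and (for the trait preset) a
#' trait CSV.
#'
#' @param preset one of `"two-region"` (hairy vs sparse region),
#'   `"eight-region"` (all canonical regions, graded densities),
#'   `"contamination"` (hairy patch with pollen disks), or
#'   `"trait-recovery"` (species trait table with known true subset).
#' @param dir output directory (created if needed).
#' @param seed integer master seed.
#' @return Character vector of the files written, invisibly.
#' @export
writeFixtureBundle <- function(preset, dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  writeImg <- function(rgb, path) {
    img <- EBImage::Image(aperm(rgb / 255, c(2, 1, 3)),
                          colormode = "Color")
    EBImage::writeImage(img, path)
    path
  }
  if (preset == "two-region" || preset == "eight-region") {
    regs <- if (preset == "two-region") {
      list(face = 0.5, thorax_dorsal = 0.1)
    } else {
      setNames(as.list(seq(0.1, 0.8, length.out = 8)), canonicalRegions())
    }
    spec <- makeSpecimen(regs, seed = seed)
    id <- imageId(spec$roiset)
    files <- c(files, writeImg(spec$rgb, file.path(dir, paste0(id, ".png"))))
    files <- c(files, saveRoiSet(spec$roiset,
                                 file.path(dir, paste0(id, ".rois.json"))))
    jsonlite::write_json(spec$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, file.path(dir, "truth.json"))
  } else if (preset == "contamination") {
    spec <- makeSpecimen(list(thorax_dorsal = 0.4), seed = seed,
                         patchSize = c(160, 160))
    mask <- rasterizeRoi(regions(spec$roiset)[[1]],
                         imageSize(spec$roiset)["width"],
                         imageSize(spec$roiset)["height"])
    cont <- addPollenArtifacts(spec$rgb, n = 8, seed = seed + 17L,
                               regionMask = mask)
    id <- imageId(spec$roiset)
    files <- c(files, writeImg(cont$rgb, file.path(dir, paste0(id, ".png"))))
    files <- c(files, saveRoiSet(spec$roiset,
                                 file.path(dir, paste0(id, ".rois.json"))))
    jsonlite::write_json(list(regions = spec$truth, circles = cont$circles),
                         file.path(dir, "truth.json"), auto_unbox = TRUE,
                         digits = NA)
    files <- c(files, file.path(dir, "truth.json"))
  } else if (preset == "trait-recovery") {
    tt <- makeTraitTable(syntheticTraitConfig(seed = seed))
    utils::write.csv(tt$table, file.path(dir, "traits.csv"),
                     row.names = FALSE)
    jsonlite::write_json(tt$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, file.path(dir, c("traits.csv", "truth.json")))
  } else {
    stop("unknown preset '", preset, "'")
  }
  invisible(files)
}
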