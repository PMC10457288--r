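# Whole-slide assembly: tile-grid planning, overlap-blended stitching, and
# tilt/illumination flattening.
#
# Tiles are positioned by plan coordinates only (dead-reckoned stage); no
# correlation-based tile registration is attempted.  Blending uses feathered
# (tent) weights normalized to sum to one at every mosaic pixel, which makes
# stitching of mutually consistent tiles lossless.

#' Plan a tile grid covering an area
#'
#' Per axis the tile count is 1 when the area fits one field of view, and
#' `1 + ceiling((area - fov) / (fov * (1 - overlap)))` otherwise.  The last
#' row/column is shifted inward so no tile exceeds the area (the run-time
#' overlap adjustment), which can only increase its overlap.
#'
#' @param areaMm length-2 numeric (width, height) in millimetres; a scalar
#'   is recycled to a square area.
#' @param cfg an [InstrumentConfig()] supplying the tile field of view.
#' @param overlap nominal overlap fraction in [0, 1).
#' @return a `TilePlan`; origins are (x, y) micrometres in row-major order.
#' @examples
#' plan <- planTiles(c(15, 15), instrumentPreset("lsm10x"), 0.1)
#' plan   # 17 x 17 grid, 289 tiles
#' @export
planTiles <- function(areaMm, cfg, overlap = 0.1) {
  stopifnot(is(cfg, "InstrumentConfig"))
  if (length(areaMm) == 1L) areaMm <- rep(areaMm, 2L)
  if (any(areaMm < 0)) stop("'areaMm' must be >= 0")
  if (overlap < 0 || overlap >= 1) stop("'overlap' must be in [0, 1)")
  fov <- fovUm(cfg)
  areaUm <- areaMm * 1000
  axisPlan <- function(extent) {
    if (extent <= fov) return(list(n = 1L, org = 0))
    n <- 1L + as.integer(ceiling((extent - fov) / (fov * (1 - overlap))))
    org <- (seq_len(n) - 1L) * fov * (1 - overlap)
    org[n] <- extent - fov                  # shift the last tile inward
    list(n = n, org = org)
  }
  px <- axisPlan(areaUm[1]); py <- axisPlan(areaUm[2])
  origins <- cbind(x = rep(px$org, times = py$n),
                   y = rep(py$org, each = px$n))
  new("TilePlan", originsUm = origins, tileFovUm = fov,
      overlap = overlap, gridShape = c(py$n, px$n))
}

# pixel-grid geometry shared by extract/stitch
.planPixelGeometry <- function(plan, pixelSizeUm) {
  tilePx <- as.integer(round(plan@tileFovUm / pixelSizeUm))
  orgPx <- round(plan@originsUm / pixelSizeUm)    # 0-based pixel offsets
  extent <- c(max(orgPx[, 2]) + tilePx, max(orgPx[, 1]) + tilePx)
  list(tilePx = tilePx, orgPx = orgPx, extentPx = extent)
}

#' Cut tiles out of a reference image according to a plan
#'
#' Used to emulate stage motion over a large scene and in stitching round
#' trips.  The image must cover the plan extent.
#'
#' @param image numeric matrix (a single-band image).
#' @param plan a `TilePlan` from [planTiles()].
#' @param pixelSizeUm sampling of `image`.
#' @return list of tile matrices in plan order.
#' @export
extractTiles <- function(image, plan, pixelSizeUm) {
  g <- .planPixelGeometry(plan, pixelSizeUm)
  if (nrow(image) < g$extentPx[1] || ncol(image) < g$extentPx[2])
    stop(sprintf("image (%d x %d) does not cover the plan extent (%d x %d)",
                 nrow(image), ncol(image), g$extentPx[1], g$extentPx[2]))
  lapply(seq_len(nrow(g$orgPx)), function(i)
    image[g$orgPx[i, 2] + seq_len(g$tilePx),
          g$orgPx[i, 1] + seq_len(g$tilePx), drop = FALSE])
}

#' Stitch tiles into a mosaic with feathered blending
#'
#' Each tile carries a separable tent weight (maximal at the tile centre,
#' falling toward the edges); overlapping contributions are combined as the
#' weighted mean, so blending weights sum to exactly one at every mosaic
#' pixel and stitching noiseless consistent tiles is lossless.
#'
#' @param tiles list of tile matrices (or single-band cubes) in plan order;
#'   a `NULL` entry raises an error naming the missing grid index.
#' @param plan the `TilePlan` the tiles were acquired under.
#' @param pixelSizeUm sampling of the tiles.
#' @return mosaic matrix spanning the plan extent.
#' @examples
#' cfg <- instrumentPreset("lsm10x")
#' plan <- planTiles(c(2, 2), cfg, 0.1)
#' img <- matrix(runif(1000^2), 1000)
#' mos <- stitchTiles(extractTiles(img, plan, 2), plan, 2)
#' max(abs(mos - img))
#' @export
stitchTiles <- function(tiles, plan, pixelSizeUm) {
  g <- .planPixelGeometry(plan, pixelSizeUm)
  nT <- nrow(g$orgPx)
  if (length(tiles) != nT)
    stop(sprintf("plan expects %d tiles, got %d", nT, length(tiles)))
  missing <- which(vapply(tiles, is.null, logical(1)))
  if (length(missing)) {
    rc <- cbind((missing - 1L) %/% plan@gridShape[2] + 1L,
                (missing - 1L) %% plan@gridShape[2] + 1L)
    stop("missing tile(s) at grid index ",
         paste(sprintf("(%d, %d)", rc[, 1], rc[, 2]), collapse = ", "))
  }
  w1 <- pmin(seq_len(g$tilePx), rev(seq_len(g$tilePx)))
  W <- outer(w1, w1)
  num <- matrix(0, g$extentPx[1], g$extentPx[2])
  den <- matrix(0, g$extentPx[1], g$extentPx[2])
  for (i in seq_len(nT)) {
    tile <- tiles[[i]]
    if (!identical(dim(tile)[1:2], c(g$tilePx, g$tilePx)))
      stop(sprintf("tile %d has shape %s, expected %d x %d", i,
                   paste(dim(tile), collapse = " x "), g$tilePx, g$tilePx))
    ri <- g$orgPx[i, 2] + seq_len(g$tilePx)
    ci <- g$orgPx[i, 1] + seq_len(g$tilePx)
    num[ri, ci] <- num[ri, ci] + W * tile
    den[ri, ci] <- den[ri, ci] + W
  }
  num / den
}

#' Total blending weight across a mosaic
#'
#' The per-pixel sum of normalized tile weights; by construction this is
#' exactly 1 wherever at least one tile contributes, which makes the
#' weight-conservation property of the blend directly assertable.
#'
#' @param plan a `TilePlan`.
#' @param pixelSizeUm tile sampling.
#' @return matrix of summed normalized weights over the mosaic extent.
#' @export
blendWeightMap <- function(plan, pixelSizeUm) {
  g <- .planPixelGeometry(plan, pixelSizeUm)
  ones <- lapply(seq_len(nrow(g$orgPx)),
                 function(i) matrix(1, g$tilePx, g$tilePx))
  stitchTiles(ones, plan, pixelSizeUm)
}

#' Remove a linear shading plane from an image
#'
#' Least-squares plane fit (`a + b x + c y`) subtracted with the image mean
#' preserved; used for sample-tilt/illumination flattening of mosaics.  A
#' constant image yields a zero-slope plane and is returned unchanged.
#'
#' @param image numeric matrix, at least 3 x 3.
#' @return list with `image` (flattened) and `coefficients`
#'   (named `a`, `bx`, `cy`; x grows with column, y with row, in pixels).
#' @export
flattenTilt <- function(image) {
  if (nrow(image) < 3L || ncol(image) < 3L) stop("image must be at least 3 x 3")
  r <- as.vector(row(image)); c_ <- as.vector(col(image))
  fit <- stats::lm.fit(cbind(1, c_, r), as.vector(image))
  cf <- fit$coefficients
  plane <- matrix(cf[1] + cf[2] * c_ + cf[3] * r, nrow(image))
  list(image = image - plane + mean(plane),
       coefficients = c(a = unname(cf[1]), bx = unname(cf[2]),
                        cy = unname(cf[3])))
}
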