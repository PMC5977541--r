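# Nuclei I/O: GeoJSON polygons, integer label masks, the classical
# segmentation stand-in for externally produced deep-learning segmentations,
# and epithelium/stroma compartment assignment.

#' Write a NucleiPatch as a GeoJSON FeatureCollection
#'
#' One Polygon feature per nucleus with properties \code{id},
#' \code{compartment} and \code{orientation_deg}; patch metadata
#' (\code{patch_id}, \code{patient_id}, \code{width_px}, \code{height_px},
#' \code{magnification}) in the collection's \code{properties}.
#'
#' @param patch a \linkS4class{NucleiPatch}.
#' @param path output file path.
#' @export
writeNuclei <- function(patch, path) {
  features <- lapply(seq_along(patch@polygons), function(i) {
    poly <- patch@polygons[[i]]
    ring <- rbind(poly, poly[1, , drop = FALSE])  # GeoJSON closes the ring
    list(
      type = "Feature",
      geometry = list(type = "Polygon",
                      coordinates = list(unname(split(ring, row(ring))))),
      properties = list(id = patch@meta$id[i],
                        compartment = patch@meta$compartment[i],
                        orientation_deg = patch@meta$orientation_deg[i])
    )
  })
  obj <- list(
    type = "FeatureCollection",
    properties = list(patch_id = patch@patchId,
                      patient_id = patch@patientId,
                      width_px = patch@width, height_px = patch@height,
                      magnification = patch@magnification),
    features = features
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
}

#' Read nuclei into a NucleiPatch
#'
#' @param path a GeoJSON FeatureCollection (as written by
#'   \code{\link{writeNuclei}}) or a 16-bit grayscale PNG label mask.
#' @param format \code{"geojson"} or \code{"label_mask"}.
#' @param patchId,patientId,magnification metadata for the label-mask path
#'   (the GeoJSON path carries its own).
#' @return a \linkS4class{NucleiPatch}.
#' @export
readNuclei <- function(path, format = c("geojson", "label_mask"),
                       patchId = "patch", patientId = "patient",
                       magnification = "40x") {
  format <- match.arg(format)
  if (format == "label_mask") {
    labels <- readLabelMask(path)
    recs <- labelMaskToPolygons(labels)
    return(NucleiPatch(recs$polygons,
                       width = nrow(labels), height = ncol(labels),
                       patchId = patchId, patientId = patientId,
                       compartment = "unknown",
                       magnification = magnification, checkSimple = FALSE))
  }
  obj <- jsonlite::read_json(path)
  stopIfNot(identical(obj$type, "FeatureCollection"),
            "expected a GeoJSON FeatureCollection")
  meta <- obj$properties %||% list()
  polys <- list()
  comp <- character(0)
  ori <- numeric(0)
  for (i in seq_along(obj$features)) {
    ft <- obj$features[[i]]
    if (!identical(ft$geometry$type, "Polygon"))
      stop(sprintf("feature %d: only Polygon geometries are supported", i),
           call. = FALSE)
    ring <- ft$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    if (nrow(m) >= 2 &&
        isTRUE(all.equal(m[1, ], m[nrow(m), ], tolerance = 1e-12)))
      m <- m[-nrow(m), , drop = FALSE]
    if (nrow(m) < 3 || !polygonIsSimple(m))
      stop(sprintf("feature %d: malformed (self-intersecting or degenerate) polygon",
                   i), call. = FALSE)
    polys[[length(polys) + 1]] <- m
    comp <- c(comp, ft$properties$compartment %||% "unknown")
    ori <- c(ori, ft$properties$orientation_deg %||% NA_real_)
  }
  if (all(is.na(ori))) ori <- NULL
  NucleiPatch(polys,
              width = meta$width_px %||% 0, height = meta$height_px %||% 0,
              patchId = meta$patch_id %||% patchId,
              patientId = meta$patient_id %||% patientId,
              compartment = if (length(comp)) comp else "unknown",
              orientation_deg = ori,
              magnification = meta$magnification %||% magnification,
              checkSimple = FALSE)
}

# Trace the outer boundary of a binary pixel set along pixel edges ("crack
# following"), so the polygon of a w x h pixel block has area exactly w*h.
# Vertices live on the half-integer corner grid of the pixel-center
# convention (pixel (x, y) spans [x-0.5, x+0.5] x [y-0.5, y+0.5]).
traceCrackBoundary <- function(bin) {
  w <- nrow(bin); h <- ncol(bin)
  pix <- which(bin, arr.ind = TRUE)  # 1-based (x+1, y+1)
  x <- pix[, 1]; y <- pix[, 2]
  pad <- function(dx, dy) {
    nx <- x + dx; ny <- y + dy
    ok <- nx >= 1 & nx <= w & ny >= 1 & ny <= h
    nb <- rep(FALSE, length(x))
    nb[ok] <- bin[cbind(nx[ok], ny[ok])]
    nb
  }
  # directed boundary edges (object kept on the left walking the loop)
  segs <- rbind(
    if (any(!pad(0, -1))) { i <- !pad(0, -1)
      cbind(x[i] - 1, y[i] - 1, x[i], y[i] - 1) },      # top: left -> right
    if (any(!pad(1, 0))) { i <- !pad(1, 0)
      cbind(x[i], y[i] - 1, x[i], y[i]) },               # right: up -> down
    if (any(!pad(0, 1))) { i <- !pad(0, 1)
      cbind(x[i], y[i], x[i] - 1, y[i]) },               # bottom: right -> left
    if (any(!pad(-1, 0))) { i <- !pad(-1, 0)
      cbind(x[i] - 1, y[i], x[i] - 1, y[i] - 1) }        # left: down -> up
  )
  if (is.null(segs) || nrow(segs) == 0) return(NULL)
  keyOf <- function(cx, cy) as.integer(cx) * (h + 2L) + as.integer(cy)
  startKey <- keyOf(segs[, 1], segs[, 2])
  groups <- split(seq_len(nrow(segs)), startKey)
  lookup <- list2env(groups, hash = TRUE)
  used <- logical(nrow(segs))
  loops <- list()
  for (s0 in seq_len(nrow(segs))) {
    if (used[s0]) next
    loop <- matrix(NA_real_, nrow(segs) + 1, 2)
    cur <- s0
    n <- 0L
    prevDir <- NULL
    repeat {
      used[cur] <- TRUE
      n <- n + 1L
      loop[n, ] <- segs[cur, 1:2]
      endPt <- segs[cur, 3:4]
      inDir <- segs[cur, 3:4] - segs[cur, 1:2]
      cands <- get0(as.character(keyOf(endPt[1], endPt[2])), envir = lookup,
                    ifnotfound = integer(0))
      cands <- cands[!used[cands]]
      if (length(cands) == 0) break
      if (length(cands) > 1) {
        # ambiguous (diagonally touching) corner: prefer the sharpest left
        # turn so the loop hugs the same pixel region
        turn <- vapply(cands, function(cc) {
          d <- segs[cc, 3:4] - segs[cc, 1:2]
          atan2(inDir[1] * d[2] - inDir[2] * d[1],
                inDir[1] * d[1] + inDir[2] * d[2])
        }, numeric(1))
        cur <- cands[which.max(turn)]
      } else cur <- cands
    }
    loops[[length(loops) + 1]] <- loop[seq_len(n), , drop = FALSE]
  }
  areas <- vapply(loops, polygonArea, numeric(1))
  poly <- loops[[which.max(areas)]]
  poly - 0.5  # corner grid -> pixel-center coordinate convention
}

#' Convert an integer label mask to nucleus boundary polygons
#'
#' One record per distinct positive label, boundaries traced along pixel
#' edges at pixel resolution (so a 10 x 10 pixel label yields a polygon of
#' area exactly 100 px^2), sorted by label. A label whose pixels form more
#' than one connected component is rejected.
#'
#' @param labels integer matrix indexed [x+1, y+1]; 0 = background.
#' @return list with \code{polygons} (list of vertex matrices) and
#'   \code{labels} (the corresponding label values).
#' @export
labelMaskToPolygons <- function(labels) {
  stopIfNot(all(labels >= 0), "label mask must be non-negative")
  ids <- sort(unique(labels[labels > 0]))
  polys <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    bin <- labels == ids[k]
    ncomp <- max(EBImage::bwlabel(EBImage::Image(bin * 1)))
    if (ncomp > 1)
      stop(sprintf("label %d occupies %d disjoint regions", ids[k], ncomp),
           call. = FALSE)
    polys[[k]] <- traceCrackBoundary(bin)
  }
  list(polygons = polys, labels = ids)
}

#' Classical nucleus segmentation stand-in
#'
#' Color-deconvolves the RGB patch to a hematoxylin-like channel using fixed
#' H&E stain vectors, thresholds it globally (Otsu), fills holes, removes
#' objects below \code{areaMin}, and splits touching nuclei by a
#' distance-transform watershed with h-minima-style suppression
#' (\code{hMin}). Intended as a classical stand-in where deep-learning
#' segmentations are not available; externally produced label masks can be
#' ingested directly via \code{\link{readNuclei}}.
#'
#' @param rgb width x height x 3 array in [0, 1], indexed [x+1, y+1, ch].
#' @param areaMin minimum object area in px^2 (default 40 at 40x).
#' @param hMin watershed suppression depth in px (default 2).
#' @return integer label matrix (width x height), labels consecutive from 1.
#' @export
segmentNucleiClassical <- function(rgb, areaMin = 40, hMin = 2) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3)
    stop("segmentNucleiClassical() needs a 3-channel RGB image",
         call. = FALSE)
  d <- dim(rgb)
  flat <- matrix(rgb, d[1] * d[2], 3)
  od <- -log10(pmax(flat, 1 / 255))
  stains <- rbind(
    h = c(0.650, 0.704, 0.286),
    e = c(0.072, 0.990, 0.105),
    d = c(0.268, 0.570, 0.776)  # residual, orthogonal complement
  )
  stains <- stains / sqrt(rowSums(stains^2))
  conc <- od %*% solve(stains)
  hch <- matrix(conc[, 1], d[1], d[2])
  rng <- range(hch)
  if (diff(rng) < 1e-9) return(matrix(0L, d[1], d[2]))
  hn <- (hch - rng[1]) / diff(rng)
  img <- EBImage::Image(hn)
  th <- EBImage::otsu(img)
  bw <- EBImage::fillHull(img > th)
  lab <- EBImage::bwlabel(bw)
  sizes <- table(lab[lab > 0])
  small <- as.integer(names(sizes)[sizes < areaMin])
  if (length(small)) bw[lab %in% small] <- 0
  if (!any(bw > 0)) return(matrix(0L, d[1], d[2]))
  dm <- EBImage::distmap(bw)
  ws <- EBImage::watershed(dm, tolerance = hMin, ext = 1)
  out <- EBImage::imageData(ws)
  ids <- sort(unique(out[out > 0]))
  relab <- matrix(0L, d[1], d[2])
  for (k in seq_along(ids)) relab[out == ids[k]] <- k
  relab
}

#' Assign nuclei to the epithelial or stromal compartment
#'
#' A nucleus is epithelial iff more than 50\% of its covered pixels lie
#' inside the epithelium mask; an exact 50\% tie falls back to whether the
#' centroid pixel is inside. No nucleus is left unknown.
#'
#' @param patch a \linkS4class{NucleiPatch}.
#' @param epitheliumMask logical matrix indexed [x+1, y+1] whose dimensions
#'   cover the patch.
#' @return the patch with compartments (and the mask) set.
#' @export
assignCompartment <- function(patch, epitheliumMask) {
  if (nrow(epitheliumMask) < patch@width ||
      ncol(epitheliumMask) < patch@height)
    stop("epithelium mask does not cover the patch", call. = FALSE)
  w <- nrow(epitheliumMask); h <- ncol(epitheliumMask)
  comp <- character(nNuclei(patch))
  for (i in seq_along(patch@polygons)) {
    pix <- polygonPixelCenters(patch@polygons[[i]])
    keep <- pix[, 1] >= 0 & pix[, 1] < w & pix[, 2] >= 0 & pix[, 2] < h
    pix <- pix[keep, , drop = FALSE]
    frac <- if (nrow(pix) > 0)
      mean(epitheliumMask[cbind(pix[, 1] + 1L, pix[, 2] + 1L)]) else 0.5
    if (frac > 0.5) comp[i] <- "epithelial"
    else if (frac < 0.5) comp[i] <- "stromal"
    else {
      cx <- min(max(round(patch@meta$x[i]), 0), w - 1) + 1L
      cy <- min(max(round(patch@meta$y[i]), 0), h - 1) + 1L
      comp[i] <- if (epitheliumMask[cx, cy]) "epithelial" else "stromal"
    }
  }
  patch@meta$compartment <- comp
  patch@epitheliumMask <- epitheliumMask
  validObject(patch)
  patch
}

#' Write / read an integer label mask as 16-bit grayscale TIFF
#' @param labels integer matrix indexed [x+1, y+1].
#' @param path file path.
#' @export
writeLabelMask <- function(labels, path) {
  stopIfNot(max(labels) < 65536, "more than 65535 labels")
  # TIFF rasters are row-major
  tiff::writeTIFF(t(labels) / 65535, path, bits.per.sample = 16L)
}

#' @rdname writeLabelMask
#' @export
readLabelMask <- function(path) {
  raster <- tiff::readTIFF(path)
  if (length(dim(raster)) == 3) raster <- raster[, , 1]
  t(round(raster * 65535))
}

#' Write / read an epithelium mask as 8-bit PNG (255 = epithelium)
#' @param mask logical matrix indexed [x+1, y+1].
#' @param path file path.
#' @export
writeEpitheliumMask <- function(mask, path) {
  png::writePNG(t(mask * 1), path)
}

#' @rdname writeEpitheliumMask
#' @export
readEpitheliumMask <- function(path) {
  raster <- png::readPNG(path)
  if (length(dim(raster)) == 3) raster <- raster[, , 1]
  t(raster) > 0.5
}
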