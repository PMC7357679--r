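# Multispectral raster and label-mask input/output, plus patch extraction.
#
# Scenes are stored as multi-page 32-bit TIFF (one band per page,
# reflectance in [0, 1], fixed-point samples with ~2.3e-10 quantization).
# Nodata is carried in a GDAL-style external mask sidecar "<file>.msk"
# (single-page 8-bit TIFF, 0 = nodata), written only when the scene
# contains nodata.  Any non-finite pixel read back is promoted into the
# nodata mask.

DEFAULT_CLASSES <- c("seagrass", "sea", "sand", "land", "intertidal")

#' Construct a multispectral scene
#'
#' A scene is an H x W x B array of band reflectance (unitless, in \[0, 1\])
#' together with a logical nodata mask and optional band names.  Non-finite
#' pixels are promoted into the nodata mask and zeroed.
#'
#' @param pixels numeric H x W x B array (a matrix is treated as B = 1).
#' @param band_names optional character vector of length B.
#' @param nodata_mask optional H x W logical matrix; TRUE marks invalid pixels.
#' @param geo opaque georeferencing metadata, carried through untouched.
#' @return an object of class `msscene`.
#' @export
multispectral_scene <- function(pixels, band_names = NULL, nodata_mask = NULL,
                                geo = NULL) {
  if (is.matrix(pixels)) dim(pixels) <- c(dim(pixels), 1L)
  if (length(dim(pixels)) != 3L) {
    stop("`pixels` must be an H x W x B array", call. = FALSE)
  }
  d <- dim(pixels)
  if (any(d < 1L)) stop("scene dimensions must be >= 1", call. = FALSE)
  if (is.null(band_names)) band_names <- paste0("band", seq_len(d[3]))
  if (length(band_names) != d[3]) {
    stop("`band_names` must have one entry per band", call. = FALSE)
  }
  if (is.null(nodata_mask)) nodata_mask <- matrix(FALSE, d[1], d[2])
  stopifnot(is.logical(nodata_mask), all(dim(nodata_mask) == d[1:2]))
  bad <- !is.finite(pixels)
  if (any(bad)) {
    nodata_mask <- nodata_mask | apply(bad, c(1, 2), any)
    pixels[bad] <- 0
  }
  pixels[rep(nodata_mask, times = d[3])] <- 0
  structure(list(pixels = pixels, band_names = band_names,
                 nodata_mask = nodata_mask, geo = geo),
            class = "msscene")
}

#' @export
print.msscene <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<msscene> %d x %d pixels, %d band(s), %d nodata\n",
              d[1], d[2], d[3], sum(x$nodata_mask)))
  invisible(x)
}

#' Construct a label mask
#'
#' Integer class labels per pixel: 0 means unlabeled, 1..N_c index the
#' classes in `class_names` order (default seagrass, sea, sand, land,
#' intertidal).
#'
#' @param labels integer H x W matrix in `{0, ..., length(class_names)}`.
#' @param class_names ordered class names.
#' @return an object of class `label_mask`.
#' @export
label_mask <- function(labels, class_names = DEFAULT_CLASSES) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix", call. = FALSE)
  if (any(!is.finite(labels)) || any(labels != round(labels))) {
    stop("label mask must be integer-valued", call. = FALSE)
  }
  nc <- length(class_names)
  if (any(labels < 0L) || any(labels > nc)) {
    stop(sprintf("label values must lie in 0..%d", nc), call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, class_names = class_names),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %d x %d, %d labeled pixel(s), classes: %s\n",
              nrow(x$labels), ncol(x$labels), sum(x$labels > 0L),
              paste(x$class_names, collapse = ", ")))
  invisible(x)
}

#' Write a multispectral scene to a multi-page TIFF
#'
#' One 32-bit page per band, reflectance in \[0, 1\].  If the scene has
#' nodata, a sidecar `<path>.msk` mask raster is written alongside (0 =
#' nodata).  Values are quantized to the writer's 32-bit sample grid on
#' every write (step about 2.3e-10); round trips are exact to that
#' quantization, not bitwise.
#'
#' @param scene an `msscene`.
#' @param path output file path (".tif").
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "msscene"))
  px <- scene$pixels
  if (any(px < 0 | px > 1)) {
    stop("scene reflectance must lie in [0, 1] for storage", call. = FALSE)
  }
  b <- dim(px)[3]
  pages <- lapply(seq_len(b), function(k) px[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  msk <- paste0(path, ".msk")
  if (any(scene$nodata_mask)) {
    tiff::writeTIFF((!scene$nodata_mask) * 1, msk, bits.per.sample = 8L,
                    compression = "none")
  } else if (file.exists(msk)) {
    unlink(msk)
  }
  invisible(path)
}

#' Read a multispectral scene from a TIFF file
#'
#' Accepts any single- or multi-page TIFF; page order defines band order.
#' A `<path>.msk` sidecar, if present, is read as the nodata mask; non-finite
#' pixels are additionally marked nodata.
#'
#' @param path TIFF file path.
#' @param band_names optional band names.
#' @return an `msscene`.
#' @export
read_scene <- function(path, band_names = NULL) {
  if (!file.exists(path)) stop("scene file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p[, , 1] else p  # tolerate RGB-expanded pages
  })
  if (length(pages) == 0L) stop("TIFF contains no bands", call. = FALSE)
  d <- dim(pages[[1]])
  px <- array(unlist(pages, use.names = FALSE),
              dim = c(d[1], d[2], length(pages)))
  mask <- NULL
  msk <- paste0(path, ".msk")
  if (file.exists(msk)) {
    m <- tiff::readTIFF(msk, as.is = TRUE)
    mask <- m == 0L
  }
  multispectral_scene(px, band_names = band_names, nodata_mask = mask)
}

#' Write a label mask as a single-band integer raster
#'
#' 8-bit single-page TIFF; `read_label_mask()` inverts it exactly.
#' Optionally renders a colored PNG using the habitat colormap
#' (seagrass green, sea blue, sand cyan, land yellow, intertidal magenta;
#' unlabeled black).
#'
#' @param mask a `label_mask`.
#' @param path output TIFF path.
#' @param png_path optional path for a color-rendered PNG.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(mask, path, png_path = NULL) {
  stopifnot(inherits(mask, "label_mask"))
  if (length(mask$class_names) > 255L) {
    stop("at most 255 classes supported by the 8-bit mask container",
         call. = FALSE)
  }
  tiff::writeTIFF(mask$labels / 255, path, bits.per.sample = 8L,
                  compression = "none")
  if (!is.null(png_path)) {
    png::writePNG(render_label_mask(mask), png_path)
  }
  invisible(path)
}

#' Class colormap for rendered habitat maps
#'
#' @param class_names class names; the five canonical classes get their
#'   conventional colors, any others are assigned from a fallback palette.
#' @return named character vector of hex colors (unlabeled = black first).
#' @export
class_colormap <- function(class_names = DEFAULT_CLASSES) {
  canon <- c(seagrass = "#00FF00", sea = "#0000FF", sand = "#00FFFF",
             land = "#FFFF00", intertidal = "#FF00FF")
  fallback <- grDevices::rainbow(max(1L, length(class_names)))
  cols <- ifelse(class_names %in% names(canon),
                 canon[class_names], fallback[seq_along(class_names)])
  stats::setNames(cols, class_names)
}

render_label_mask <- function(mask) {
  cols <- c("#000000", class_colormap(mask$class_names))
  rgb <- grDevices::col2rgb(cols) / 255
  idx <- mask$labels + 1L
  arr <- array(0, c(nrow(idx), ncol(idx), 3L))
  for (ch in 1:3) arr[, , ch] <- matrix(rgb[ch, idx], nrow(idx), ncol(idx))
  arr
}

#' Read a label mask raster
#'
#' @param path single-band integer TIFF path.
#' @param class_names ordered class names fixing the valid range 0..N_c.
#' @return a `label_mask`.
#' @export
read_label_mask <- function(path, class_names = DEFAULT_CLASSES) {
  if (!file.exists(path)) stop("mask file not found: ", path, call. = FALSE)
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  if (!is.integer(m)) {
    stop("label mask raster must be integer-valued", call. = FALSE)
  }
  label_mask(m, class_names = class_names)
}

#' Construct a patch set
#'
#' N center-labeled P x P x B patches with provenance coordinates.  Labels
#' are 0-based internal class indices (0..N_c-1), or NULL for an unlabeled
#' set.
#'
#' @param patches numeric N x P x P x B array.
#' @param labels optional integer vector of length N (0-based classes).
#' @param centers integer N x 2 matrix of (row, col) patch centers (1-based).
#' @param class_names ordered class names.
#' @return an object of class `patch_set`.
#' @export
patch_set <- function(patches, labels = NULL, centers = NULL,
                      class_names = DEFAULT_CLASSES) {
  stopifnot(length(dim(patches)) == 4L)
  n <- dim(patches)[1]
  p <- dim(patches)[2]
  stopifnot(dim(patches)[3] == p)
  if (any(!is.finite(patches))) stop("patches must be finite", call. = FALSE)
  if (!is.null(labels)) {
    stopifnot(length(labels) == n)
    if (n > 0 && (any(labels < 0L) || any(labels >= length(class_names)))) {
      stop("labels must lie in 0..N_c-1", call. = FALSE)
    }
    labels <- as.integer(labels)
  }
  if (is.null(centers)) centers <- matrix(NA_integer_, n, 2L)
  structure(list(patches = patches, labels = labels, centers = centers,
                 patch_size = p, n_bands = dim(patches)[4],
                 class_names = class_names),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patch(es) of %d x %d x %d%s\n",
              n_patches(x), x$patch_size, x$patch_size, x$n_bands,
              if (is.null(x$labels)) " (unlabeled)" else ""))
  invisible(x)
}

#' Number of patches in a patch set
#' @param ps a `patch_set`.
#' @export
n_patches <- function(ps) dim(ps$patches)[1]

#' Subset a patch set by index
#'
#' If the set carries an `access_log` attribute (an environment with an
#' `idx` vector), the accessed indices are recorded there; this supports
#' auditing which labeled samples an adaptation run actually touched.
#'
#' @param ps a `patch_set`.
#' @param idx integer indices.
#' @return the subset `patch_set`.
#' @export
ps_take <- function(ps, idx) {
  log <- attr(ps, "access_log")
  if (is.environment(log)) log$idx <- c(log$idx, idx)
  patch_set(ps$patches[idx, , , , drop = FALSE],
            labels = if (!is.null(ps$labels)) ps$labels[idx],
            centers = ps$centers[idx, , drop = FALSE],
            class_names = ps$class_names)
}

# Flatten patches to an N x (P*P*B) matrix (column index i + (j-1)P + (b-1)P^2).
ps_matrix <- function(ps) {
  x <- ps$patches
  dim(x) <- c(dim(x)[1], prod(dim(x)[2:4]))
  x
}

#' Extract center-labeled patches from a scene
#'
#' A patch is the closed window of side `patch_size` centered on a pixel
#' (0-based coordinate convention, row-major center ordering).  Eligible
#' centers have a full window inside the scene with no nodata pixel; with
#' `labeled_only = TRUE` the center pixel must additionally be labeled.
#' Border centers are skipped, never padded.  Labels in the returned set are
#' 0-based (center class minus one).
#'
#' @param scene an `msscene`.
#' @param mask optional `label_mask` with the same H x W.
#' @param patch_size odd window side, default 5.
#' @param labeled_only keep only patches whose center is labeled.
#' @return a `patch_set`.
#' @export
extract_patches <- function(scene, mask = NULL, patch_size = 5L,
                            labeled_only = FALSE) {
  stopifnot(inherits(scene, "msscene"))
  if (patch_size %% 2L == 0L) stop("`patch_size` must be odd", call. = FALSE)
  d <- dim(scene$pixels)
  h <- d[1]; w <- d[2]; b <- d[3]; p <- as.integer(patch_size)
  half <- p %/% 2L
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "label_mask"))
    if (!all(dim(mask$labels) == c(h, w))) {
      stop("scene and mask dimensions differ", call. = FALSE)
    }
  }
  if (labeled_only && is.null(mask)) {
    stop("`labeled_only` requires a mask", call. = FALSE)
  }
  if (h < p || w < p) {
    return(empty_patch_set(p, b,
                           if (is.null(mask)) DEFAULT_CLASSES else mask$class_names))
  }
  # window nodata counts via summed-area table
  sat <- window_sums(scene$nodata_mask * 1L, p)
  ok <- sat == 0
  if (labeled_only) {
    interior <- mask$labels[(half + 1L):(h - half), (half + 1L):(w - half),
                            drop = FALSE]
    ok <- ok & interior > 0L
  }
  # row-major ordering: sweep rows, then columns within a row
  keep <- which(t(ok))
  if (length(keep) == 0L) {
    return(empty_patch_set(p, b,
                           if (is.null(mask)) DEFAULT_CLASSES else mask$class_names))
  }
  nr <- h - p + 1L
  nw <- w - p + 1L
  rows <- (keep - 1L) %/% nw + half + 1L
  cols <- (keep - 1L) %% nw + half + 1L
  base <- rows + (cols - 1L) * h
  di <- rep.int(seq_len(p) - half - 1L, p * b)
  dj <- rep(rep(seq_len(p) - half - 1L, each = p), b)
  db <- rep(seq_len(b) - 1L, each = p * p)
  offs <- di + dj * h + db * h * w
  idx <- outer(base, offs, "+")
  patches <- scene$pixels[idx]
  dim(patches) <- c(length(keep), p, p, b)
  labels <- NULL
  if (labeled_only) labels <- mask$labels[cbind(rows, cols)] - 1L
  patch_set(patches, labels = labels, centers = cbind(rows, cols),
            class_names = if (is.null(mask)) DEFAULT_CLASSES else mask$class_names)
}

empty_patch_set <- function(p, b, class_names) {
  patch_set(array(numeric(0), c(0L, p, p, b)),
            labels = NULL, centers = matrix(integer(0), 0L, 2L),
            class_names = class_names)
}

# Sum of x over every full p x p window; returns (H-p+1) x (W-p+1).
window_sums <- function(x, p) {
  h <- nrow(x); w <- ncol(x)
  cs <- matrix(0, h + 1L, w + 1L)
  colcum <- apply(x, 2L, cumsum)
  if (h == 1L) colcum <- matrix(colcum, 1L, w)
  cs[-1L, -1L] <- t(apply(colcum, 1L, cumsum))
  if (w == 1L) cs[-1L, -1L] <- colcum
  i <- seq_len(h - p + 1L)
  j <- seq_len(w - p + 1L)
  cs[i + p, j + p, drop = FALSE] - cs[i, j + p, drop = FALSE] -
    cs[i + p, j, drop = FALSE] + cs[i, j, drop = FALSE]
}
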