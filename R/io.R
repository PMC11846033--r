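# TIFF readers/writers and the sidecar metadata format.
#
# Raw acquisitions are stored as multi-page 16-bit unsigned integer TIFF
# (camera-count semantics, exact round trip) with a plain-text sidecar
# `<stem>.meta` holding pixel metadata. Reconstructed volumes are
# written as 32-bit float TIFF scaled into [0, 1] with the scale
# recorded in the sidecar.

.sidecarPath <- function(path) paste0(sub("\\.tiff?$", "", path), ".meta")

.writeSidecar <- function(path, kv) {
  writeLines(sprintf("%s = %s", names(kv),
                     vapply(kv, function(v) paste(format(v, digits = 17),
                                                  collapse = " "), "")),
             .sidecarPath(path))
}

.readSidecar <- function(path) {
  f <- .sidecarPath(path)
  if (!file.exists(f)) stop("missing sidecar metadata file: ", f)
  lines <- trimws(readLines(f))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(x) {
    v <- trimws(x[2])
    num <- suppressWarnings(as.numeric(strsplit(v, "\\s+")[[1]]))
    if (anyNA(num)) v else num
  })
  names(vals) <- vapply(kv, function(x) trimws(x[1]), "")
  vals
}

# page order dialects: which of (phase, angle, z) varies fastest.
# "PAZ" = phase fastest, then angle, then z (canonical), etc.
.layoutOrder <- function(layout) {
  switch(layout,
         PAZ = c("phase", "angle", "z"),
         APZ = c("angle", "phase", "z"),
         ZAP = c("z", "angle", "phase"),
         stop("unknown layout token: ", layout,
              " (expected PAZ, APZ, ZAP, or explicit)"))
}

#' Read a raw 3D-SIM acquisition from TIFF
#'
#' Reads a multi-page TIFF whose page count is divisible by 15 and
#' reorders the pages into the canonical (angle, phase, z) organisation
#' given the declared instrument dialect. The dialect is never sniffed:
#' `layout` states which index varies fastest across pages (e.g. `"PAZ"`
#' means phase fastest, then angle, then z). `layout = "explicit"`
#' requires `pageIndex`, a `n x 3` matrix giving (angle, phase, z) of
#' every page. Odd lateral sizes are padded by one row/column (edge
#' replication) to keep the grid even.
#'
#' Metadata comes from the sidecar `<stem>.meta` file unless supplied
#' directly.
#'
#' @param path TIFF path.
#' @param layout `"PAZ"`, `"APZ"`, `"ZAP"`, or `"explicit"`.
#' @param pageIndex page index matrix for `layout = "explicit"`.
#' @param lateralPixelNm,axialStepNm,wavelengthEmNm,na optional metadata
#'   overriding the sidecar.
#' @return a [RawStack-class].
#' @export
readRawStack <- function(path, layout = "PAZ", pageIndex = NULL,
                         lateralPixelNm = NULL, axialStepNm = NULL,
                         wavelengthEmNm = NULL, na = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  n <- length(pages)
  if (n %% 15L != 0L)
    stop(sprintf("pages (%d) not divisible by 15", n))
  nz <- n %/% 15L
  meta <- tryCatch(.readSidecar(path), error = function(e) list())
  lateralPixelNm <- lateralPixelNm %||% meta$lateral_pixel_nm %||%
    stop("lateralPixelNm not given and not in sidecar")
  axialStepNm <- axialStepNm %||% meta$axial_step_nm %||% 125
  wavelengthEmNm <- wavelengthEmNm %||% meta$wavelength_em_nm %||% 525
  na <- na %||% meta$na %||% 1.4

  if (layout == "explicit") {
    if (is.null(pageIndex) || !all(dim(pageIndex) == c(n, 3L)))
      stop("layout = 'explicit' requires an n x 3 pageIndex (angle, phase, z)")
    idx <- pageIndex
  } else {
    ord <- .layoutOrder(layout)
    sizes <- c(phase = 5L, angle = 3L, z = nz)[ord]
    grid <- expand.grid(a = seq_len(sizes[1]), b = seq_len(sizes[2]),
                        c = seq_len(sizes[3]))
    idx <- matrix(0L, n, 3L)
    colnames(idx) <- c("angle", "phase", "z")
    idx[, ord[1]] <- grid$a; idx[, ord[2]] <- grid$b; idx[, ord[3]] <- grid$c
  }
  p1 <- pages[[1]]
  ny <- nrow(p1); nx <- ncol(p1)
  nyp <- ny + ny %% 2L; nxp <- nx + nx %% 2L
  side <- max(nyp, nxp)
  data <- array(0, c(side, side, nz, 5L, 3L))
  for (k in seq_len(n)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]
    img <- matrix(0, side, side)
    img[seq_len(ny), seq_len(nx)] <- pg
    if (side > ny) img[(ny + 1):side, ] <- img[rep(ny, side - ny), ]
    if (side > nx) img[, (nx + 1):side] <- img[, rep(nx, side - nx)]
    data[, , idx[k, 3], idx[k, 2], idx[k, 1]] <- img
  }
  RawStack(data, lateralPixelNm, axialStepNm, wavelengthEmNm, na)
}

#' Write a raw acquisition as 16-bit TIFF plus sidecar
#'
#' Pages in canonical PAZ order (phase fastest, then angle, then z);
#' integer counts are stored losslessly in 16 bits. A plain-text sidecar
#' records the pixel metadata (and, for simulated stacks, any
#' ground-truth parameters passed in `truth`).
#'
#' @param stack a [RawStack-class] with integer counts in \[0, 65535\].
#' @param path output TIFF path.
#' @param truth optional named list of ground-truth values to record in
#'   the sidecar (e.g. true wavevectors of a simulation).
#' @return `path`, invisibly.
#' @export
writeRawStack <- function(stack, path, truth = NULL) {
  d <- dim(stack@data)
  if (max(stack@data) > 65535 || any(stack@data != round(stack@data)))
    stop("raw stacks must hold integer counts in [0, 65535] for 16-bit storage")
  pages <- vector("list", d[3] * 15L)
  k <- 1L
  for (z in seq_len(d[3])) for (a in 1:3) for (p in 1:5) {
    pages[[k]] <- stack@data[, , z, p, a] / 65535
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  kv <- list(lateral_pixel_nm = stack@lateralPixelNm,
             axial_step_nm = stack@axialStepNm,
             wavelength_em_nm = stack@wavelengthEmNm,
             na = stack@na)
  if (!is.null(truth)) kv <- c(kv, truth)
  .writeSidecar(path, kv)
  invisible(path)
}

#' Write / read a reconstructed volume as 32-bit float TIFF
#'
#' Values are scaled into \[0, 1\] for storage; the scale and offset are
#' recorded in the sidecar together with the stage tag and pixel
#' metadata, and undone on reading.
#'
#' @param vol an [SRVolume-class].
#' @param path output TIFF path (one page per z plane).
#' @return `path` (write) / an [SRVolume-class] (read).
#' @export
writeSRVolume <- function(vol, path) {
  d <- dim(vol@data)
  rng <- range(vol@data)
  scale <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
  pages <- lapply(seq_len(d[3]),
                  function(z) (vol@data[, , z] - rng[1]) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  .writeSidecar(path, list(stage = vol@stage,
                           lateral_pixel_nm = vol@lateralPixelNm,
                           axial_step_nm = vol@axialStepNm,
                           offset = rng[1], scale = scale))
  invisible(path)
}

#' @rdname writeSRVolume
#' @export
readSRVolume <- function(path) {
  meta <- .readSidecar(path)
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (z in seq_along(pages)) {
    pg <- pages[[z]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]
    arr[, , z] <- pg * meta$scale + meta$offset
  }
  SRVolume(arr, meta$stage, meta$lateral_pixel_nm, meta$axial_step_nm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
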