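#' Load a segmented label image
#'
#' Reads a grayscale PNG or TIFF raster of a segmented cross-section and maps
#' its distinct values onto the three compartments. Typical use: segmented
#' electron micrographs exported as 8-bit images with one gray level per
#' compartment. Non-square images are accepted and recorded as rectangular
#' grids.
#'
#' @param path Image file (`.png`, `.tif`/`.tiff`).
#' @param label_mapping Named vector mapping raw integer values (0-255 scale)
#'   to compartments, e.g. `c("0" = "extra", "128" = "intra",
#'   "255" = "myelin")`.
#' @param pixel_size Physical pixel size, um.
#' @return A [label_map()].
#' @export
load_label_image <- function(path, label_mapping, pixel_size) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = , tiff = tiff::readTIFF(path),
                stop("unsupported image format: .", ext))
  if (length(dim(img)) == 3) img <- img[, , 1]
  raw <- round(img * 255)
  vals <- sort(unique(as.integer(raw)))
  if (length(vals) > 256) stop("more than 256 distinct values")
  known <- as.integer(names(label_mapping))
  missing_vals <- setdiff(vals, known)
  if (length(missing_vals))
    stop("image values not covered by label_mapping: ",
         paste(missing_vals, collapse = ", "))
  code <- c(extra = LBL_EXTRA, intra = LBL_INTRA, myelin = LBL_MYELIN)
  lut <- integer(256)
  lut[known + 1L] <- code[label_mapping[as.character(known)]]
  # image rows run top-to-bottom; flip to the lower-left-origin convention
  # and put x on the first index
  lab <- t(raw[rev(seq_len(nrow(raw))), , drop = FALSE])
  lab <- matrix(lut[lab + 1L], nrow(lab), ncol(lab))
  grid <- grid_spec(nrow(lab), nrow(lab) * pixel_size)
  if (ncol(lab) != nrow(lab))
    message("non-square image: ", nrow(lab), " x ", ncol(lab),
            " px recorded as rectangular raster")
  label_map(lab, grid)
}

#' Write a label map as an 8-bit image
#'
#' Inverse of [load_label_image()] with values 0 (extra), 128 (intra) and
#' 255 (myelin).
#'
#' @param map A [label_map()].
#' @param path Output `.png` or `.tif` path.
#' @export
write_label_image <- function(map, path) {
  vals <- c(0, 128, 255)[map$labels + 1L]
  img <- matrix(vals / 255, nrow(map$labels), ncol(map$labels))
  # back to image convention: transpose and top-to-bottom rows
  img <- t(img)[rev(seq_len(ncol(map$labels))), , drop = FALSE]
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(img, path),
         tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = 8),
         stop("unsupported image format: .", ext))
  invisible(path)
}

#' Portable text array dump
#'
#' Lossless plain-text serialization of a raster (label map or field map):
#' a one-line JSON header followed by one row of whitespace-separated values
#' per matrix column.
#'
#' @param x A [label_map()] or `field_map`.
#' @param path Output path.
#' @export
write_array_dump <- function(x, path) {
  if (inherits(x, "label_map")) {
    m <- x$labels; kind <- "labels"
  } else if (inherits(x, "field_map")) {
    m <- x$delta_f; kind <- "delta_f"
  } else stop("unsupported object")
  hdr <- jsonlite::toJSON(list(format = "wmgre_array", kind = kind,
                               n = nrow(m), ncol = ncol(m),
                               extent = x$grid$extent,
                               periodic = x$periodic),
                          auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(t(m), con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an array dump written by [write_array_dump()]
#' @param path File path.
#' @return A [label_map()] or `field_map`, per the stored kind.
#' @export
read_array_dump <- function(path) {
  hdr <- jsonlite::fromJSON(readLines(path, n = 1))
  if (!identical(hdr$format, "wmgre_array")) stop("not an array dump")
  m <- t(as.matrix(utils::read.table(path, skip = 1)))
  dimnames(m) <- NULL
  grid <- grid_spec(hdr$n, hdr$extent)
  if (hdr$kind == "labels") {
    storage.mode(m) <- "integer"
    label_map(m, grid, periodic = hdr$periodic)
  } else {
    field_map(m, grid, periodic = hdr$periodic)
  }
}
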