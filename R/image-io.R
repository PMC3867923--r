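# Grayscale image I/O.
#
# Images are plain integer matrices with values in [0, 255] (row = image
# row). PNG goes through the png package; 8-bit uncompressed palette BMP --
# the format clinical archives in this line of work commonly export -- is
# read and written directly since no installed package handles BMP.

#' Read a grayscale image
#'
#' Reads an 8-bit PNG or uncompressed 8-bit BMP into an integer matrix with
#' values in `[0, 255]`. Multi-channel PNG input is converted to luminance
#' with the Rec. 601 weights (0.299, 0.587, 0.114).
#'
#' @param path Path to a `.png` or `.bmp` file.
#' @return An integer matrix (rows x cols) of intensities in `[0, 255]`.
#' @export
read_gray_image <- function(path) {
  if (!is.character(path) || length(path) != 1) {
    stop_param("`path` must be a single file path")
  }
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path), path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = read_png_gray(path),
    bmp = read_bmp_gray(path),
    stop_param(sprintf("unsupported image format '.%s' (need PNG or BMP): %s",
                       ext, path))
  )
  assert_gray_image(img, "image")
  img
}

read_png_gray <- function(path) {
  arr <- tryCatch(png::readPNG(path),
                  error = function(e) stop_io(
                    sprintf("cannot read PNG %s: %s", path, conditionMessage(e)),
                    path))
  if (length(dim(arr)) == 3) {
    nc <- dim(arr)[3]
    if (nc >= 3) {
      arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr <- arr[, , 1] # gray (+alpha)
    }
  }
  matrix(as.integer(round(arr * 255)), nrow(arr), ncol(arr))
}

#' Write a grayscale image
#'
#' Writes an integer matrix of intensities in `[0, 255]` as an 8-bit
#' grayscale PNG or an uncompressed 8-bit palette BMP, chosen by the file
#' extension. Both formats are lossless, so write/read round-trips are
#' pixel-identical.
#'
#' @param img Integer matrix with values in `[0, 255]`.
#' @param path Output path ending in `.png` or `.bmp`.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path) {
  assert_gray_image(img)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(matrix(as.integer(round(img)), nrow(img)) / 255, path),
    bmp = write_bmp_gray(img, path),
    stop_param(sprintf("unsupported output format '.%s' (need PNG or BMP)", ext))
  )
  invisible(path)
}

# --- minimal 8-bit BMP (BITMAPINFOHEADER, uncompressed, gray palette) ------

read_bmp_gray <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  if (!identical(rawToChar(magic), "BM")) {
    stop_io(sprintf("not a BMP file: %s", path), path)
  }
  readBin(con, "integer", 1, 4, endian = "little")          # file size
  readBin(con, "integer", 2, 2, endian = "little")          # reserved
  offset <- readBin(con, "integer", 1, 4, endian = "little")
  hdr_size <- readBin(con, "integer", 1, 4, endian = "little")
  if (hdr_size < 40) stop_io("unsupported BMP header", path)
  width  <- readBin(con, "integer", 1, 4, endian = "little")
  height <- readBin(con, "integer", 1, 4, endian = "little")
  readBin(con, "integer", 1, 2, endian = "little")          # planes
  bpp <- readBin(con, "integer", 1, 2, endian = "little")
  compression <- readBin(con, "integer", 1, 4, endian = "little")
  if (bpp != 8 || compression != 0) {
    stop_io("only uncompressed 8-bit BMP is supported", path)
  }
  readBin(con, "integer", 5, 4, endian = "little")          # rest of DIB
  n_colors <- 256
  pal <- readBin(con, "integer", n_colors * 4, 1, signed = FALSE)
  pal <- matrix(pal, nrow = 4)                              # B, G, R, 0
  gray <- round(0.299 * pal[3, ] + 0.587 * pal[2, ] + 0.114 * pal[1, ])
  seek(con, offset)
  pad <- (4 - width %% 4) %% 4
  px <- readBin(con, "integer", (width + pad) * abs(height), 1, signed = FALSE)
  rows <- matrix(px, ncol = width + pad, byrow = TRUE)[, seq_len(width), drop = FALSE]
  if (height > 0) rows <- rows[rev(seq_len(height)), , drop = FALSE] # bottom-up
  matrix(as.integer(gray[rows + 1]), nrow = abs(height), ncol = width)
}

write_bmp_gray <- function(img, path) {
  img <- matrix(as.integer(round(img)), nrow(img))
  h <- nrow(img); w <- ncol(img)
  pad <- (4 - w %% 4) %% 4
  data_size <- (w + pad) * h
  offset <- 14L + 40L + 1024L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  writeBin(as.integer(offset + data_size), con, 4, endian = "little")
  writeBin(0L, con, 4, endian = "little")
  writeBin(as.integer(offset), con, 4, endian = "little")
  writeBin(40L, con, 4, endian = "little")
  writeBin(as.integer(w), con, 4, endian = "little")
  writeBin(as.integer(h), con, 4, endian = "little")
  writeBin(as.raw(c(1, 0, 8, 0)), con)                      # planes, bpp
  writeBin(0L, con, 4, endian = "little")                   # compression
  writeBin(as.integer(data_size), con, 4, endian = "little")
  writeBin(c(2835L, 2835L), con, 4, endian = "little")      # 72 dpi
  writeBin(c(256L, 0L), con, 4, endian = "little")          # colors used/important
  pal <- as.raw(rbind(0:255, 0:255, 0:255, 0L))             # B G R 0 gray ramp
  writeBin(pal, con)
  body <- rbind(t(img[rev(seq_len(h)), , drop = FALSE]),
                matrix(0L, nrow = pad, ncol = h))
  writeBin(as.raw(body), con)
  invisible(path)
}
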