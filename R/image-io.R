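# PGM is the native format of the MIAS mammography database; both the ASCII
# (P2) and binary (P5) dialects are supported at 8 and 16 bits. No
# pre-installed package reads PGM, so the format is parsed here directly.

#' Read a PGM image
#'
#' Supports ASCII (P2) and binary (P5) portable graymaps with maxval up to
#' 65535 (16-bit values are big-endian per the format). Intensities are
#' normalized to `[0, 1]` on read.
#'
#' @param path file path.
#' @return gray image matrix in `[0, 1]`.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || ch == "") stop("unexpected end of PGM header")
      if (ch == "#") {  # comment to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch %in% c("\n", "\r", "")) break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok) else next
      }
      tok <- paste0(tok, ch)
    }
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P5")) stop("not a PGM file (magic ", magic, ")")
  width <- as.integer(read_token())
  height <- as.integer(read_token())
  maxval <- as.integer(read_token())
  n <- width * height
  if (magic == "P5") {
    size <- if (maxval > 255) 2L else 1L
    raw_vals <- readBin(con, "integer", n = n, size = size, signed = FALSE,
                        endian = "big")
    vals <- raw_vals
  } else {
    txt <- readChar(con, file.size(path), useBytes = TRUE)
    vals <- as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1]])[seq_len(n)]
  }
  img <- matrix(vals, nrow = height, ncol = width, byrow = TRUE)
  normalize_intensity(img, bit_depth = NULL, max_value = maxval)
}

#' Write a PGM image
#'
#' @param image gray image matrix in `[0, 1]`.
#' @param path output path.
#' @param maxval maximum gray level (255 or 65535).
#' @param ascii write the ASCII (P2) dialect instead of binary (P5).
#' @export
write_pgm <- function(image, path, maxval = 255, ascii = FALSE) {
  vals <- round(pmin(pmax(image, 0), 1) * maxval)
  vals <- matrix(as.integer(vals), nrow(image), ncol(image))
  flat <- as.integer(t(vals))  # row-major per the format
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(image), nrow(image)), as.character(maxval)),
               con)
    writeLines(paste(flat, collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n%d\n", ncol(image), nrow(image), maxval),
              con, eos = NULL)
    size <- if (maxval > 255) 2L else 1L
    writeBin(flat, con, size = size, endian = "big")
  }
  invisible(path)
}

#' Read a PNG image as a gray image
#'
#' Requires the optional `png` package; color images are converted to
#' luminance by channel averaging.
#'
#' @param path file path.
#' @export
read_png_gray <- function(path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG input; use PGM instead")
  }
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3L, dim(a)[3]), drop = FALSE],
                                       c(1, 2), mean)
  gray_image(a)
}

#' Write a gray image as PNG
#'
#' Requires the optional `png` package.
#'
#' @param image gray image matrix in `[0, 1]`.
#' @param path output path.
#' @export
write_png_gray <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG output; use PGM instead")
  }
  png::writePNG(matrix(pmin(pmax(image, 0), 1), nrow(image)), path)
  invisible(path)
}

#' Read a gray image, dispatching on file extension
#'
#' @param path `.pgm` or `.png` file.
#' @export
read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         pgm = read_pgm(path),
         png = read_png_gray(path),
         stop("unsupported image format: .", ext))
}
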