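# Minimal portable anymap (PNM) raster I/O. No raster-image package is part
# of the supported environment, and PNM is a plain, dependency-free format:
# P5 (grayscale) / P6 (RGB) binary, maxval 255 or 65535 (big-endian).

#' Write an image or mask as PNM
#'
#' 2D matrices are written as PGM (P5), H x W x 3 arrays as PPM (P6).
#' Values are expected in `[0, 1]` and are quantized to `maxval` levels.
#'
#' @param image Numeric matrix (grayscale) or H x W x 3 array (RGB).
#' @param path Output file path (conventionally `.pgm` / `.ppm`).
#' @param maxval 255 (8-bit) or 65535 (16-bit), default 255.
#' @return `path`, invisibly.
#' @export
write_pnm <- function(image, path, maxval = 255) {
  stopifnot(maxval %in% c(255L, 65535L))
  rgb <- length(dim(image)) == 3
  if (rgb) stopifnot(dim(image)[3] == 3)
  h <- dim(image)[1]; w <- dim(image)[2]
  v <- pmin(pmax(as.numeric(image), 0), 1)
  q <- as.integer(round(v * maxval))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("%s\n%d %d\n%d\n", if (rgb) "P6" else "P5", w, h, maxval),
            con, eos = NULL)
  if (rgb) {
    # interleave channels row-major: R G B per pixel
    a <- array(q, dim = c(h, w, 3))
    px <- aperm(a, c(3, 2, 1))  # channel fastest, then x, then y
    q <- as.integer(px)
  } else {
    q <- as.integer(t(matrix(q, h, w)))
  }
  if (maxval == 255L) {
    writeBin(as.raw(q), con)
  } else {
    writeBin(q, con, size = 2, endian = "big")
  }
  invisible(path)
}

#' Read a PNM image
#'
#' Supports binary P5/P6 and ASCII P2/P3, maxval up to 65535.
#'
#' @param path File path.
#' @return Numeric matrix (P5/P2) or H x W x 3 array (P6/P3) with values
#'   scaled to `[0, 1]`.
#' @export
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- pnm_tokens(con, 4L)
  magic <- tok[1]
  w <- as.integer(tok[2]); h <- as.integer(tok[3]); maxval <- as.integer(tok[4])
  n <- w * h * if (magic %in% c("P3", "P6")) 3L else 1L
  if (magic %in% c("P5", "P6")) {
    if (maxval <= 255) {
      vals <- as.integer(readBin(con, "raw", n = n))
    } else {
      vals <- readBin(con, "integer", n = n, size = 2, signed = FALSE,
                      endian = "big")
    }
  } else if (magic %in% c("P2", "P3")) {
    vals <- as.integer(pnm_tokens(con, n))
  } else {
    stop("unsupported PNM magic: ", magic)
  }
  x <- vals / maxval
  if (magic %in% c("P3", "P6")) {
    a <- array(x, dim = c(3, w, h))
    aperm(a, c(3, 2, 1))
  } else {
    t(matrix(x, w, h))
  }
}

# read whitespace-separated tokens, skipping '#' comments
pnm_tokens <- function(con, n) {
  out <- character(0)
  buf <- character(0)
  in_comment <- FALSE
  while (length(out) < n) {
    ch <- readChar(con, 1, useBytes = TRUE)
    if (length(ch) == 0) {
      if (length(buf)) out <- c(out, paste(buf, collapse = ""))
      break
    }
    if (in_comment) {
      if (ch %in% c("\n", "\r")) in_comment <- FALSE
      next
    }
    if (ch == "#") { in_comment <- TRUE; next }
    if (grepl("[[:space:]]", ch)) {
      if (length(buf)) { out <- c(out, paste(buf, collapse = "")); buf <- character(0) }
    } else {
      buf <- c(buf, ch)
    }
  }
  if (length(out) < n) stop("truncated PNM header/data")
  out
}
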