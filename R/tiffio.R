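# Minimal baseline TIFF I/O (single-channel, uncompressed, little-endian).
# No TIFF library is available in the supported dependency set, so the
# package ships a codec for the small subset it needs: 8/16-bit grayscale,
# strip-organized, no compression. Round-trip is exact for 16-bit data.

#' Write a matrix as a 16-bit grayscale TIFF
#'
#' Values are rescaled from `[0, 1]` to the 16-bit range (values outside
#' `[0, 1]` are clipped on export only).
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_tiff_gray16 <- function(image, path) {
  H <- nrow(image); W <- ncol(image)
  px <- as.integer(round(clamp01(image) * 65535))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(c(42L), con, size = 2, endian = "little")
  data_off <- 8L
  n_bytes <- W * H * 2L
  ifd_off <- data_off + n_bytes
  writeBin(ifd_off, con, size = 4, endian = "little")
  # pixel data, row-major
  writeBin(as.integer(t(matrix(px, H, W))), con, size = 2, endian = "little")
  tags <- list(
    c(256L, 3L, 1L, W), c(257L, 3L, 1L, H), c(258L, 3L, 1L, 16L),
    c(259L, 3L, 1L, 1L), c(262L, 3L, 1L, 1L), c(273L, 4L, 1L, data_off),
    c(277L, 3L, 1L, 1L), c(278L, 3L, 1L, H), c(279L, 4L, 1L, n_bytes),
    c(339L, 3L, 1L, 1L)
  )
  writeBin(length(tags), con, size = 2, endian = "little")
  for (tg in tags) {
    writeBin(tg[1], con, size = 2, endian = "little")
    writeBin(tg[2], con, size = 2, endian = "little")
    writeBin(tg[3], con, size = 4, endian = "little")
    if (tg[2] == 3L) {
      writeBin(tg[4], con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(tg[4], con, size = 4, endian = "little")
    }
  }
  writeBin(0L, con, size = 4, endian = "little")
  invisible(path)
}

#' Read a grayscale TIFF written by this package (baseline subset)
#'
#' Supports uncompressed single-channel 8- or 16-bit little-endian TIFFs in
#' one or more strips. Returns intensities rescaled to `[0, 1]`.
#'
#' @param path file path.
#' @return numeric matrix.
#' @export
read_tiff_gray <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.numeric(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
  if (rawToChar(raw[1:2]) != "II") stop_config("only little-endian TIFF supported")
  ifd <- u32(4)
  n <- u16(ifd)
  tags <- list()
  for (i in seq_len(n)) {
    e <- ifd + 2 + (i - 1) * 12
    id <- u16(e)
    typ <- u16(e + 2)
    cnt <- u32(e + 4)
    val <- if (typ == 3L && cnt == 1) u16(e + 8) else u32(e + 8)
    tags[[as.character(id)]] <- list(typ = typ, cnt = cnt, val = val, off = e + 8)
  }
  W <- tags[["256"]]$val; H <- tags[["257"]]$val
  bits <- tags[["258"]]$val %||% 8
  if ((tags[["259"]]$val %||% 1) != 1) stop_config("compressed TIFF not supported")
  get_vec <- function(tag) {
    t <- tags[[tag]]
    if (t$cnt == 1) return(t$val)
    base <- t$val
    sz <- if (t$typ == 3L) 2 else 4
    vapply(seq_len(t$cnt), function(j) {
      o <- base + (j - 1) * sz
      if (sz == 2) u16(o) else u32(o)
    }, numeric(1))
  }
  offs <- get_vec("273")
  counts <- get_vec("279")
  bpp <- bits / 8
  vals <- numeric(0)
  for (j in seq_along(offs)) {
    nb <- counts[j]
    bytes <- raw[offs[j] + seq_len(nb)]
    v <- if (bits == 16) {
      readBin(bytes, "integer", n = nb / 2, size = 2, signed = FALSE,
              endian = "little")
    } else {
      as.integer(bytes)
    }
    vals <- c(vals, v)
  }
  m <- matrix(vals, nrow = H, ncol = W, byrow = TRUE)
  m / (2^bits - 1)
}
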