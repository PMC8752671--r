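# Minimal multi-page TIFF I/O for image stacks: baseline (uncompressed),
# 8-bit grayscale, little-endian, one page per (frame, channel), pages
# channel-interleaved in frame-major order (page = frame * n_channels +
# channel). Metadata travels in the first page's ImageDescription tag.
# Implemented in-package because no TIFF-capable R package is available in
# the target environment.

TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
               Compression = 259L, Photometric = 262L,
               ImageDescription = 270L, StripOffsets = 273L,
               RowsPerStrip = 278L, StripByteCounts = 279L)

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

#' Write an image stack as a multi-page TIFF
#'
#' Pages are 8-bit grayscale, uncompressed, in frame-major channel-interleaved
#' order (`page = frame * n_channels + channel`); stack metadata (frame count,
#' channel semantics, frame interval, pixel size) is stored in the first
#' page's ImageDescription tag so that [read_stack()] round-trips exactly.
#'
#' @param stack An `image_stack` from [simulate_field()] or [read_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$data)
  nf <- d[1]; H <- d[2]; W <- d[3]; nc <- d[4]
  desc <- sprintf(
    "cognatevid;n_frames=%d;n_channels=%d;H=%d;W=%d;frame_interval=%g;pixel_size=%g;channels=%s",
    nf, nc, H, W, stack$frame_interval, stack$pixel_size,
    paste(stack$channels, collapse = ","))
  desc_raw <- c(charToRaw(desc), as.raw(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), as.raw(c(42, 0))), con)  # header, magic 42
  n_pages <- nf * nc
  strip_len <- H * W
  # layout: 8-byte header, then per page [pixel strip][IFD (+desc on page 1)]
  offset <- 8L
  first_ifd <- offset + strip_len
  writeBin(u32(first_ifd), con)
  for (pg in seq_len(n_pages) - 1L) {
    f <- pg %/% nc + 1L
    ch <- pg %% nc + 1L
    # pixel data row-major (TIFF rows), 8-bit
    img <- stack$data[f, , , ch]
    writeBin(as.raw(pmin(pmax(as.integer(t(img)), 0L), 255L)), con)
    has_desc <- pg == 0L
    n_entries <- if (has_desc) 9L else 8L
    ifd_off <- offset + strip_len
    ifd_size <- 2L + n_entries * 12L + 4L
    desc_off <- ifd_off + ifd_size
    strip_next <- ifd_off + ifd_size + (if (has_desc) length(desc_raw) else 0L)
    next_off <- if (pg == n_pages - 1L) 0L else strip_next + strip_len
    entry <- function(tag, type, count, value) {
      c(u16(tag), u16(type), u32(count), u32(value))
    }
    entries <- list(
      entry(TIFF_TAGS["ImageWidth"], 3L, 1L, W),
      entry(TIFF_TAGS["ImageLength"], 3L, 1L, H),
      entry(TIFF_TAGS["BitsPerSample"], 3L, 1L, 8L),
      entry(TIFF_TAGS["Compression"], 3L, 1L, 1L),
      entry(TIFF_TAGS["Photometric"], 3L, 1L, 1L)
    )
    if (has_desc) {
      entries <- c(entries, list(
        entry(TIFF_TAGS["ImageDescription"], 2L, length(desc_raw), desc_off)))
    }
    entries <- c(entries, list(
      entry(TIFF_TAGS["StripOffsets"], 4L, 1L, offset),
      entry(TIFF_TAGS["RowsPerStrip"], 3L, 1L, H),
      entry(TIFF_TAGS["StripByteCounts"], 4L, 1L, strip_len)
    ))
    # entries must be sorted by tag id
    tags <- vapply(entries, function(e) {
      as.integer(e[1]) + 256L * as.integer(e[2])
    }, 0L)
    entries <- entries[order(tags)]
    writeBin(u16(n_entries), con)
    for (e in entries) writeBin(e, con)
    writeBin(u32(next_off), con)
    if (has_desc) writeBin(desc_raw, con)
    offset <- strip_next
  }
  invisible(path)
}

read_u16 <- function(raw, off) {
  as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
}
read_u32 <- function(raw, off) {
  as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2]) +
    65536L * as.integer(raw[off + 3]) + 16777216L * as.integer(raw[off + 4])
}

#' Read a multi-page TIFF written by [write_stack()]
#'
#' @param path TIFF file path.
#' @return An `image_stack`.
#' @export
read_stack <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 8 || rawToChar(bytes[1:2]) != "II" ||
      read_u16(bytes, 2) != 42L) {
    stop_cv("not a little-endian TIFF file", "cognatevid_tiff_error")
  }
  ifd_off <- read_u32(bytes, 4)
  pages <- list()
  desc <- NULL
  page <- 0L
  while (ifd_off != 0L) {
    page <- page + 1L
    if (ifd_off + 2 > length(bytes)) {
      stop_cv(sprintf("truncated TIFF: IFD of page %d out of range", page),
              "cognatevid_tiff_error")
    }
    n <- read_u16(bytes, ifd_off)
    tags <- list()
    for (i in seq_len(n)) {
      e <- ifd_off + 2L + (i - 1L) * 12L
      if (e + 12 > length(bytes)) {
        stop_cv(sprintf("truncated TIFF: IFD entry in page %d out of range", page),
                "cognatevid_tiff_error")
      }
      tag <- read_u16(bytes, e)
      type <- read_u16(bytes, e + 2L)
      count <- read_u32(bytes, e + 4L)
      val <- read_u32(bytes, e + 8L)
      tags[[as.character(tag)]] <- list(type = type, count = count, value = val)
    }
    need <- c("256", "257", "273", "279")
    if (!all(need %in% names(tags))) {
      stop_cv(sprintf("malformed TIFF: page %d missing required tags", page),
              "cognatevid_tiff_error")
    }
    W <- tags[["256"]]$value; H <- tags[["257"]]$value
    so <- tags[["273"]]$value; sc <- tags[["279"]]$value
    if (sc != H * W || so + sc > length(bytes)) {
      stop_cv(sprintf("truncated TIFF: pixel data of page %d out of range", page),
              "cognatevid_tiff_error")
    }
    px <- as.integer(bytes[(so + 1):(so + sc)])
    pages[[page]] <- t(matrix(px, nrow = W, ncol = H))  # stored row-major
    if (page == 1L && "270" %in% names(tags)) {
      dd <- tags[["270"]]
      if (dd$value + dd$count <= length(bytes)) {
        desc <- rawToChar(bytes[(dd$value + 1):(dd$value + dd$count - 1L)])
      }
    }
    ifd_off <- read_u32(bytes, ifd_off + 2L + n * 12L)
  }
  if (is.null(desc) || !startsWith(desc, "cognatevid;")) {
    stop_cv("missing cognatevid metadata in TIFF ImageDescription",
            "cognatevid_tiff_error")
  }
  kv <- strsplit(strsplit(desc, ";", fixed = TRUE)[[1]][-1], "=", fixed = TRUE)
  meta <- setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  nf <- as.integer(meta$n_frames); nc <- as.integer(meta$n_channels)
  H <- as.integer(meta$H); W <- as.integer(meta$W)
  if (length(pages) != nf * nc) {
    stop_cv(sprintf("TIFF has %d pages, metadata promises %d",
                    length(pages), nf * nc), "cognatevid_tiff_error")
  }
  data <- array(0L, dim = c(nf, H, W, nc))
  for (pg in seq_len(nf * nc) - 1L) {
    data[pg %/% nc + 1L, , , pg %% nc + 1L] <- pages[[pg + 1L]]
  }
  structure(list(data = data,
                 frame_interval = as.numeric(meta$frame_interval),
                 pixel_size = as.numeric(meta$pixel_size),
                 channels = strsplit(meta$channels, ",", fixed = TRUE)[[1]]),
            class = "image_stack")
}
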