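# Minimal baseline TIFF codec: uncompressed 8-bit grayscale, multi-page.
# Grey values ARE the data (compound identifiers), so bit-exactness matters
# more than format breadth; anything fancier than baseline is rejected.

.tiffTypeSize <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L)

.rdInt <- function(raw, off, size, endian) {
  b <- as.integer(raw[off + seq_len(size)])
  if (endian == "little") b <- rev(b)
  v <- 0
  for (x in b) v <- v * 256 + x
  v
}

.readIfdEntries <- function(raw, off, endian) {
  n <- .rdInt(raw, off, 2L, endian)
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    e <- off + 2L + (i - 1L) * 12L
    tag <- .rdInt(raw, e, 2L, endian)
    typ <- .rdInt(raw, e + 2L, 2L, endian)
    cnt <- .rdInt(raw, e + 4L, 4L, endian)
    sz <- .tiffTypeSize[as.character(typ)]
    vals <- NULL
    if (!is.na(sz)) {
      total <- sz * cnt
      src <- if (total <= 4L) e + 8L else .rdInt(raw, e + 8L, 4L, endian)
      vals <- vapply(seq_len(cnt), function(j)
        .rdInt(raw, src + (j - 1L) * sz, sz, endian), numeric(1))
    }
    entries[[i]] <- list(tag = tag, values = vals)
  }
  list(entries = entries,
       nextIfd = .rdInt(raw, off + 2L + n * 12L, 4L, endian))
}

.tiffTag <- function(ifd, tag, default = NULL) {
  for (e in ifd$entries) if (e$tag == tag) return(e$values)
  default
}

.readTiffPages <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  order <- rawToChar(raw[1:2])
  endian <- switch(order, II = "little", MM = "big",
                   stop("not a TIFF file: ", path))
  if (.rdInt(raw, 2L, 2L, endian) != 42L)
    stop("not a TIFF file (bad magic): ", path)
  off <- .rdInt(raw, 4L, 4L, endian)
  pages <- list()
  while (off != 0L) {
    ifd <- .readIfdEntries(raw, off, endian)
    w <- .tiffTag(ifd, 256L); h <- .tiffTag(ifd, 257L)
    bits <- .tiffTag(ifd, 258L, 1)
    comp <- .tiffTag(ifd, 259L, 1)
    spp <- .tiffTag(ifd, 277L, 1)
    if (is.null(w) || is.null(h))
      stop("TIFF format error: page without dimensions in ", path)
    if (any(bits != 8) || any(spp != 1))
      stop("TIFF format error: only 8-bit single-sample grayscale is ",
           "supported (got ", paste(bits, collapse = "/"), "-bit, ",
           spp, " samples) in ", path)
    if (any(comp != 1))
      stop("TIFF format error: compressed TIFF not supported in ", path)
    offs <- .tiffTag(ifd, 273L)
    cnts <- .tiffTag(ifd, 279L)
    if (is.null(offs) || is.null(cnts))
      stop("TIFF format error: missing strip layout in ", path)
    data <- raw(0)
    for (k in seq_along(offs))
      data <- c(data, raw[offs[k] + seq_len(cnts[k])])
    if (length(data) != w * h)
      stop("TIFF format error: strip data does not cover the page in ",
           path)
    pages[[length(pages) + 1L]] <-
      t(matrix(as.integer(data), nrow = w, ncol = h))
    off <- ifd$nextIfd
  }
  pages
}

#' Read a labelled TIFF stack into a VoxelMatrix
#'
#' Reads either a multi-page 8-bit grayscale TIFF or a directory of
#' numbered single-page TIFFs (sorted by the number embedded in the file
#' name). Slice order follows page/file order. Every grey value present
#' must be declared in `labelMap`; an unknown value is an error naming the
#' value and the first slice containing it.
#'
#' @param path file or directory path.
#' @param labelMap named character vector mapping grey value to role;
#'   defaults to [defaultLabelMap()].
#' @param voxelEdge voxel edge length in mm (stacks carry no physical
#'   scale; the conventional value is 0.028).
#' @return A [VoxelMatrix-class].
#' @seealso [writeTiffStack()]
#' @examples
#' f <- tempfile(fileext = ".tif")
#' m <- VoxelMatrix(array(0L, c(2, 3, 3)), 0.028)
#' writeTiffStack(m, f)
#' readTiffStack(f)
#' @export
readTiffStack <- function(path, labelMap = defaultLabelMap(),
                          voxelEdge = 0.028) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                        full.names = TRUE)
    if (!length(files)) stop("no TIFF files found in directory ", path)
    num <- suppressWarnings(as.numeric(sub(
      ".*?([0-9]+)[^0-9]*\\.tiff?$", "\\1", basename(files),
      ignore.case = TRUE)))
    files <- files[order(num, basename(files))]
    pages <- do.call(c, lapply(files, .readTiffPages))
  } else {
    pages <- .readTiffPages(path)
  }
  dims <- unique(t(vapply(pages, dim, integer(2))))
  if (nrow(dims) != 1L)
    stop("TIFF pages differ in size; a stack must be uniform")
  labels <- array(0L, c(length(pages), dims[1L, 1L], dims[1L, 2L]))
  for (s in seq_along(pages)) labels[s, , ] <- pages[[s]]
  known <- as.integer(names(labelMap))
  for (s in seq_along(pages)) {
    vals <- unique(as.vector(pages[[s]]))
    bad <- setdiff(vals, known)
    if (length(bad))
      stop(sprintf("unknown grey value %d in slice %d (not in labelMap)",
                   bad[1L], s))
  }
  VoxelMatrix(labels, voxelEdge = voxelEdge, labelMap = labelMap,
              metadata = list(source = path))
}

.writeTiffPage <- function(con, page, offset) {
  # page: H x W integer matrix; returns offset of this page's IFD and the
  # file offset immediately after the IFD (where the next page starts).
  h <- nrow(page); w <- ncol(page)
  data <- as.raw(as.vector(t(page)))         # row-major strip
  pad <- (length(data) %% 2L) == 1L
  ifdOffset <- offset + length(data) + if (pad) 1L else 0L
  u16 <- function(v) writeBin(as.integer(v), con, size = 2L,
                              endian = "little")
  u32 <- function(v) writeBin(as.integer(v), con, size = 4L,
                              endian = "little")
  entry <- function(tag, type, count, value) {
    u16(tag); u16(type); u32(count)
    if (type == 3L) { u16(value); u16(0L) } else u32(value)
  }
  writeBin(data, con)
  if (pad) writeBin(as.raw(0L), con)
  u16(9L)                                    # entry count
  entry(256L, 4L, 1L, w)                     # ImageWidth
  entry(257L, 4L, 1L, h)                     # ImageLength
  entry(258L, 3L, 1L, 8L)                    # BitsPerSample
  entry(259L, 3L, 1L, 1L)                    # Compression: none
  entry(262L, 3L, 1L, 1L)                    # Photometric: BlackIsZero
  entry(273L, 4L, 1L, offset)                # StripOffsets
  entry(277L, 3L, 1L, 1L)                    # SamplesPerPixel
  entry(278L, 4L, 1L, h)                     # RowsPerStrip
  entry(279L, 4L, 1L, w * h)                 # StripByteCounts
  list(ifd = ifdOffset, after = ifdOffset + 2L + 9L * 12L + 4L)
}

#' Write a VoxelMatrix as a multi-page 8-bit grayscale TIFF
#'
#' Uncompressed baseline TIFF, little-endian, one page per slice;
#' bit-exact round trip with [readTiffStack()].
#'
#' @param matrix a [VoxelMatrix-class] with labels in `[0, 255]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".tif")
#' writeTiffStack(VoxelMatrix(array(1L, c(2, 3, 3)), 0.028), f)
#' @export
writeTiffStack <- function(matrix, path) {
  stopifnot(is(matrix, "VoxelMatrix"))
  labels <- matrix@labels
  if (any(labels < 0L | labels > 255L))
    stop("labels outside the 8-bit range [0, 255] cannot be written")
  d <- dim(labels)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, size = 2L, endian = "little")
  # first IFD offset: first page data starts at byte 8
  firstData <- 8L
  # compute layout up front so IFD chain offsets are known
  stripLen <- d[2L] * d[3L]
  padded <- stripLen + (stripLen %% 2L)
  ifdLen <- 2L + 9L * 12L + 4L
  pageStart <- firstData + (seq_len(d[1L]) - 1L) * (padded + ifdLen)
  writeBin(as.integer(pageStart[1L] + padded), con, size = 4L,
           endian = "little")
  for (s in seq_len(d[1L])) {
    page <- matrix(labels[s, , ], nrow = d[2L], ncol = d[3L])
    res <- .writeTiffPage(con, page, pageStart[s])
    nextIfd <- if (s < d[1L]) pageStart[s + 1L] + padded else 0L
    writeBin(as.integer(nextIfd), con, size = 4L, endian = "little")
  }
  invisible(path)
}
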