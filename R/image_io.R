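#' Read / write 2-D detector images
#'
#' Two formats are supported, selected by extension: plain-text matrices
#' (`.tsv`, `.txt`, `.dat`; whitespace-separated, one image row per line) and
#' the ESRF data format (`.edf`; ASCII header in `{}` padded to a 512-byte
#' multiple followed by a raw binary block).  EDF data types DoubleValue,
#' FloatValue, UnsignedShort, SignedInteger and UnsignedInteger are read;
#' writing always uses DoubleValue, low byte first.  (TIFF/HDF5 inputs would
#' need bindings not available in this environment.)
#'
#' @param path file path.
#' @return numeric matrix.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "edf") return(.read_edf(path))
  as.matrix(read.table(path, header = FALSE))
}

#' @rdname read_image
#' @param img numeric matrix to write.
#' @export
write_image <- function(img, path) {
  stopifnot(is.matrix(img))
  ext <- tolower(tools::file_ext(path))
  if (ext == "edf") return(.write_edf(img, path))
  write.table(img, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw_hdr <- raw(0)
  repeat {
    chunk <- readBin(con, "raw", 512)
    if (length(chunk) == 0) stop("EDF header not terminated in ", path)
    raw_hdr <- c(raw_hdr, chunk)
    if (any(chunk == charToRaw("}"))) break
    if (length(raw_hdr) > 65536) stop("EDF header not terminated in ", path)
  }
  hdr <- rawToChar(raw_hdr)
  get <- function(key, default = NULL) {
    m <- regmatches(hdr, regexec(paste0(key, "\\s*=\\s*([^;]+);"), hdr))[[1]]
    if (length(m) < 2) {
      if (is.null(default)) stop("EDF header lacks key '", key, "' in ", path)
      return(default)
    }
    trimws(m[2])
  }
  nx <- as.integer(get("Dim_1"))
  ny <- as.integer(get("Dim_2"))
  dtype <- get("DataType", "DoubleValue")
  endian <- if (identical(get("ByteOrder", "LowByteFirst"), "HighByteFirst"))
    "big" else "little"
  spec <- switch(dtype,
                 DoubleValue = list(what = "double", size = 8),
                 FloatValue = list(what = "double", size = 4),
                 UnsignedShort = list(what = "integer", size = 2, signed = FALSE),
                 SignedInteger = list(what = "integer", size = 4),
                 UnsignedInteger = list(what = "integer", size = 4),
                 stop("unsupported EDF DataType: ", dtype))
  vals <- readBin(con, spec$what, n = nx * ny, size = spec$size,
                  signed = !isFALSE(spec$signed), endian = endian)
  if (length(vals) < nx * ny) stop("EDF data block truncated in ", path)
  matrix(as.numeric(vals), nrow = ny, byrow = TRUE)  # Dim_1 is the fast axis
}

.write_edf <- function(img, path) {
  ny <- nrow(img); nx <- ncol(img)
  hdr <- paste0("{\nHeaderID = EH:000001:000000:000000 ;\n",
                "ByteOrder = LowByteFirst ;\nDataType = DoubleValue ;\n",
                sprintf("Dim_1 = %d ;\nDim_2 = %d ;\n", nx, ny),
                sprintf("Size = %d ;\n", 8 * nx * ny))
  pad <- 512 * ceiling((nchar(hdr) + 2) / 512) - nchar(hdr) - 2
  hdr <- paste0(hdr, strrep(" ", pad), "}\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  writeBin(as.vector(t(img)), con, size = 8, endian = "little")
  invisible(path)
}
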