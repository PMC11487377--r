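# Volume and manifest I/O.
#
# Volumes live one-per-exam-view in NumPy ".npy" container files holding the
# full L x H x W stack in C (row-major) order -- the layout the public
# multi-view knee-MRI datasets use -- so exported phantoms are directly
# loadable from Python and vice versa.  The reader promotes every numeric
# dtype to double.  No R package in this stack reads .npy, so the small v1/v2
# header codec is implemented here.

.npy_magic <- as.raw(c(0x93, charToRaw("NUMPY")))

.npy_descr <- c("<f8" = "double", "<f4" = "float", "|u1" = "uint8",
                "|i1" = "int8", "<i2" = "int16", "<i4" = "int32",
                "<i8" = "int64", "<u2" = "uint16")

.read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (!identical(magic, .npy_magic)) stop("not an npy file: ", path)
  ver <- readBin(con, "raw", 2L)
  hlen <- if (as.integer(ver[1]) >= 2L)
    readBin(con, "integer", 1L, size = 4L, endian = "little")
  else readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = "little")
  header <- rawToChar(readBin(con, "raw", hlen))

  descr <- sub(".*'descr'\\s*:\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order'\\s*:\\s*True", header)
  shape_str <- sub(".*'shape'\\s*:\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_str), ",")[[1]])
  if (!descr %in% names(.npy_descr))
    stop("unsupported npy dtype: ", descr)

  n <- prod(shape)
  vals <- switch(.npy_descr[[descr]],
    double = readBin(con, "double", n, size = 8L, endian = "little"),
    float  = readBin(con, "double", n, size = 4L, endian = "little"),
    uint8  = as.double(readBin(con, "integer", n, size = 1L, signed = FALSE)),
    int8   = as.double(readBin(con, "integer", n, size = 1L, signed = TRUE)),
    int16  = as.double(readBin(con, "integer", n, size = 2L, endian = "little")),
    uint16 = as.double(readBin(con, "integer", n, size = 2L, signed = FALSE,
                               endian = "little")),
    int32  = as.double(readBin(con, "integer", n, size = 4L, endian = "little")),
    int64  = readBin(con, "double", n, size = 8L, endian = "little") # lossy only > 2^53
  )
  if (descr == "<i8") {
    # reinterpret: read again properly as integers via raw
    # (int64 values in volume files are expected to be small intensities)
    seek(con, -n * 8L, origin = "current")
    raw64 <- readBin(con, "raw", n * 8L)
    m <- matrix(as.numeric(raw64), nrow = 8L)
    vals <- colSums(m * 2^(8 * (0:7)))
    neg <- m[8L, ] >= 128
    vals[neg] <- vals[neg] - 2^64
  }
  k <- length(shape)
  if (k > 1L) {
    if (fortran) dim(vals) <- shape
    else {
      dim(vals) <- rev(shape)
      vals <- aperm(vals, k:1)
    }
  }
  vals
}

.write_npy <- function(x, path, dtype = c("double", "uint8", "float")) {
  dtype <- match.arg(dtype)
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  descr <- switch(dtype, double = "<f8", float = "<f4", uint8 = "|u1")
  shape <- paste0("(", paste(d, collapse = ", "),
                  if (length(d) == 1L) ",", ")")
  header <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': %s, }",
                    descr, shape)
  pad <- 64L - ((10L + nchar(header) + 1L) %% 64L)
  if (pad == 64L) pad <- 0L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.npy_magic, con)
  writeBin(as.raw(c(1L, 0L)), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeBin(charToRaw(header), con)
  v <- if (length(d) > 1L) as.vector(aperm(x, length(d):1)) else as.vector(x)
  switch(dtype,
    double = writeBin(v, con, size = 8L, endian = "little"),
    float  = writeBin(v, con, size = 4L, endian = "little"),
    uint8  = writeBin(as.integer(round(v)), con, size = 1L))
  invisible(path)
}

#' Read a stacked-slice volume file
#'
#' Reads one exam-view volume (an \code{L x H x W} array stored in an
#' \code{.npy} container) and promotes it to double precision.
#'
#' @param path path to the volume file.
#' @param view acquisition plane tag to attach.
#' @param examId exam identifier to attach (default: file stem).
#' @return An \linkS4class{ExamVolume}.
#' @seealso [writeVolume()]
#' @export
readVolume <- function(path, view = "axial", examId = NULL) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  x <- .read_npy(path)
  if (length(dim(x)) != 3L)
    stop("expected a 3-D (L x H x W) array in ", path, ", got ",
         length(dim(x)) %||% 1L, " dimensions")
  if (is.null(examId))
    examId <- sub("\\.[^.]*$", "", basename(path))
  examVolume(x, view = view, examId = examId)
}

#' Write a stacked-slice volume file
#'
#' @param vol an \linkS4class{ExamVolume} or a 3-D array.
#' @param path output path (\code{.npy}).
#' @param dtype on-disk element type.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(vol, path, dtype = c("double", "uint8", "float")) {
  x <- if (is(vol, "ExamVolume")) vol@data else vol
  if (length(dim(x)) != 3L) stop("volume must be a 3-D array")
  .write_npy(x, path, match.arg(dtype))
}

#' Read a CSV label manifest
#'
#' The manifest has header \code{exam_id,label,axial,coronal,sagittal} with
#' one row per exam; record order is preserved.
#'
#' @param path CSV file path.
#' @param splitTag split the manifest belongs to.
#' @return A \linkS4class{DatasetManifest}.
#' @export
readManifest <- function(path, splitTag = "train") {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(exam_id = "character"))
  need <- c("exam_id", "label", .VIEWS)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$exam_id))
    stop("duplicate exam_id in manifest: ",
         paste(unique(df$exam_id[duplicated(df$exam_id)]), collapse = ", "))
  if (!all(df$label %in% c(0L, 1L)))
    stop("labels must be 0 or 1")
  datasetManifest(df[need], splitTag = splitTag)
}

#' Write a CSV label manifest
#'
#' @param manifest a \linkS4class{DatasetManifest}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  utils::write.csv(manifest@records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Positive-class prevalence of a manifest
#'
#' Fraction of exams labelled as ACL tears; the training-split prevalence
#' feeds the class-balance weight of the loss (alpha = 1 - prevalence).
#'
#' @param manifest a \linkS4class{DatasetManifest}.
#' @return Fraction in [0, 1].
#' @examples
#' m <- datasetManifest(data.frame(exam_id = c("a", "b"), label = c(1, 0),
#'                                 axial = "", coronal = "", sagittal = ""))
#' classPrevalence(m)  # 0.5
#' @export
classPrevalence <- function(manifest) {
  r <- manifest@records
  if (nrow(r) == 0L) stop("empty manifest")
  sum(r$label) / nrow(r)
}
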