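#' Read and write frames and masks
#'
#' Frames are RGB arrays (rows x cols x 3) with intensities in [0, 1];
#' masks are single-channel integer matrices with values in {0, 255}.
#' PNG is the on-disk format for both.
#'
#' @param path file path.
#' @return `readFrame` returns an H x W x 3 array; `readMask` an integer
#'   matrix in {0, 255}.
#' @export
readFrame <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' @rdname readFrame
#' @param frame H x W x 3 array in [0, 1].
#' @export
writeFrame <- function(frame, path) {
  png::writePNG(frame, path)
  invisible(path)
}

#' @rdname readFrame
#' @export
readMask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(round(m) * 255L), nrow(m), ncol(m))
}

#' @rdname readFrame
#' @param mask integer matrix in {0, 255}.
#' @export
writeMask <- function(mask, path) {
  png::writePNG(mask / 255, path)
  invisible(path)
}

# CSV with a provenance comment header; read back with comment.char = "#"
.writeCsvProv <- function(df, path, seed = NA, extra = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# DropletCascade %s",
                       as.character(utils::packageVersion("DropletCascade"))),
               sprintf("# seed: %s", seed), extra), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

.readCsvProv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

# Resize a matrix; bilinear for intensity data, nearest for labels.
# EBImage::resize treats the first matrix dimension as image width, which
# maps onto our row axis; passing w = target rows keeps (row, col) order.
.resizeMatrix <- function(m, targetH, targetW, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (nrow(m) == targetH && ncol(m) == targetW) return(m)
  filt <- if (method == "bilinear") "bilinear" else "none"
  out <- EBImage::resize(m, w = targetH, h = targetW, filter = filt)
  matrix(as.numeric(out), targetH, targetW)
}

.resizeImage <- function(img, targetH, targetW, method = "bilinear") {
  if (length(dim(img)) == 2) return(.resizeMatrix(img, targetH, targetW, method))
  out <- array(0, dim = c(targetH, targetW, dim(img)[3]))
  for (ch in seq_len(dim(img)[3]))
    out[, , ch] <- .resizeMatrix(img[, , ch], targetH, targetW, method)
  out
}

.isBinaryMask <- function(m) {
  u <- unique(as.vector(m))
  all(u %in% c(0, 1)) || all(u %in% c(0, 255))
}

.maskTo01 <- function(m) {
  if (max(m) > 1) m / 255 else m + 0
}
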