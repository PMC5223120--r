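# File interfaces: 8-bit RGB PNG images, homography and correspondence CSVs.

#' Read / write arena images as 8-bit RGB PNG
#'
#' @param path file path.
#' @param resolution,timestamp,cameraId metadata attached on read.
#' @return `readArenaPNG` returns an [ArenaFrame-class]; `writeArenaPNG`
#'   returns `path` invisibly.
#' @export
readArenaPNG <- function(path, resolution = 0.677, timestamp = 0,
                         cameraId = "cam") {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L)
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  arenaFrame(img * 255, resolution = resolution, timestamp = timestamp,
             cameraId = cameraId)
}

#' @rdname readArenaPNG
#' @param frame an [ArenaFrame-class].
#' @export
writeArenaPNG <- function(frame, path) {
  png::writePNG(pixels(frame) / 255, path)
  invisible(path)
}

#' Read / write a homography as a 9-value CSV row (row-major)
#'
#' @param h 3 x 3 homography matrix.
#' @param path file path.
#' @export
writeHomographyCSV <- function(h, path) {
  utils::write.table(matrix(as.vector(t(h)), nrow = 1), path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeHomographyCSV
#' @export
readHomographyCSV <- function(path) {
  v <- as.numeric(utils::read.csv(path, header = FALSE)[1, ])
  matrix(v, 3, 3, byrow = TRUE)
}

#' Read correspondence pairs (src_x, src_y, dst_x, dst_y) from CSV
#'
#' @param path CSV with columns `src_x`, `src_y`, `dst_x`, `dst_y`.
#' @return data.frame suitable for [estimateHomography()].
#' @export
readCorrespondencesCSV <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("src_x", "src_y", "dst_x", "dst_y") %in% names(df)))
  df
}

#' Read a point pattern from CSV (columns x_cm, y_cm)
#'
#' @param path CSV file.
#' @param region observation region for the pattern.
#' @return a [PointPattern-class].
#' @export
readPatternCSV <- function(path, region) {
  df <- utils::read.csv(path)
  stopifnot(all(c("x_cm", "y_cm") %in% names(df)))
  pointPattern(cbind(df$x_cm, df$y_cm), region)
}
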