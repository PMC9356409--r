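#' Labeled movie container
#'
#' A `label_movie` is an ordered stack of 2D integer label masks, one per
#' time point. Label 0 is background; every nonzero integer identifies one
#' segmented object (cell or bud). All frames share the same grid, and the
#' physical pixel edge length is carried along so geometric quantities can
#' be reported in micrometres / femtolitres.
#'
#' @param frames list of integer matrices, all of identical dimensions.
#' @param pixel_size_um physical edge length of one pixel in micrometres.
#'   The default of 1 leaves every geometric output in pixel units.
#'
#' @return An object of class `label_movie`: a list with elements `frames`
#'   (list of integer matrices) and `pixel_size_um`.
#' @export
#' @examples
#' f <- matrix(0L, 16, 16); f[4:8, 4:8] <- 1L
#' mv <- label_movie(list(f, f))
#' n_frames(mv)
label_movie <- function(frames, pixel_size_um = 1.0) {
  if (!is.list(frames) || length(frames) == 0L)
    stop("'frames' must be a non-empty list of integer matrices")
  frames <- lapply(frames, as_label_frame)
  d <- dim(frames[[1L]])
  for (k in seq_along(frames)) {
    if (!identical(dim(frames[[k]]), d))
      stop(sprintf("frame %d has dimensions %s, expected %s",
                   k - 1L, paste(dim(frames[[k]]), collapse = "x"),
                   paste(d, collapse = "x")))
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("'pixel_size_um' must be a single positive number")
  structure(list(frames = frames, pixel_size_um = as.numeric(pixel_size_um)),
            class = "label_movie")
}

# Coerce a single frame to a validated integer label matrix.
as_label_frame <- function(x) {
  if (!is.matrix(x)) stop("each frame must be a matrix")
  if (is.double(x)) {
    if (any(x != floor(x), na.rm = TRUE))
      stop("label pixels must be integers (non-integer values found)")
    x <- matrix(as.integer(x), nrow(x), ncol(x))
  }
  if (!is.integer(x)) stop("label pixels must be integer-valued")
  if (anyNA(x) || any(x < 0L)) stop("labels must be non-negative and non-missing")
  x
}

#' @rdname label_movie
#' @param x a `label_movie`.
#' @export
n_frames <- function(x) length(x$frames)

#' @rdname label_movie
#' @param i frame index, 0-based (frame indices are 0-based throughout,
#'   matching the `frame_i` column of annotation tables).
#' @export
frame_at <- function(x, i) {
  stopifnot(inherits(x, "label_movie"))
  if (i < 0L || i >= n_frames(x)) stop("frame index out of range: ", i)
  x$frames[[i + 1L]]
}

#' @export
print.label_movie <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  ids <- sort(unique(unlist(lapply(x$frames, frame_labels))))
  cat(sprintf("label_movie: %d frame(s), %dx%d px, pixel size %g um\n",
              n_frames(x), d[1L], d[2L], x$pixel_size_um))
  cat(sprintf("  %d distinct object ID(s)%s\n", length(ids),
              if (length(ids)) paste0(": ", paste(utils::head(ids, 12L), collapse = ", "),
                                      if (length(ids) > 12L) ", ..." else "") else ""))
  invisible(x)
}

# Nonzero labels present in a frame, sorted.
frame_labels <- function(frame) {
  u <- unique(as.vector(frame))
  sort(u[u != 0L])
}

#' Read a label movie from TIFF
#'
#' Accepts either a multi-page TIFF (one page per time point) or a directory
#' of single-page TIFFs taken in lexicographic filename order. Pixel values
#' must be integral; they are preserved exactly.
#'
#' @param path path to a multi-page TIFF file or a directory of TIFFs.
#' @param pixel_size_um pixel edge length in micrometres.
#' @return a [label_movie].
#' @export
read_label_movie <- function(path, pixel_size_um = 1.0) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0L) stop("no TIFF files found in directory: ", path)
    pages <- unlist(lapply(files, function(f) tiff::readTIFF(f, all = TRUE, as.is = TRUE)),
                    recursive = FALSE)
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  }
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3L] != 1L)
        stop("multi-channel TIFF is not a label mask (", dim(p)[3L], " channels)")
      p <- p[, , 1L]
    }
    if (is.double(p) && any(p != floor(p)))
      stop("TIFF contains non-integer pixel values; not a label mask")
    if (anyNA(p) || any(p < 0) || any(p > 1e7))
      stop("TIFF pixel values outside the label range; non-integer ",
           "(floating-point) TIFFs are not label masks")
    matrix(as.integer(p), nrow(p), ncol(p))
  })
  label_movie(frames, pixel_size_um = pixel_size_um)
}

#' Write a label movie to a multi-page TIFF
#'
#' Labels are stored as 16-bit pages (maximum label 65535) so the written
#' file reads back bit-identically with [read_label_movie()].
#'
#' @param movie a [label_movie].
#' @param path output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_label_movie <- function(movie, path) {
  stopifnot(inherits(movie, "label_movie"))
  mx <- max(0L, vapply(movie$frames, max, integer(1)))
  if (mx > 65535L) stop("labels exceed 65535; cannot store as 16-bit TIFF")
  pages <- lapply(movie$frames, function(f) f / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Connected components of a binary mask
#'
#' Labels connected foreground regions using 8-connectivity (the convention
#' used by every contour-based operation in this package). Implemented as a
#' 4-connected pass with a union stage that joins diagonally touching
#' components.
#'
#' @param mask logical or 0/1 integer matrix.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)                 # 4-connected pass
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  n <- max(lab)
  if (n <= 1L) return(lab)
  # union components that touch only diagonally
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  join <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[rb] <<- ra }
  nr <- nrow(lab); nc <- ncol(lab)
  # pairs across the two diagonal directions
  if (nr > 1L && nc > 1L) {
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right neighbour
    a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left neighbour
    sel1 <- a1 > 0L & b1 > 0L & a1 != b1
    sel2 <- a2 > 0L & b2 > 0L & a2 != b2
    pr <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
    if (nrow(pr)) for (k in seq_len(nrow(pr))) join(pr[k, 1L], pr[k, 2L])
  }
  roots <- vapply(seq_len(n), find, integer(1))
  remap <- integer(n)
  remap[unique(roots)] <- seq_along(unique(roots))
  out <- lab
  out[lab > 0L] <- remap[roots[lab[lab > 0L]]]
  out
}

# Pixel coordinates (row, col), 1-based, of one label in a frame.
label_coords <- function(frame, id) {
  which(frame == id, arr.ind = TRUE)
}
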