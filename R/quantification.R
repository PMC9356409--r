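#' Estimate cell volume from a 2D mask
#'
#' Solid-of-revolution volume from a single 2D segmentation mask: the
#' object is aligned along its second-moment major axis, each 1-pixel-high
#' slice perpendicular to that axis is treated as a disk of radius half
#' the slice's foreground width (rotational symmetry about the middle
#' axis), and the slice volumes `pi * r^2 * 1` are summed. Alignment is
#' performed by rotating the pixel-center coordinates (no resampling, so
#' the mask's pixel count is conserved) and binning them into unit-height
#' slices along the major axis; the slice width is the pixel count of the
#' bin, which is robust to small boundary concavities.
#'
#' @param mask logical or 0/1 matrix with a single non-empty object.
#' @param pixel_size_um pixel edge length in micrometres (isotropic).
#' @return list with `volume_vox` (cubic pixels) and `volume_fl`
#'   (femtolitres, `volume_vox * pixel_size_um^3`).
#' @export
estimate_volume <- function(mask, pixel_size_um = 1.0) {
  coords <- which(mask != 0, arr.ind = TRUE)
  if (nrow(coords) == 0L) stop("empty mask")
  xy <- coords
  mu <- colMeans(xy)
  xc <- xy[, 1L] - mu[1L]; yc <- xy[, 2L] - mu[2L]
  m20 <- mean(xc^2); m02 <- mean(yc^2); m11 <- mean(xc * yc)
  theta <- 0.5 * atan2(2 * m11, m20 - m02)   # major-axis angle
  axial <- xc * cos(theta) + yc * sin(theta) # coordinate along major axis
  bins <- floor(axial - min(axial))          # unit-height slices
  widths <- tabulate(bins + 1L)
  vol <- sum(pi * (widths / 2)^2)
  list(volume_vox = vol, volume_fl = vol * pixel_size_um^3)
}

#' Background-corrected fluorescence metrics per cell
#'
#' The background level is the median intensity over all pixels outside
#' every cell mask in the frame. Per cell, the corrected mean is the raw
#' in-mask mean minus that median; the signal amount is corrected mean
#' times area (so adding a constant offset to the whole image cancels
#' exactly); the concentration divides the amount by the cell's estimated
#' volume.
#'
#' @param labels integer label matrix.
#' @param intensity numeric matrix of the same dimensions.
#' @param pixel_size_um pixel edge length in micrometres, used for the
#'   per-cell volume estimate.
#' @return data frame with one row per label: `id`, `area`, `mean_raw`,
#'   `median_raw`, `max_raw`, quantiles `q05/q25/q50/q75/q95`, `bg_median`,
#'   `corrected_mean`, `amount`, `volume_vox`, `volume_fl`,
#'   `concentration_vox` (amount / volume_vox) and `concentration_fl`
#'   (amount / volume_fl).
#' @export
fluor_metrics <- function(labels, intensity, pixel_size_um = 1.0) {
  if (!identical(dim(labels), dim(intensity)))
    stop("label and intensity images differ in shape")
  bg <- intensity[labels == 0L]
  if (length(bg) == 0L)
    stop("no background pixels in frame; supply an explicit background region")
  bg_median <- stats::median(bg)
  ids <- frame_labels(labels)
  rows <- lapply(ids, function(id) {
    mask <- labels == id
    v <- intensity[mask]
    qs <- stats::quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
    vol <- estimate_volume(mask, pixel_size_um)
    corrected <- mean(v) - bg_median
    amount <- corrected * length(v)
    data.frame(id = id, area = length(v), mean_raw = mean(v),
               median_raw = stats::median(v), max_raw = max(v),
               q05 = qs[1L], q25 = qs[2L], q50 = qs[3L], q75 = qs[4L],
               q95 = qs[5L], bg_median = bg_median,
               corrected_mean = corrected, amount = amount,
               volume_vox = vol$volume_vox, volume_fl = vol$volume_fl,
               concentration_vox = if (vol$volume_vox > 0) amount / vol$volume_vox else NA_real_,
               concentration_fl = if (vol$volume_fl > 0) amount / vol$volume_fl else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Quantify every frame of a movie
#'
#' Runs [fluor_metrics()] on each frame of a label movie against the
#' matching intensity movie and stacks the results with a 0-based
#' `frame_i` column.
#'
#' @param movie a [label_movie].
#' @param intensity list of numeric matrices, one per frame.
#' @return data frame, one row per (frame, cell).
#' @export
quantify_movie <- function(movie, intensity) {
  stopifnot(inherits(movie, "label_movie"))
  if (length(intensity) != n_frames(movie))
    stop("intensity stack length does not match movie length")
  rows <- lapply(seq_len(n_frames(movie)), function(k) {
    fm <- fluor_metrics(movie$frames[[k]], intensity[[k]],
                        pixel_size_um = movie$pixel_size_um)
    if (nrow(fm)) cbind(frame_i = k - 1L, fm) else NULL
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Combine mother and bud signal
#'
#' For every frame in which a mother has a reciprocated bud, the combined
#' amount (and volume) is the sum over the pair; in G1 frames the mother's
#' own values pass through unchanged. This gives whole-cell traces that
#' are continuous across bud emergence.
#'
#' @param table validated annotation data frame.
#' @param metrics per-(frame, cell) data frame with columns `frame_i`,
#'   `id`, `amount`, `volume_vox`.
#' @return data frame with one row per (frame, mother): `frame_i`,
#'   `Cell_ID`, `amount`, `volume_vox`, `bud_ID` (-1 in G1).
#' @export
combine_mother_bud <- function(table, metrics) {
  mothers <- table[table$relationship == "mother", , drop = FALSE]
  rows <- lapply(seq_len(nrow(mothers)), function(k) {
    f <- mothers$frame_i[k]; id <- mothers$Cell_ID[k]
    mi <- which(metrics$frame_i == f & metrics$id == id)
    if (!length(mi)) return(NULL)
    amount <- metrics$amount[mi]; vol <- metrics$volume_vox[mi]
    bud <- -1L
    if (mothers$cell_cycle_stage[k] == "S/G2/M" && mothers$relative_ID[k] != -1L) {
      bi <- which(metrics$frame_i == f & metrics$id == mothers$relative_ID[k])
      ti <- annot_idx(table, f, mothers$relative_ID[k])
      if (length(bi) && length(ti) && table$relationship[ti] == "bud" &&
          table$relative_ID[ti] == id) {
        amount <- amount + metrics$amount[bi]
        vol <- vol + metrics$volume_vox[bi]
        bud <- mothers$relative_ID[k]
      }
    }
    data.frame(frame_i = f, Cell_ID = id, amount = amount, volume_vox = vol,
               bud_ID = bud)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(frame_i = integer(0), Cell_ID = integer(0),
                                      amount = numeric(0), volume_vox = numeric(0),
                                      bud_ID = integer(0)))
  out <- out[order(out$frame_i, out$Cell_ID), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Align single-cell traces at bud emergence
#'
#' Re-indexes each mother's time series so that t = 0 is the first frame
#' its (first) bud exists. Cells that never bud are excluded and reported.
#'
#' @param table annotation data frame.
#' @param series data frame with columns `frame_i`, `Cell_ID` and one or
#'   more value columns.
#' @return list with `aligned` (the series rows of budding mothers plus a
#'   `t` column, `frame_i - emergence frame of the bud`) and `excluded`
#'   (data frame of `Cell_ID`, `reason` for cells without a bud).
#' @export
align_at_bud_emergence <- function(table, series) {
  mothers <- sort(unique(series$Cell_ID))
  aligned <- list(); excluded <- list()
  for (id in mothers) {
    # first bud this cell ever has: earliest reciprocated link
    rows <- table[table$Cell_ID == id & table$relationship == "mother" &
                    table$relative_ID != -1L, , drop = FALSE]
    t0 <- NA_integer_
    if (nrow(rows)) {
      buds <- unique(rows$relative_ID)
      emerg <- vapply(buds, function(b) {
        bf <- table$frame_i[table$Cell_ID == b & table$relative_ID == id &
                              table$relationship == "bud"]
        if (length(bf)) min(bf) else NA_integer_
      }, integer(1))
      if (any(!is.na(emerg))) t0 <- min(emerg, na.rm = TRUE)
    }
    if (is.na(t0)) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(Cell_ID = id, reason = "never buds")
      next
    }
    s <- series[series$Cell_ID == id, , drop = FALSE]
    s$t <- s$frame_i - t0
    aligned[[length(aligned) + 1L]] <- s
  }
  list(aligned = if (length(aligned)) do.call(rbind, aligned) else NULL,
       excluded = if (length(excluded)) do.call(rbind, excluded)
                  else data.frame(Cell_ID = integer(0), reason = character(0)))
}
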