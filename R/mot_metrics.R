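#' Match predicted to ground-truth objects in one frame
#'
#' One-to-one matching by intersection-over-union, keeping only pairs with
#' IoU strictly above 0.5 (the multiple-object-tracking convention). An
#' IoU above 0.5 is mutually exclusive, so the matching is unique.
#' Unmatched ground-truth objects are false negatives, unmatched predicted
#' objects false positives.
#'
#' @param gt,pred integer label matrices of identical dimensions.
#' @return list with `matches` (data frame `gt_id`, `pred_id`, `iou`),
#'   `FN`, `FP` (counts) and the unmatched id vectors `fn_ids`, `fp_ids`.
#' @export
match_frame <- function(gt, pred) {
  if (!identical(dim(gt), dim(pred))) stop("frames differ in shape")
  gt_ids <- frame_labels(gt); pred_ids <- frame_labels(pred)
  matches <- data.frame(gt_id = integer(0), pred_id = integer(0),
                        iou = numeric(0))
  if (length(gt_ids) && length(pred_ids)) {
    sel <- gt != 0L & pred != 0L
    if (any(sel)) {
      ov <- unclass(table(factor(gt[sel], levels = gt_ids),
                          factor(pred[sel], levels = pred_ids)))
      a_gt <- tabulate(match(gt[gt != 0L], gt_ids), nbins = length(gt_ids))
      a_pr <- tabulate(match(pred[pred != 0L], pred_ids), nbins = length(pred_ids))
      un <- outer(a_gt, a_pr, `+`) - ov
      iou <- ov / un
      hit <- which(iou > 0.5, arr.ind = TRUE)
      if (nrow(hit))
        matches <- data.frame(gt_id = gt_ids[hit[, 1L]],
                              pred_id = pred_ids[hit[, 2L]],
                              iou = iou[hit])
    }
  }
  fn_ids <- setdiff(gt_ids, matches$gt_id)
  fp_ids <- setdiff(pred_ids, matches$pred_id)
  list(matches = matches, FN = length(fn_ids), FP = length(fp_ids),
       fn_ids = fn_ids, fp_ids = fp_ids)
}

#' Multiple-object-tracking accuracy report
#'
#' Evaluates a predicted (tracked) label movie against ground truth.
#' Identities are the label values of each movie. Per frame, objects are
#' matched with [match_frame()]; false negatives, false positives and
#' identity switches are accumulated and
#' `MOTA = 1 - (sum FN + FP + IDSW) / (sum GT)`.
#'
#' An identity switch is counted when a ground-truth trajectory's matched
#' predicted identity differs from its previously matched identity -- but
#' only the first time each (trajectory, new identity) transition occurs,
#' so a persistent swap costs one switch however long it lasts. The total
#' time spent in a switched state is reported separately as
#' `switch_duration_frames` (frames matched to a non-original identity).
#'
#' @param gt,pred [label_movie]s of the same length and shape.
#' @return object of class `mot_report`: per-frame vectors `FN_t`, `FP_t`,
#'   `IDSW_t`, `GT_t`, totals `FN`, `FP`, `IDSW`, `GT`, `mota` and
#'   `switch_duration_frames`.
#' @export
mot_report <- function(gt, pred) {
  stopifnot(inherits(gt, "label_movie"), inherits(pred, "label_movie"))
  if (n_frames(gt) != n_frames(pred)) stop("movies differ in length")
  t_n <- n_frames(gt)
  FN_t <- FP_t <- IDSW_t <- GT_t <- integer(t_n)
  last_id <- list()      # most recent matched pred id per gt trajectory
  first_id <- list()     # original (first ever) matched pred id
  seen_transition <- character(0)
  switch_duration <- 0L
  for (t in seq_len(t_n)) {
    g <- gt$frames[[t]]; p <- pred$frames[[t]]
    GT_t[t] <- length(frame_labels(g))
    mf <- match_frame(g, p)
    FN_t[t] <- mf$FN; FP_t[t] <- mf$FP
    sw <- 0L
    for (k in seq_len(nrow(mf$matches))) {
      gid <- as.character(mf$matches$gt_id[k])
      pid <- mf$matches$pred_id[k]
      if (!is.null(last_id[[gid]]) && last_id[[gid]] != pid) {
        key <- paste(gid, pid)
        if (!(key %in% seen_transition)) {
          sw <- sw + 1L
          seen_transition <- c(seen_transition, key)
        }
      }
      if (is.null(first_id[[gid]])) first_id[[gid]] <- pid
      if (first_id[[gid]] != pid) switch_duration <- switch_duration + 1L
      last_id[[gid]] <- pid
    }
    IDSW_t[t] <- sw
  }
  GT <- sum(GT_t)
  structure(list(FN_t = FN_t, FP_t = FP_t, IDSW_t = IDSW_t, GT_t = GT_t,
                 FN = sum(FN_t), FP = sum(FP_t), IDSW = sum(IDSW_t), GT = GT,
                 mota = if (GT > 0) 1 - (sum(FN_t) + sum(FP_t) + sum(IDSW_t)) / GT
                        else NA_real_,
                 switch_duration_frames = switch_duration),
            class = "mot_report")
}

#' @export
print.mot_report <- function(x, ...) {
  cat(sprintf("MOT report over %d frame(s): GT=%d FN=%d FP=%d IDSW=%d\n",
              length(x$GT_t), x$GT, x$FN, x$FP, x$IDSW))
  cat(sprintf("  MOTA = %.4f, switch duration = %d frame(s)\n",
              x$mota, x$switch_duration_frames))
  invisible(x)
}

#' Link-based tracking precision, recall and F-score
#'
#' A link is a pair of consecutive time points of one trajectory. With `G`
#' ground-truth links, `R` predicted links and `c` the number of
#' ground-truth links whose two endpoints are matched (by [match_frame()])
#' to the same predicted identity in both frames,
#' `precision = c / R`, `recall = c / G`, and F is their harmonic mean.
#' Degenerate 0/0 ratios are reported as 0.
#'
#' @param gt,pred [label_movie]s of the same length and shape.
#' @return list with `c`, `R`, `G`, `precision`, `recall`, `fscore`.
#' @export
link_fscore <- function(gt, pred) {
  stopifnot(inherits(gt, "label_movie"), inherits(pred, "label_movie"))
  if (n_frames(gt) != n_frames(pred)) stop("movies differ in length")
  t_n <- n_frames(gt)
  count_links <- function(movie) {
    total <- 0L
    for (t in seq_len(t_n - 1L))
      total <- total + length(intersect(frame_labels(movie$frames[[t]]),
                                        frame_labels(movie$frames[[t + 1L]])))
    total
  }
  G <- count_links(gt); R <- count_links(pred)
  matches <- lapply(seq_len(t_n), function(t)
    match_frame(gt$frames[[t]], pred$frames[[t]])$matches)
  c_links <- 0L
  for (t in seq_len(t_n - 1L)) {
    m1 <- matches[[t]]; m2 <- matches[[t + 1L]]
    common <- intersect(frame_labels(gt$frames[[t]]),
                        frame_labels(gt$frames[[t + 1L]]))
    for (gid in common) {
      p1 <- m1$pred_id[m1$gt_id == gid]
      p2 <- m2$pred_id[m2$gt_id == gid]
      if (length(p1) == 1L && length(p2) == 1L && p1 == p2)
        c_links <- c_links + 1L
    }
  }
  precision <- if (R > 0) c_links / R else 0
  recall <- if (G > 0) c_links / G else 0
  fscore <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(c = c_links, R = R, G = G, precision = precision, recall = recall,
       fscore = fscore)
}
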