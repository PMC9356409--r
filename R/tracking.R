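#' Intersection-over-area cost matrix
#'
#' For consecutive frames, entry `(i, j)` is the overlap of current object
#' `y_i` with previous object `x_j`, divided by the area of `x_j`. Dividing
#' by the *previous* area makes the score asymmetric on purpose: a small
#' new bud overlapping nothing scores 0 against every previous cell, while
#' a cell that merely grew keeps a score near 1 against its predecessor.
#'
#' @param prev,curr integer label matrices of identical dimensions.
#' @return list with `prev_ids`, `curr_ids` (sorted nonzero labels) and
#'   `cost`, a `length(curr_ids) x length(prev_ids)` matrix with entries in
#'   `[0, 1]`; each column sums to at most 1.
#' @export
ioa_matrix <- function(prev, curr) {
  if (!identical(dim(prev), dim(curr)))
    stop("frames differ in shape: ", paste(dim(prev), collapse = "x"), " vs ",
         paste(dim(curr), collapse = "x"))
  prev_ids <- frame_labels(prev)
  curr_ids <- frame_labels(curr)
  cost <- matrix(0, nrow = length(curr_ids), ncol = length(prev_ids),
                 dimnames = list(curr_ids, prev_ids))
  if (length(prev_ids) && length(curr_ids)) {
    sel <- prev != 0L & curr != 0L
    if (any(sel)) {
      ov <- table(factor(curr[sel], levels = curr_ids),
                  factor(prev[sel], levels = prev_ids))
      area_prev <- tabulate(match(prev[prev != 0L], prev_ids),
                            nbins = length(prev_ids))
      cost <- sweep(unclass(ov), 2L, area_prev, `/`)
      dimnames(cost) <- list(curr_ids, prev_ids)
    }
  }
  list(prev_ids = prev_ids, curr_ids = curr_ids, cost = cost)
}

#' Frame-to-frame object assignment by maximal overlap
#'
#' Implements continuous tracking between two consecutive frames. First,
#' every current object whose best IoA against all previous objects is
#' strictly below `new_object_threshold` is declared new (a bud emerging,
#' or a cell drifting into view). Each remaining object is assigned to the
#' previous object it overlaps best, unless that previous object overlaps
#' another current object strictly better, in which case the loser is not
#' re-assigned to its second choice but joins the new-object pool
#' (single-pass semantics). Ties are broken deterministically: among equal
#' previous candidates the lower label wins; among equal current
#' competitors for one previous object the lower label wins.
#'
#' @param prev,curr integer label matrices of identical dimensions.
#' @param new_object_threshold IoA cutoff in (0, 1]; an object at exactly
#'   the threshold is assigned, only strictly smaller scores mean "new".
#' @return list of class `id_mapping`:
#'   `assignments` -- named integer vector, current label -> previous label;
#'   `new_ids` -- integer vector of current labels considered new;
#'   `lost_ids` -- previous labels with no successor;
#'   `ioa` -- the [ioa_matrix()] used.
#' @export
track_pair <- function(prev, curr, new_object_threshold = 0.4) {
  if (!is.numeric(new_object_threshold) || new_object_threshold <= 0 ||
      new_object_threshold > 1)
    stop("'new_object_threshold' must be in (0, 1]")
  m <- ioa_matrix(prev, curr)
  cost <- m$cost
  n_curr <- length(m$curr_ids)
  assignments <- integer(0)
  new_ids <- integer(0)
  if (n_curr > 0L) {
    max_ioa <- if (length(m$prev_ids)) apply(cost, 1L, max) else rep(0, n_curr)
    is_new <- max_ioa < new_object_threshold
    keep <- which(!is_new)
    assigned_to <- rep(NA_integer_, n_curr)        # index into prev_ids
    for (i in keep) {
      j <- which(cost[i, ] == max_ioa[i])[1L]      # lower prev label on ties
      competitors <- setdiff(keep, i)
      blocked <- FALSE
      if (length(competitors)) {
        cc <- cost[competitors, j]
        if (any(cc > cost[i, j])) blocked <- TRUE
        else {
          tied <- competitors[cc == cost[i, j]]
          # equal competition: only the lowest current label keeps the claim,
          # and only competitors for which j is also the argmax count
          tied <- tied[vapply(tied, function(k) {
            which(cost[k, ] == max(cost[k, ]))[1L] == j
          }, logical(1))]
          if (length(tied) && any(m$curr_ids[tied] < m$curr_ids[i])) blocked <- TRUE
        }
      }
      if (!blocked) assigned_to[i] <- j
    }
    ok <- which(!is.na(assigned_to))
    assignments <- m$prev_ids[assigned_to[ok]]
    names(assignments) <- m$curr_ids[ok]
    new_ids <- m$curr_ids[setdiff(seq_len(n_curr), ok)]
  }
  lost_ids <- setdiff(m$prev_ids, unname(assignments))
  structure(list(assignments = assignments, new_ids = new_ids,
                 lost_ids = lost_ids, ioa = m), class = "id_mapping")
}

#' Track a whole label movie
#'
#' Propagates object identities through the movie. Frame 0 keeps its labels
#' verbatim; every later frame is relabeled so that an object assigned by
#' [track_pair()] inherits the (possibly already-remapped) identity of its
#' predecessor, and every new object receives a fresh identity one above
#' the highest ever used in the movie. Identities are never recycled, so
#' pedigree links stay valid for the whole movie. Foreground pixels are
#' never moved -- only label values change.
#'
#' @param movie a [label_movie].
#' @param new_object_threshold IoA cutoff passed to [track_pair()].
#' @return list with `movie` (the relabeled [label_movie]) and `mappings`
#'   (list of per-frame-pair `id_mapping`s, element `t` linking frame
#'   `t - 1` to frame `t`).
#' @export
track_movie <- function(movie, new_object_threshold = 0.4) {
  stopifnot(inherits(movie, "label_movie"))
  if (n_frames(movie) < 1L) stop("empty movie")
  out <- movie$frames
  max_id <- max(0L, frame_labels(out[[1L]]))
  mappings <- vector("list", max(0L, n_frames(movie) - 1L))
  for (t in seq_len(n_frames(movie) - 1L)) {
    prev_tracked <- out[[t]]
    curr_raw <- movie$frames[[t + 1L]]
    mp <- track_pair(prev_tracked, curr_raw, new_object_threshold)
    relab <- curr_raw
    new_out <- mp
    if (length(mp$assignments)) {
      from <- as.integer(names(mp$assignments))
      for (k in seq_along(from))
        relab[curr_raw == from[k]] <- mp$assignments[[k]]
    }
    fresh <- integer(0)
    if (length(mp$new_ids)) {
      fresh <- max_id + seq_along(sort(mp$new_ids))
      names(fresh) <- sort(mp$new_ids)
      for (k in seq_along(fresh))
        relab[curr_raw == as.integer(names(fresh)[k])] <- fresh[[k]]
      max_id <- max(max_id, fresh)
    }
    max_id <- max(max_id, frame_labels(relab), 0L)
    new_out$new_ids <- fresh        # map raw curr label -> fresh movie label
    out[[t + 1L]] <- relab
    mappings[[t]] <- new_out
  }
  list(movie = label_movie(out, pixel_size_um = movie$pixel_size_um),
       mappings = mappings)
}
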