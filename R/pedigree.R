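#' Build a mother-bud pairing problem
#'
#' When new objects appear in a frame they are candidate buds, and every
#' cell currently in G1 is a candidate mother. The assignment cost between
#' a new cell and a G1 cell is the single-linkage distance: the minimum
#' Euclidean distance between the pixels of their contours. A bud emerges
#' attached to its mother, so the true pair usually has cost ~0-1 px.
#'
#' @param frame integer label matrix for the emergence frame.
#' @param new_cells integer labels of the newly appeared objects.
#' @param g1_cells integer labels of the cells in G1.
#' @return list with `new_cells`, `g1_cells` and `cost`
#'   (`length(new_cells) x length(g1_cells)` matrix, pixels).
#' @export
pairing_problem <- function(frame, new_cells, g1_cells) {
  contours <- lapply(c(new_cells, g1_cells), function(id) object_contour(frame, id))
  names(contours) <- as.character(c(new_cells, g1_cells))
  cost <- matrix(0, length(new_cells), length(g1_cells),
                 dimnames = list(new_cells, g1_cells))
  for (i in seq_along(new_cells)) {
    ca <- contours[[as.character(new_cells[i])]]
    for (j in seq_along(g1_cells)) {
      cb <- contours[[as.character(g1_cells[j])]]
      dx <- outer(ca[, 1L], cb[, 1L], `-`)
      dy <- outer(ca[, 2L], cb[, 2L], `-`)
      cost[i, j] <- sqrt(min(dx^2 + dy^2))
    }
  }
  list(new_cells = as.integer(new_cells), g1_cells = as.integer(g1_cells),
       cost = cost)
}

#' Assign new buds to mothers in G1
#'
#' Solves the minimum-total-cost one-to-one assignment of new cells to G1
#' cells (the linear sum assignment problem) on the cost matrix of a
#' [pairing_problem()]. With more new cells than G1 cells only
#' `length(g1_cells)` pairs are formed -- the subset of lowest total cost --
#' and an `insufficient_G1` warning is recorded for the caller to resolve
#' (typically by marking the unpaired newcomers as cells of unknown
#' history).
#'
#' @param problem a [pairing_problem()].
#' @return list of class `pairing_result` with `pairs` (named integer
#'   vector, bud label -> mother label; injective) and `warnings` (list of
#'   `list(kind, details)` records).
#' @export
pair_buds <- function(problem) {
  a <- problem$new_cells; b <- problem$g1_cells
  warnings <- list()
  pairs <- integer(0)
  if (length(a) > 0L && length(b) > 0L) {
    if (any(!is.finite(problem$cost))) stop("pairing cost matrix must be finite")
    if (length(a) <= length(b)) {
      sol <- clue::solve_LSAP(problem$cost)
      pairs <- b[as.integer(sol)]
      names(pairs) <- a
    } else {
      sol <- clue::solve_LSAP(t(problem$cost))   # each G1 cell gets one bud
      pairs <- b
      names(pairs) <- a[as.integer(sol)]
      warnings[[length(warnings) + 1L]] <- list(
        kind = "insufficient_G1",
        details = sprintf("%d new cell(s) but only %d cell(s) in G1; unpaired: %s",
                          length(a), length(b),
                          paste(setdiff(a, as.integer(names(pairs))), collapse = ",")))
    }
  } else if (length(a) > 0L) {
    warnings[[length(warnings) + 1L]] <- list(
      kind = "insufficient_G1",
      details = sprintf("%d new cell(s) but no cell in G1", length(a)))
  }
  structure(list(pairs = pairs, warnings = warnings), class = "pairing_result")
}

# Frames of a bud's (undivided) life: relationship == "bud".
bud_lifetime <- function(table, bud) {
  sort(table$frame_i[table$Cell_ID == bud & table$relationship == "bud"])
}

#' Can a bud be (re)assigned to this mother?
#'
#' A mother is eligible when it is in G1 at the pairing frame (a budded
#' cell cannot take a second bud) and has no other reciprocated bud in any
#' frame of the bud's lifetime.
#'
#' @param table annotation data frame.
#' @param bud,mother cell labels.
#' @param frames frames to check; defaults to the bud's lifetime.
#' @return list with `ok` (logical) and, when not ok, `reason` (one of
#'   `"mother_not_in_G1"`, `"mother_already_has_bud"`, `"unknown_label"`)
#'   and `detail`.
#' @export
check_assignment_eligibility <- function(table, bud, mother, frames = NULL) {
  if (!any(table$Cell_ID == bud) || !any(table$Cell_ID == mother))
    stop("unknown label(s): ", paste(setdiff(c(bud, mother), table$Cell_ID),
                                     collapse = ", "))
  if (is.null(frames)) frames <- bud_lifetime(table, bud)
  if (!length(frames)) frames <- sort(table$frame_i[table$Cell_ID == bud])
  pairing_frame <- frames[1L]
  i <- annot_idx(table, pairing_frame, mother)
  if (!length(i))
    return(list(ok = FALSE, reason = "unknown_label",
                detail = sprintf("mother %d absent at frame %d", mother, pairing_frame)))
  if (table$cell_cycle_stage[i] != "G1" &&
      !(table$relative_ID[i] == bud && table$relationship[i] == "mother"))
    return(list(ok = FALSE, reason = "mother_not_in_G1",
                detail = sprintf("cell %d is in %s at frame %d", mother,
                                 table$cell_cycle_stage[i], pairing_frame)))
  for (f in frames) {
    j <- annot_idx(table, f, mother)
    if (!length(j)) next
    if (table$cell_cycle_stage[j] == "S/G2/M" && table$relationship[j] == "mother" &&
        table$relative_ID[j] != -1L && table$relative_ID[j] != bud) {
      k <- annot_idx(table, f, table$relative_ID[j])
      if (length(k) && table$relationship[k] == "bud" &&
          table$relative_ID[k] == mother)
        return(list(ok = FALSE, reason = "mother_already_has_bud",
                    detail = sprintf("cell %d already has bud %d at frame %d",
                                     mother, table$relative_ID[j], f)))
    }
  }
  list(ok = TRUE)
}

# Apply one bud -> mother assignment at the emergence frame and every later
# frame where the bud exists. Creates the bud's rows if absent.
apply_pairing <- function(table, frame_i, bud, mother) {
  frames <- sort(table$frame_i[table$Cell_ID == bud])
  frames <- frames[frames >= frame_i]
  if (!length(frames)) frames <- frame_i
  for (f in frames) {
    bi <- annot_idx(table, f, bud)
    if (!length(bi)) {
      table <- rbind(table, annotation_row(f, bud))
      bi <- annot_idx(table, f, bud)
    }
    table$cell_cycle_stage[bi] <- "S/G2/M"
    table$relationship[bi] <- "bud"
    table$relative_ID[bi] <- mother
    table$generation_num[bi] <- 0L
    table$emerg_frame_i[bi] <- frame_i
    table$division_frame_i[bi] <- -1L
    table$is_history_known[bi] <- TRUE
    mi <- annot_idx(table, f, mother)
    if (length(mi)) {
      table$cell_cycle_stage[mi] <- "S/G2/M"
      table$relationship[mi] <- "mother"
      table$relative_ID[mi] <- bud
    }
  }
  normalize_annotations(table)
}

# Resolve the (mother, bud) pair involved in a division-related click.
resolve_pair <- function(table, frame_i, cell) {
  i <- annot_idx(table, frame_i, cell)
  if (!length(i)) stop("cell ", cell, " absent at frame ", frame_i)
  partner <- table$relative_ID[i]
  if (partner == -1L) stop("cell ", cell, " has no paired relative at frame ", frame_i)
  j <- annot_idx(table, frame_i, partner)
  if (!length(j)) stop("relative ", partner, " of cell ", cell,
                       " absent at frame ", frame_i)
  if (table$relationship[i] == "bud") list(mother = partner, bud = cell)
  else list(mother = cell, bud = partner)
}

#' Annotate a cell-division event
#'
#' Marks division of a mother-bud pair at `frame_i` and propagates the new
#' state to every later frame previously annotated as the same S/G2/M
#' stretch: the mother returns to G1 with its generation incremented and
#' `division_frame_i` set; the bud becomes a mother in G1 of generation 1,
#' keeping its `relative_ID` as the pedigree link to its mother.
#'
#' @param table annotation data frame.
#' @param frame_i 0-based frame of the division.
#' @param cell either member of the pair (mother or bud).
#' @return the updated table.
#' @export
annotate_division <- function(table, frame_i, cell) {
  i <- annot_idx(table, frame_i, cell)
  if (!length(i)) stop("cell ", cell, " absent at frame ", frame_i)
  if (table$cell_cycle_stage[i] != "S/G2/M")
    stop("cell ", cell, " is in G1 at frame ", frame_i,
         "; use undo_division to revert an annotated division")
  pr <- resolve_pair(table, frame_i, cell)
  mother <- pr$mother; bud <- pr$bud
  mother_gen <- table$generation_num[annot_idx(table, frame_i, mother)]
  f <- frame_i
  repeat {
    mi <- annot_idx(table, f, mother)
    bi <- annot_idx(table, f, bud)
    # stop at the first frame no longer part of this S/G2/M stretch
    if (!length(mi) || table$cell_cycle_stage[mi] != "S/G2/M" ||
        table$relative_ID[mi] != bud) {
      if (f == frame_i) stop("pair not in S/G2/M at frame ", frame_i)
      break
    }
    table$cell_cycle_stage[mi] <- "G1"
    table$generation_num[mi] <- mother_gen + 1L
    table$division_frame_i[mi] <- frame_i
    if (length(bi)) {
      table$cell_cycle_stage[bi] <- "G1"
      table$relationship[bi] <- "mother"
      table$generation_num[bi] <- 1L
      table$division_frame_i[bi] <- frame_i
    }
    f <- f + 1L
    if (!length(annot_idx(table, f, mother))) break
  }
  normalize_annotations(table)
}

#' Undo a division annotation
#'
#' Reverts an annotated division: the cell and the bud it had in the
#' previous cycle go back to S/G2/M over the whole G1 stretch created by
#' the division -- forward until each cell re-enters S/G2/M (or the table
#' ends) and backward to the division frame itself. Generation numbers and
#' `division_frame_i` are restored from the last frame before the division,
#' making this the exact inverse of [annotate_division()].
#'
#' @param table annotation data frame.
#' @param frame_i 0-based frame inside the G1 stretch to revert.
#' @param cell either member of the divided pair.
#' @return the updated table.
#' @export
undo_division <- function(table, frame_i, cell) {
  i <- annot_idx(table, frame_i, cell)
  if (!length(i)) stop("cell ", cell, " absent at frame ", frame_i)
  if (table$cell_cycle_stage[i] == "S/G2/M")
    stop("cell ", cell, " is in S/G2/M at frame ", frame_i,
         "; only an annotated division (cell in G1) can be undone")
  s <- table$division_frame_i[i]
  if (s < 0L) stop("cell ", cell, " has no annotated division to undo")
  partner <- table$relative_ID[i]
  if (partner == -1L) stop("cell ", cell, " has no recorded previous-cycle partner")
  if (s == 0L) stop("division at frame 0 cannot be undone (no pre-division state)")
  for (id in c(cell, partner)) {
    ref <- annot_idx(table, s - 1L, id)
    if (!length(ref))
      stop("no pre-division row for cell ", id, " at frame ", s - 1L)
    f <- s
    repeat {
      k <- annot_idx(table, f, id)
      if (!length(k) || table$cell_cycle_stage[k] != "G1" ||
          table$division_frame_i[k] != s) break
      table$cell_cycle_stage[k] <- table$cell_cycle_stage[ref]
      table$relationship[k] <- table$relationship[ref]
      table$generation_num[k] <- table$generation_num[ref]
      table$relative_ID[k] <- table$relative_ID[ref]
      table$division_frame_i[k] <- table$division_frame_i[ref]
      f <- f + 1L
    }
  }
  normalize_annotations(table)
}

#' Reassign a bud to the correct mother
#'
#' When automatic pairing picked the wrong mother, this rewrites every
#' frame of the bud's (undivided) lifetime: the wrong mother goes back to
#' the state it had before the bud was assigned to it (G1, its previous
#' relative link), and the new mother is paired reciprocally with the bud.
#' The new mother must pass [check_assignment_eligibility()].
#'
#' @param table annotation data frame.
#' @param bud bud label.
#' @param new_mother label of the correct mother.
#' @return the updated table.
#' @export
correct_mother <- function(table, bud, new_mother) {
  frames <- bud_lifetime(table, bud)
  if (!length(frames)) stop("cell ", bud, " has no undivided bud frames")
  elig <- check_assignment_eligibility(table, bud, new_mother, frames)
  if (!elig$ok)
    stop("cell ", new_mother, " is not an eligible mother [", elig$reason, "]: ",
         elig$detail)
  emerg <- frames[1L]
  wrong <- table$relative_ID[annot_idx(table, emerg, bud)]
  # state of the wrong mother before the bud was assigned to it
  pre <- annot_idx(table, emerg - 1L, wrong)
  pre_rel <- if (length(pre)) table$relative_ID[pre] else -1L
  pre_stage <- if (length(pre)) table$cell_cycle_stage[pre] else "G1"
  pre_relshp <- if (length(pre)) table$relationship[pre] else "mother"
  for (f in frames) {
    wi <- annot_idx(table, f, wrong)
    if (length(wi) && wrong != new_mother && wrong != -1L) {
      table$cell_cycle_stage[wi] <- pre_stage
      table$relationship[wi] <- pre_relshp
      table$relative_ID[wi] <- pre_rel
    }
    ni <- annot_idx(table, f, new_mother)
    if (length(ni)) {
      table$cell_cycle_stage[ni] <- "S/G2/M"
      table$relationship[ni] <- "mother"
      table$relative_ID[ni] <- bud
    }
    bi <- annot_idx(table, f, bud)
    table$relative_ID[bi] <- new_mother
  }
  normalize_annotations(table)
}

#' Annotate a tracked movie frame by frame
#'
#' Builds a cell-cycle annotation table for a tracked label movie. Cells
#' present at frame 0 start in G1 with unknown history. At every later
#' frame, surviving cells carry their state forward; newly appearing
#' objects are treated as candidate buds and assigned to G1 cells with
#' [pair_buds()]; newcomers that cannot be paired (no G1 cell available)
#' are recorded as cells of unknown history in G1. A bud whose label
#' disappears while still a bud is closed with `is_history_known = FALSE`
#' at its last frame and its mother reverts to G1 (`washed_away_bud`
#' warning). Division events (not detectable from masks alone) can be
#' supplied and are applied with [annotate_division()] during the sweep.
#'
#' @param movie a tracked [label_movie] (labels consistent over time).
#' @param divisions optional data frame with columns `frame_i`, `Cell_ID`
#'   giving division events to annotate during the sweep.
#' @return list with `table` (annotation data frame) and `warnings`
#'   (list of `list(kind, frame_i, details)`).
#' @export
annotate_movie <- function(movie, divisions = NULL) {
  stopifnot(inherits(movie, "label_movie"))
  warnings <- list()
  f0 <- frame_at(movie, 0L)
  rows <- lapply(frame_labels(f0), function(id)
    annotation_row(0L, id, cell_cycle_stage = "G1", generation_num = 2L,
                   relative_ID = -1L, relationship = "mother",
                   emerg_frame_i = -1L, is_history_known = FALSE))
  table <- if (length(rows)) do.call(rbind, rows) else empty_annotations()
  table <- normalize_annotations(table)
  apply_divisions <- function(table, f) {
    if (is.null(divisions)) return(table)
    dd <- divisions[divisions$frame_i == f, , drop = FALSE]
    for (q in seq_len(nrow(dd)))
      table <- annotate_division(table, f, dd$Cell_ID[q])
    table
  }
  table <- apply_divisions(table, 0L)
  if (n_frames(movie) > 1L) for (t in seq_len(n_frames(movie) - 1L)) {
    prev_ids <- frame_labels(frame_at(movie, t - 1L))
    curr <- frame_at(movie, t)
    curr_ids <- frame_labels(curr)
    # carry surviving cells forward
    for (id in intersect(prev_ids, curr_ids)) {
      r <- table[annot_idx(table, t - 1L, id), , drop = FALSE]
      r$frame_i <- t
      table <- rbind(table, r)
    }
    # washed-away buds and other disappearances
    for (id in setdiff(prev_ids, curr_ids)) {
      li <- annot_idx(table, t - 1L, id)
      if (table$relationship[li] == "bud") {
        table$is_history_known[li] <- FALSE
        mother <- table$relative_ID[li]
        warnings[[length(warnings) + 1L]] <- list(
          kind = "washed_away_bud", frame_i = t,
          details = sprintf("bud %d (mother %d) disappeared before division", id, mother))
        mi <- annot_idx(table, t, mother)
        if (length(mi)) {
          table$cell_cycle_stage[mi] <- "G1"
          table$relative_ID[mi] <- -1L
        }
      }
    }
    # new objects: candidate buds
    new_ids <- setdiff(curr_ids, prev_ids)
    if (length(new_ids)) {
      ft <- table[table$frame_i == t, , drop = FALSE]
      g1 <- ft$Cell_ID[ft$cell_cycle_stage == "G1" & !ft$is_cell_dead &
                         !ft$is_cell_excluded]
      pb <- pair_buds(pairing_problem(curr, new_ids, g1))
      for (w in pb$warnings)
        warnings[[length(warnings) + 1L]] <- c(w, frame_i = t)
      for (bud_chr in names(pb$pairs)) {
        bud <- as.integer(bud_chr)
        table <- apply_pairing(table, t, bud, pb$pairs[[bud_chr]])
      }
      for (id in setdiff(new_ids, as.integer(names(pb$pairs))))
        table <- rbind(table, annotation_row(t, id, cell_cycle_stage = "G1",
                                             generation_num = 2L,
                                             emerg_frame_i = t,
                                             is_history_known = FALSE))
    }
    table <- normalize_annotations(table)
    table <- apply_divisions(table, t)
  }
  list(table = normalize_annotations(table), warnings = warnings)
}
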