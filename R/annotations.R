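#' Cell-cycle annotation tables
#'
#' Pedigree and cell-cycle state is stored as one row per (frame, cell) in a
#' plain data frame, mirroring the CSV written by the annotation pipeline.
#' Columns:
#'
#' * `frame_i` -- 0-based frame index.
#' * `Cell_ID` -- integer object label in the tracked movie.
#' * `cell_cycle_stage` -- `"G1"` or `"S/G2/M"`. Bud emergence marks the
#'   G1 -> S transition; division returns both cells to G1.
#' * `generation_num` -- completed divisions; a bud carries 0 until its
#'   first division, then 1.
#' * `relative_ID` -- the paired cell (bud for a mother, mother for a bud),
#'   or -1 when unpaired.
#' * `relationship` -- `"mother"` (all cells in G1 and budded mothers) or
#'   `"bud"` (a bud that has not divided yet).
#' * `emerg_frame_i` -- frame the cell first appeared, -1 if unknown.
#' * `division_frame_i` -- frame of the last annotated division, -1 if none.
#' * `is_history_known` -- FALSE for cells whose origin was not observed
#'   (present at frame 0, or drifted in from outside the field of view).
#' * `is_cell_excluded`, `is_cell_dead` -- optional analyst flags.
#'
#' @name annotations
NULL

ANNOT_COLUMNS <- c("frame_i", "Cell_ID", "cell_cycle_stage", "generation_num",
                   "relative_ID", "relationship", "emerg_frame_i",
                   "division_frame_i", "is_history_known",
                   "is_cell_excluded", "is_cell_dead")

#' Create an empty annotation table
#'
#' @return zero-row data frame with the full annotation schema.
#' @export
empty_annotations <- function() {
  data.frame(frame_i = integer(0), Cell_ID = integer(0),
             cell_cycle_stage = character(0), generation_num = integer(0),
             relative_ID = integer(0), relationship = character(0),
             emerg_frame_i = integer(0), division_frame_i = integer(0),
             is_history_known = logical(0), is_cell_excluded = logical(0),
             is_cell_dead = logical(0), stringsAsFactors = FALSE)
}

#' Build one annotation row
#'
#' @param frame_i,Cell_ID row key (0-based frame, integer label).
#' @param cell_cycle_stage `"G1"` or `"S/G2/M"`.
#' @param generation_num completed divisions (bud: 0 until it divides).
#' @param relative_ID paired cell label or -1.
#' @param relationship `"mother"` or `"bud"`.
#' @param emerg_frame_i,division_frame_i frame indices or -1 (unknown).
#' @param is_history_known,is_cell_excluded,is_cell_dead logical flags.
#' @return one-row data frame in the annotation schema.
#' @export
annotation_row <- function(frame_i, Cell_ID, cell_cycle_stage = "G1",
                           generation_num = 2L, relative_ID = -1L,
                           relationship = "mother", emerg_frame_i = -1L,
                           division_frame_i = -1L, is_history_known = TRUE,
                           is_cell_excluded = FALSE, is_cell_dead = FALSE) {
  data.frame(frame_i = as.integer(frame_i), Cell_ID = as.integer(Cell_ID),
             cell_cycle_stage = cell_cycle_stage,
             generation_num = as.integer(generation_num),
             relative_ID = as.integer(relative_ID),
             relationship = relationship,
             emerg_frame_i = as.integer(emerg_frame_i),
             division_frame_i = as.integer(division_frame_i),
             is_history_known = is_history_known,
             is_cell_excluded = is_cell_excluded,
             is_cell_dead = is_cell_dead, stringsAsFactors = FALSE)
}

# Canonical row order and column set; tolerates missing optional columns.
normalize_annotations <- function(table) {
  for (col in c("is_cell_excluded", "is_cell_dead"))
    if (is.null(table[[col]])) table[[col]] <- rep(FALSE, nrow(table))
  missing <- setdiff(ANNOT_COLUMNS, names(table))
  if (length(missing))
    stop("annotation table lacks column(s): ", paste(missing, collapse = ", "))
  table <- table[ANNOT_COLUMNS]
  table <- table[order(table$frame_i, table$Cell_ID), , drop = FALSE]
  rownames(table) <- NULL
  for (col in c("frame_i", "Cell_ID", "generation_num", "relative_ID",
                "emerg_frame_i", "division_frame_i"))
    table[[col]] <- as.integer(table[[col]])
  table
}

#' Validate an annotation table
#'
#' Checks every structural invariant of the pedigree model and returns the
#' violations as data, not as errors, so a table can be inspected and
#' repaired. Rules checked:
#'
#' * `duplicate_key`: at most one row per (frame_i, Cell_ID);
#' * `bad_stage` / `bad_relationship`: enum values;
#' * `bud_needs_mother`: a bud must be in S/G2/M with `relative_ID != -1`;
#' * `one_bud_rule`: a mother in S/G2/M has exactly one reciprocating bud
#'   row at the same frame;
#' * `bud_generation`: an undivided bud has `generation_num == 0`;
#' * `continuity`: a cell present at a frame is present at every frame back
#'   to its emergence (unless flagged excluded).
#'
#' @param table annotation data frame.
#' @return data frame of violations with columns `frame_i`, `Cell_ID`,
#'   `rule`, `detail`; zero rows when the table is consistent.
#' @export
validate_annotations <- function(table) {
  viol <- list()
  flag <- function(frame_i, Cell_ID, rule, detail) {
    viol[[length(viol) + 1L]] <<- data.frame(
      frame_i = as.integer(frame_i), Cell_ID = as.integer(Cell_ID),
      rule = rule, detail = detail, stringsAsFactors = FALSE)
  }
  if (nrow(table) == 0L) return(no_violations())
  table <- normalize_annotations(table)

  key <- paste(table$frame_i, table$Cell_ID)
  dup <- duplicated(key)
  for (i in which(dup))
    flag(table$frame_i[i], table$Cell_ID[i], "duplicate_key",
         "more than one row for this (frame_i, Cell_ID)")

  bad_st <- !(table$cell_cycle_stage %in% c("G1", "S/G2/M"))
  for (i in which(bad_st))
    flag(table$frame_i[i], table$Cell_ID[i], "bad_stage",
         paste0("unknown cell_cycle_stage '", table$cell_cycle_stage[i], "'"))
  bad_rel <- !(table$relationship %in% c("mother", "bud"))
  for (i in which(bad_rel))
    flag(table$frame_i[i], table$Cell_ID[i], "bad_relationship",
         paste0("unknown relationship '", table$relationship[i], "'"))

  is_bud <- table$relationship == "bud"
  bad_bud <- is_bud & (table$cell_cycle_stage != "S/G2/M" | table$relative_ID == -1L)
  for (i in which(bad_bud))
    flag(table$frame_i[i], table$Cell_ID[i], "bud_needs_mother",
         "a bud must be in S/G2/M with a mother relative_ID")
  bad_gen <- is_bud & table$generation_num != 0L
  for (i in which(bad_gen))
    flag(table$frame_i[i], table$Cell_ID[i], "bud_generation",
         "an undivided bud must have generation_num 0")

  # one-bud rule per frame: every S/G2/M mother has exactly one
  # reciprocating bud row at the same frame
  for (f in unique(table$frame_i)) {
    ft <- table[table$frame_i == f, , drop = FALSE]
    mothers <- ft[ft$relationship == "mother" & ft$cell_cycle_stage == "S/G2/M", ,
                  drop = FALSE]
    for (i in seq_len(nrow(mothers))) {
      mid <- mothers$Cell_ID[i]
      buds <- ft[ft$relationship == "bud" & ft$relative_ID == mid, , drop = FALSE]
      recip <- buds[buds$Cell_ID == mothers$relative_ID[i], , drop = FALSE]
      if (nrow(buds) != 1L || nrow(recip) != 1L)
        flag(f, mid, "one_bud_rule",
             sprintf("mother %d in S/G2/M has %d bud row(s) claiming it (needs exactly one, reciprocated)",
                     mid, nrow(buds)))
    }
    # a bud must point at a mother row that exists at the same frame
    buds <- ft[ft$relationship == "bud", , drop = FALSE]
    for (i in seq_len(nrow(buds))) {
      if (buds$relative_ID[i] != -1L && !(buds$relative_ID[i] %in% ft$Cell_ID))
        flag(f, buds$Cell_ID[i], "bud_needs_mother",
             sprintf("bud %d points at mother %d absent from frame %d",
                     buds$Cell_ID[i], buds$relative_ID[i], f))
    }
  }

  # continuity: each cell covers every frame between its first and last
  # appearance (unless excluded at the missing frames' side)
  for (id in unique(table$Cell_ID)) {
    rows <- table[table$Cell_ID == id, , drop = FALSE]
    if (any(rows$is_cell_excluded)) next
    fr <- sort(rows$frame_i)
    gaps <- setdiff(seq(fr[1L], fr[length(fr)]), fr)
    if (length(gaps))
      flag(gaps[1L], id, "continuity",
           sprintf("cell %d missing from frame(s) %s inside its lifetime",
                   id, paste(gaps, collapse = ",")))
  }

  if (length(viol) == 0L) return(no_violations())
  do.call(rbind, viol)
}

no_violations <- function() {
  data.frame(frame_i = integer(0), Cell_ID = integer(0),
             rule = character(0), detail = character(0),
             stringsAsFactors = FALSE)
}

#' Write / read annotation CSV
#'
#' The CSV carries exactly the schema columns, sorted by
#' (`frame_i`, `Cell_ID`), with booleans spelled `True`/`False` and missing
#' relative/division values as -1, so a write -> read round trip reproduces
#' the table field for field. Writing refuses inconsistent tables.
#'
#' @param table annotation data frame (must validate cleanly).
#' @param path CSV file path.
#' @return `path` invisibly (write); the table (read).
#' @export
write_annotations <- function(table, path) {
  v <- validate_annotations(table)
  if (nrow(v) > 0L)
    stop("annotation table is inconsistent:\n",
         paste(sprintf("  frame %d cell %d [%s]: %s", v$frame_i, v$Cell_ID,
                       v$rule, v$detail), collapse = "\n"))
  table <- normalize_annotations(table)
  out <- table
  for (col in c("is_history_known", "is_cell_excluded", "is_cell_dead"))
    out[[col]] <- ifelse(out[[col]], "True", "False")
  tmp <- paste0(path, ".tmp")
  utils::write.csv(out, tmp, row.names = FALSE, quote = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) return(empty_annotations())
  for (col in c("is_history_known", "is_cell_excluded", "is_cell_dead"))
    if (!is.null(raw[[col]]) && is.character(raw[[col]]))
      raw[[col]] <- raw[[col]] == "True"
  normalize_annotations(raw)
}

# Fetch the single row index for (frame, cell); integer(0) when absent.
annot_idx <- function(table, frame_i, cell) {
  which(table$frame_i == frame_i & table$Cell_ID == cell)
}
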