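test_that("pair_buds solves toy problems like brute force", {
  # only possible matching
  pb <- pair_buds(list(new_cells = 5L, g1_cells = 9L,
                       cost = matrix(42, 1, 1)))
  expect_equal(pb$pairs[["5"]], 9L)

  # 2x2: diagonal beats anti-diagonal (5 < 19)
  pb2 <- pair_buds(list(new_cells = c(10L, 11L), g1_cells = c(1L, 2L),
                        cost = matrix(c(2, 9, 10, 3), 2, 2)))
  expect_equal(pb2$pairs[["10"]], 1L)
  expect_equal(pb2$pairs[["11"]], 2L)

  # more buds than G1 cells: one pair + warning
  pb3 <- pair_buds(list(new_cells = c(10L, 11L), g1_cells = 1L,
                        cost = matrix(c(4, 7), 2, 1)))
  expect_length(pb3$pairs, 1L)
  expect_equal(pb3$pairs[["10"]], 1L)
  expect_true(any(vapply(pb3$warnings, `[[`, "", "kind") == "insufficient_G1"))

  # no new cells: empty result, no error
  pb4 <- pair_buds(list(new_cells = integer(0), g1_cells = c(1L, 2L),
                        cost = matrix(0, 0, 2)))
  expect_length(pb4$pairs, 0L)
  expect_length(pb4$warnings, 0L)
})

test_that("LSAP pairing equals exhaustive minimum-cost matching", {
  set.seed(2024)
  for (trial in 1:200) {
    na <- sample.int(6, 1); nb <- na + sample.int(7 - na, 1) - 1L   # na <= nb
    cost <- matrix(round(runif(na * nb, 0, 50), 1), na, nb)
    pb <- pair_buds(list(new_cells = seq_len(na), g1_cells = seq_len(nb) + 100L,
                         cost = cost))
    total <- sum(cost[cbind(as.integer(names(pb$pairs)),
                            match(pb$pairs, seq_len(nb) + 100L))])
    expect_equal(total, exhaustive_lsap(cost)$total, tolerance = 1e-9)
  }
})

test_that("pairing costs are single-linkage contour distances", {
  f <- matrix(0L, 40, 40)
  f[5:10, 5:10] <- 1L      # G1 cell
  f[5:10, 13:18] <- 2L     # new cell, 2 px gap of background columns 11:12
  f[30:35, 30:35] <- 3L    # distant G1 cell
  prob <- pairing_problem(f, new_cells = 2L, g1_cells = c(1L, 3L))
  expect_equal(prob$cost[1, 1], 3)                # cols 10 -> 13
  expect_gt(prob$cost[1, 2], 15)
  pb <- pair_buds(prob)
  expect_equal(pb$pairs[["2"]], 1L)
})

test_that("assignment eligibility enforces G1 and the one-bud history rule", {
  tb <- toy_pair_table(f0 = 2L, last = 9L)
  # cell 3 is free G1 throughout: eligible
  expect_true(check_assignment_eligibility(tb, 2L, 3L)$ok)
  # bud 8 emerges at frame 1 (mother 1 still G1) but lives into frames where
  # mother 1 reciprocates bud 2: ineligible, naming the competing bud
  tb2 <- tb
  for (f in 1:5)
    tb2 <- rbind(tb2, annotation_row(f, 8L, "S/G2/M", 0L, 3L, "bud", 1L, -1L, TRUE))
  el <- check_assignment_eligibility(tb2, 8L, 1L)
  expect_false(el$ok)
  expect_equal(el$reason, "mother_already_has_bud")
  expect_match(el$detail, "bud 2")
  # a cell in S/G2/M at the pairing frame is not an eligible mother
  tb3 <- tb
  for (f in 3:5)
    tb3 <- rbind(tb3, annotation_row(f, 9L, "S/G2/M", 0L, 3L, "bud", 3L, -1L, TRUE))
  el2 <- check_assignment_eligibility(tb3, 9L, 1L)
  expect_false(el2$ok)
  expect_equal(el2$reason, "mother_not_in_G1")
  expect_error(check_assignment_eligibility(tb, 2L, 99L), "unknown")
})

test_that("annotate_division propagates forward and increments generation", {
  tb <- toy_pair_table(f0 = 2L, last = 9L)   # pair in S/G2/M frames 2..9
  out <- annotate_division(tb, 7L, 1L)
  for (f in 7:9) {
    mi <- which(out$frame_i == f & out$Cell_ID == 1L)
    bi <- which(out$frame_i == f & out$Cell_ID == 2L)
    expect_equal(out$cell_cycle_stage[mi], "G1")
    expect_equal(out$cell_cycle_stage[bi], "G1")
    expect_equal(out$generation_num[mi], 3L)     # was 2
    expect_equal(out$generation_num[bi], 1L)
    expect_equal(out$division_frame_i[mi], 7L)
    expect_equal(out$relationship[bi], "mother")
  }
  # frames before the event untouched
  for (f in 2:6) {
    mi <- which(out$frame_i == f & out$Cell_ID == 1L)
    expect_equal(out$cell_cycle_stage[mi], "S/G2/M")
    expect_equal(out$generation_num[mi], 2L)
  }
  expect_identical(nrow(validate_annotations(out)), 0L)

  # annotating at the last frame changes only that frame
  out2 <- annotate_division(tb, 9L, 2L)        # clicking the bud works too
  expect_equal(sum(out2$cell_cycle_stage != tb$cell_cycle_stage), 2L)

  # precondition: G1 cell cannot be "divided"
  expect_error(annotate_division(out, 8L, 1L), "undo_division")
})

test_that("undo_division is the exact inverse of annotate_division", {
  tb <- budtrack:::normalize_annotations(toy_pair_table(f0 = 2L, last = 9L))
  ann <- annotate_division(tb, 5L, 1L)
  back <- undo_division(ann, 5L, 1L)
  expect_identical(back, tb)
  # undoing from the middle of the G1 stretch reverts the whole stretch
  back2 <- undo_division(ann, 8L, 1L)
  expect_identical(back2, tb)
  # precondition: cannot undo on a cell in S/G2/M
  expect_error(undo_division(tb, 5L, 1L), "S/G2/M")
})

test_that("undo stops where a cell has re-entered S/G2/M", {
  ds <- small_colony(seed = 11L, frames = 18L)
  truth <- ds$truth_table
  divs <- truth_divisions(truth)
  # find a division whose mother later re-budded
  for (q in seq_len(nrow(divs))) {
    f <- divs$frame_i[q]; cell <- divs$Cell_ID[q]
    i <- which(truth$frame_i == f & truth$Cell_ID == cell)
    mother <- truth$relative_ID[i]
    later <- truth[truth$Cell_ID == mother & truth$frame_i > f, ]
    if (any(later$cell_cycle_stage == "S/G2/M")) {
      re <- min(later$frame_i[later$cell_cycle_stage == "S/G2/M"])
      out <- undo_division(truth, f, cell)
      # reverted only up to the re-budding frame
      seg <- out[out$Cell_ID == mother & out$frame_i >= f & out$frame_i < re, ]
      expect_true(all(seg$cell_cycle_stage == "S/G2/M"))
      at_re <- out[out$Cell_ID == mother & out$frame_i == re, ]
      expect_equal(at_re$relative_ID,
                   truth$relative_ID[truth$Cell_ID == mother & truth$frame_i == re])
      break
    }
  }
})

test_that("correct_mother rewrites the bud's lifetime and restores the wrong mother", {
  tb <- toy_pair_table(f0 = 3L, last = 6L)    # bud 2 on mother 1, frames 3..6
  pre <- budtrack:::normalize_annotations(tb)
  out <- correct_mother(tb, 2L, 3L)
  expect_identical(nrow(validate_annotations(out)), 0L)
  for (f in 3:6) {
    wi <- which(out$frame_i == f & out$Cell_ID == 1L)
    ni <- which(out$frame_i == f & out$Cell_ID == 3L)
    bi <- which(out$frame_i == f & out$Cell_ID == 2L)
    expect_equal(out$cell_cycle_stage[wi], "G1")
    expect_equal(out$relative_ID[wi], -1L)
    expect_equal(out$cell_cycle_stage[ni], "S/G2/M")
    expect_equal(out$relative_ID[ni], 2L)
    expect_equal(out$relative_ID[bi], 3L)
  }
  # wrong mother's rows equal its pre-pairing state (G1, unlinked)
  w <- out[out$Cell_ID == 1L, c("cell_cycle_stage", "relative_ID", "relationship")]
  expect_true(all(w$cell_cycle_stage == "G1"))
  # ineligible new mother: has its own reciprocated bud
  tb3 <- toy_pair_table(f0 = 3L, last = 6L)
  tb3 <- rbind(tb3,
               annotation_row(4L, 7L, "S/G2/M", 0L, 3L, "bud", 4L, -1L, TRUE))
  tb3$cell_cycle_stage[tb3$Cell_ID == 3L & tb3$frame_i >= 4L] <- "S/G2/M"
  tb3$relative_ID[tb3$Cell_ID == 3L & tb3$frame_i >= 4L] <- 7L
  tb3 <- rbind(tb3, annotation_row(5L, 7L, "S/G2/M", 0L, 3L, "bud", 4L, -1L, TRUE),
               annotation_row(6L, 7L, "S/G2/M", 0L, 3L, "bud", 4L, -1L, TRUE))
  expect_error(correct_mother(tb3, 2L, 3L), "mother_already_has_bud|not an eligible")
})

test_that("random valid operation sequences keep the table consistent", {
  set.seed(31)
  ds <- small_colony(seed = 13L, frames = 14L)
  base <- ds$truth_table
  n_seq <- 60L; ops_per_seq <- 5L
  total_ops <- 0L
  for (s in seq_len(n_seq)) {
    tb <- base
    for (o in seq_len(ops_per_seq)) {
      # choose uniformly among currently-valid operations
      budded <- tb[tb$relationship == "bud", , drop = FALSE]
      divided <- tb[tb$cell_cycle_stage == "G1" & tb$division_frame_i > 0 &
                      tb$relative_ID != -1L &
                      tb$frame_i >= tb$division_frame_i, , drop = FALSE]
      choices <- c(if (nrow(budded)) "annotate", if (nrow(divided)) "undo")
      if (!length(choices)) break
      op <- sample(choices, 1L)
      if (op == "annotate") {
        k <- sample.int(nrow(budded), 1L)
        tb <- annotate_division(tb, budded$frame_i[k], budded$Cell_ID[k])
      } else {
        k <- sample.int(nrow(divided), 1L)
        tb <- tryCatch(undo_division(tb, divided$frame_i[k], divided$Cell_ID[k]),
                       error = function(e) tb)   # division at frame 0 is not undoable
      }
      total_ops <- total_ops + 1L
      expect_identical(nrow(validate_annotations(tb)), 0L)
    }
  }
  expect_gte(total_ops, 250L)
})

test_that("annotate_movie reproduces the ground-truth pedigree", {
  ds <- small_colony(seed = 21L, frames = 16L, founders = 2L)
  ann <- annotate_movie(ds$movie, divisions = truth_divisions(ds$truth_table))
  expect_identical(nrow(validate_annotations(ann$table)), 0L)
  expect_identical(ann$table, ds$truth_table)
  lt <- mother_links(ds$truth_table); lp <- mother_links(ann$table)
  expect_identical(lp[names(lt)], lt)
})
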