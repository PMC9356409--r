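test_that("IoA matrix matches direct pixel counts", {
  prev <- matrix(0L, 20, 20); prev[5:14, 5:6] <- 1L      # 20 px? no: 10x2 = 20
  prev <- matrix(0L, 20, 20); prev[5:14, 5] <- 1L        # 10 px column
  curr <- matrix(0L, 20, 20); curr[11:14, 5] <- 1L       # overlaps 4 of the 10
  m <- ioa_matrix(prev, curr)
  expect_equal(unname(m$cost[1, 1]), 0.4)

  # identity: one object, identical frames
  one <- matrix(0L, 10, 10); one[2:6, 3] <- 1L; one[2:6, 4] <- 1L
  expect_equal(unname(ioa_matrix(one, one)$cost), matrix(1, 1, 1))

  # disjoint objects
  a <- matrix(0L, 10, 10); a[1:3, 1:3] <- 1L
  b <- matrix(0L, 10, 10); b[7:9, 7:9] <- 5L
  expect_equal(unname(ioa_matrix(a, b)$cost), matrix(0, 1, 1))

  # column sums never exceed 1 (overlaps partition the previous object)
  expect_error(ioa_matrix(matrix(0L, 3, 3), matrix(0L, 4, 4)), "shape")
})

test_that("track_pair applies threshold, mutual-max and deferral rules", {
  # identical frames -> identity assignment
  f <- random_label_frame(n = 3)
  mp <- track_pair(f, f)
  expect_identical(unname(mp$assignments), as.integer(names(mp$assignments)))
  expect_length(mp$new_ids, 0L)
  expect_length(mp$lost_ids, 0L)

  # max IoA 0.3 -> new object
  prev <- matrix(0L, 20, 20); prev[1:10, 1] <- 1L
  curr <- matrix(0L, 20, 20); curr[8:10, 1] <- 1L; curr[11:14, 1] <- 1L  # 3+4=7px, 3 overlap
  curr[] <- 0L; curr[8:10, 1] <- 2L; curr[11:17, 1] <- 2L  # 10 px, 3 overlap -> IoA 0.3
  mp2 <- track_pair(prev, curr)
  expect_identical(mp2$new_ids, 2L)
  expect_length(mp2$assignments, 0L)
  expect_identical(mp2$lost_ids, 1L)

  # cross overlaps: mutual maxima pair up diagonally
  prev <- matrix(0L, 40, 40)
  prev[1:10, 1:10] <- 1L; prev[21:30, 21:30] <- 2L
  curr <- matrix(0L, 40, 40)
  curr[1:9, 1:10] <- 5L; curr[10, 1:2] <- 6L               # y5 ~ x1
  curr[21:29, 21:30] <- 6L                                  # y6 ~ x2 (plus 2px on x1)
  mp3 <- track_pair(prev, curr)
  expect_equal(mp3$assignments[["5"]], 1L)
  expect_equal(mp3$assignments[["6"]], 2L)
})

test_that("track_pair equals the brute-force statement of the rule", {
  set.seed(421)
  for (trial in 1:120) {
    prev <- random_label_frame(max_n = 6)
    curr <- if (trial %% 3 == 0) random_label_frame(max_n = 6)
            else shift_frame(prev, sample(-3:3, 1), sample(-3:3, 1))
    if (trial %% 4 == 0) {
      ids <- sort(unique(curr[curr > 0]))
      if (length(ids)) {
        perm <- stats::setNames(shuffle(ids + 10L), ids)
        curr <- permute_labels(curr, perm)
      }
    }
    got <- track_pair(prev, curr)
    want <- oracle_track_pair(prev, curr)
    expect_identical(assign_pairs(got$assignments),
                     assign_pairs(want$assignments))
    expect_identical(sort(got$new_ids), want$new_ids)
  }
})

test_that("tracking is invariant to relabeling and conserves foreground", {
  set.seed(99)
  base <- random_label_frame(n = 4)
  frames <- list(base)
  for (t in 2:5) frames[[t]] <- shift_frame(frames[[t - 1]], sample(-1:1, 1),
                                            sample(-1:1, 1))
  mv <- label_movie(frames)
  tr1 <- track_movie(mv)
  # permute labels in frames >= 1 (frame 0 fixes the output convention)
  frames2 <- frames
  for (t in 2:5) {
    ids <- sort(unique(frames2[[t]][frames2[[t]] > 0]))
    perm <- stats::setNames(rev(ids + 20L), ids)
    frames2[[t]] <- permute_labels(frames2[[t]], perm)
  }
  tr2 <- track_movie(label_movie(frames2))
  expect_identical(tr1$movie$frames, tr2$movie$frames)
  # conservation: foreground pixel sets untouched
  for (t in 1:5)
    expect_identical(tr1$movie$frames[[t]] > 0, frames[[t]] > 0)
})

test_that("a permuted label mid-movie keeps a constant output identity", {
  f <- matrix(0L, 30, 30); f[5:12, 5:12] <- 1L; f[20:27, 18:25] <- 2L
  frames <- list(f, f, f, permute_labels(f, c(`1` = 2L, `2` = 1L)), f)
  tr <- track_movie(label_movie(frames))
  for (t in 1:5) expect_identical(tr$movie$frames[[t]], f)
})

test_that("a new object gets the next never-used ID", {
  f <- matrix(0L, 30, 30); f[5:12, 5:12] <- 3L; f[20:27, 18:25] <- 7L
  f2 <- f; f2[1:4, 25:28] <- 9L   # far from everything: IoA 0
  tr <- track_movie(label_movie(list(f, f, f2, f2)))
  ids2 <- sort(unique(tr$movie$frames[[3]][tr$movie$frames[[3]] > 0]))
  expect_identical(ids2, c(3L, 7L, 8L))   # max used was 7 -> new cell is 8
  expect_identical(tr$mappings[[2]]$new_ids[["9"]], 8L)
  # static movie: zero new IDs anywhere
  trs <- track_movie(label_movie(list(f, f, f)))
  expect_true(all(vapply(trs$mappings, function(m) length(m$new_ids), 1L) == 0L))
})

test_that("an IoA of exactly the threshold is assigned, just below is new", {
  prev <- matrix(0L, 40, 40); prev[1:10, 1] <- 1L          # 10 px
  curr <- matrix(0L, 40, 40); curr[7:10, 1] <- 4L          # 4/10 = 0.4 exactly
  mp <- track_pair(prev, curr)
  expect_equal(mp$assignments[["4"]], 1L)
  expect_length(mp$new_ids, 0L)

  prev2 <- matrix(0L, 40, 40); prev2[, 1:25] <- 0L
  prev2[1:40, 1:25] <- 1L                                  # 1000 px
  curr2 <- matrix(0L, 40, 40); curr2[1:20, 1:20] <- 4L     # 400 px
  curr2[20, 20] <- 0L                                      # 399 overlap -> 0.399
  mp2 <- track_pair(prev2, curr2)
  expect_identical(mp2$new_ids, 4L)
})
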