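test_that("volume estimates match solids of revolution", {
  v <- estimate_volume(mk_disk(20))
  expect_equal(v$volume_vox, 4 / 3 * pi * 20^3, tolerance = 0.02)

  rect <- matrix(0L, 40, 20); rect[5:34, 5:15] <- 1L   # 30 x 11
  v2 <- estimate_volume(rect)
  expect_equal(v2$volume_vox, pi * 5.5^2 * 30, tolerance = 0.03)

  px <- matrix(0L, 3, 3); px[2, 2] <- 1L
  expect_equal(estimate_volume(px)$volume_vox, pi * 0.25)

  expect_error(estimate_volume(matrix(0L, 4, 4)), "empty")

  # femtolitre conversion is cubic in the pixel size
  expect_equal(estimate_volume(mk_disk(10), pixel_size_um = 0.5)$volume_fl,
               estimate_volume(mk_disk(10))$volume_vox * 0.125)
})

test_that("volume scales as k^3 and is rotation invariant", {
  v10 <- estimate_volume(mk_disk(10))$volume_vox
  for (k in c(2, 3))
    expect_equal(estimate_volume(mk_disk(10 * k))$volume_vox / v10, k^3,
                 tolerance = 0.05)

  ell <- function(a, b, th, n = 90) {
    m <- matrix(0L, n, n); ctr <- (n + 1) / 2
    for (i in 1:n) for (j in 1:n) {
      x <- i - ctr; y <- j - ctr
      u <- x * cos(th) + y * sin(th); w <- -x * sin(th) + y * cos(th)
      if ((u / a)^2 + (w / b)^2 <= 1) m[i, j] <- 1L
    }
    m
  }
  v0 <- estimate_volume(ell(25, 15, 0))$volume_vox
  for (th in c(0.3, 0.7, 1.1, 2.0))
    expect_equal(estimate_volume(ell(25, 15, th))$volume_vox, v0,
                 tolerance = 0.03)
})

test_that("fluorescence metrics follow their definitions", {
  lab <- matrix(0L, 20, 20); lab[4:8, 4:8] <- 1L          # 25 px
  inten <- matrix(100, 20, 20); inten[lab == 1L] <- 300
  fm <- fluor_metrics(lab, inten)
  expect_equal(fm$bg_median, 100)
  expect_equal(fm$corrected_mean, 200)
  expect_equal(fm$amount, 5000)
  expect_equal(fm$concentration_vox, 5000 / fm$volume_vox)

  # cell at background level -> amount 0
  flat <- matrix(100, 20, 20)
  expect_equal(fluor_metrics(lab, flat)$amount, 0)

  # fully covered frame has no background
  full <- matrix(1L, 5, 5)
  expect_error(fluor_metrics(full, matrix(1, 5, 5)), "background")
  expect_error(fluor_metrics(lab, matrix(0, 3, 3)), "shape")
})

test_that("amounts are exactly invariant under a constant intensity offset", {
  set.seed(8)
  lab <- mk_disk(7); lab[12:14, 2:4] <- 2L
  inten <- matrix(runif(length(lab), 50, 150), nrow(lab))
  f1 <- fluor_metrics(lab, inten)
  f2 <- fluor_metrics(lab, inten + 982.7)
  expect_equal(f1$amount, f2$amount, tolerance = 1e-9)
})

test_that("mother+bud combination sums amounts and conserves the total", {
  tb <- toy_pair_table(f0 = 2L, last = 4L)
  metrics <- do.call(rbind, lapply(0:4, function(f) {
    ids <- unique(tb$Cell_ID[tb$frame_i == f])
    data.frame(frame_i = f, id = ids, amount = 1000 * ids,
               volume_vox = 100 * ids)
  }))
  comb <- combine_mother_bud(tb, metrics)
  # budded frames: mother 1 sums bud 2's amount
  for (f in 2:4) {
    expect_equal(comb$amount[comb$frame_i == f & comb$Cell_ID == 1L], 3000)
    expect_equal(comb$volume_vox[comb$frame_i == f & comb$Cell_ID == 1L], 300)
    expect_equal(comb$bud_ID[comb$frame_i == f & comb$Cell_ID == 1L], 2L)
  }
  # G1 frames pass through
  expect_equal(comb$amount[comb$frame_i == 0L & comb$Cell_ID == 1L], 1000)
  expect_equal(comb$amount[comb$frame_i == 3L & comb$Cell_ID == 3L], 3000)
  # conservation per frame: combined total equals per-cell total
  for (f in 0:4) {
    expect_equal(sum(comb$amount[comb$frame_i == f]),
                 sum(metrics$amount[metrics$frame_i == f]))
  }
})

test_that("traces align at bud emergence and non-budding cells are excluded", {
  tb <- toy_pair_table(f0 = 2L, last = 6L)
  series <- do.call(rbind, lapply(0:6, function(f)
    data.frame(frame_i = f, Cell_ID = c(1L, 3L), value = f)))
  al <- align_at_bud_emergence(tb, series)
  a1 <- al$aligned[al$aligned$Cell_ID == 1L, ]
  expect_equal(a1$t, a1$frame_i - 2L)       # bud 2 emerged at frame 2
  expect_equal(a1$t[a1$frame_i == 2L], 0L)
  expect_true(3L %in% al$excluded$Cell_ID)  # cell 3 never buds
  expect_false(3L %in% al$aligned$Cell_ID)
})
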