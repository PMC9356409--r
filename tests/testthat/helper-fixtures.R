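# Mask builders -------------------------------------------------------------

mk_disk <- function(r, n = 2 * r + 9, center = NULL, value = 1L) {
  m <- matrix(0L, n, n)
  if (is.null(center)) center <- c((n + 1) / 2, (n + 1) / 2)
  for (i in seq_len(n)) for (j in seq_len(n))
    if ((i - center[1])^2 + (j - center[2])^2 <= r^2) m[i, j] <- value
  m
}

mk_rect <- function(h, w, n = max(h, w) + 10, value = 1L) {
  m <- matrix(0L, n, n)
  r0 <- floor((n - h) / 2) + 1L; c0 <- floor((n - w) / 2) + 1L
  m[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- value
  m
}

# Two overlapping disks as one label, with the true per-pixel partition for
# split accuracy checks. Ground truth follows how merged objects arise from
# label masks: the first (mother) disk owns every pixel it covers, the
# second (bud) disk owns only its pixels outside the mother -- for equal
# disks ties go to the nearer center.
mk_dumbbell <- function(r1, r2, dist, pad = 6) {
  H <- ceiling(2 * max(r1, r2) + 2 * pad)
  W <- ceiling(2 * r1 + dist + 2 * r2 + 2 * pad)
  m <- matrix(0L, H, W)
  truth <- matrix(0L, H, W)
  cy <- H / 2; c1 <- c(cy, pad + r1); c2 <- c(cy, c1[2] + dist)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    d1 <- sqrt((i - c1[1])^2 + (j - c1[2])^2)
    d2 <- sqrt((i - c2[1])^2 + (j - c2[2])^2)
    in1 <- d1 <= r1; in2 <- d2 <= r2
    if (in1 || in2) {
      m[i, j] <- 1L
      truth[i, j] <- if (in1 && in2) {
        if (abs(r1 - r2) < 1e-9) (if (d1 <= d2) 1L else 2L) else 1L
      } else if (in1) 1L else 2L
    }
  }
  list(mask = m, truth = truth, c1 = c1, c2 = c2)
}

# Random merged mother-bud geometry: bud/mother area ratio at most
# max_ratio, overlap kept below the bud radius so a constriction exists.
random_dumbbell <- function(max_ratio = 0.3) {
  r1 <- runif(1, 9, 14)
  r2 <- r1 * sqrt(runif(1, 0.05, max_ratio))
  ov <- runif(1, 0.5, min(3, 0.8 * r2))
  mk_dumbbell(r1, r2, (r1 + r2) - ov)
}

# Random frame with up to max_n axis-aligned rectangles (labels 1..n),
# later labels overwrite earlier ones so shapes may occlude.
random_label_frame <- function(max_n = 6, n = NULL, shape = c(48L, 48L)) {
  if (is.null(n)) n <- sample.int(max_n, 1L)
  f <- matrix(0L, shape[1L], shape[2L])
  for (id in seq_len(n)) {
    h <- sample(4:12, 1L); w <- sample(4:12, 1L)
    r0 <- sample.int(shape[1L] - h, 1L); c0 <- sample.int(shape[2L] - w, 1L)
    f[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- id
  }
  f
}

# Jitter a frame's objects by small shifts, optionally permuting labels.
shift_frame <- function(f, dr = 0L, dc = 0L) {
  out <- matrix(0L, nrow(f), ncol(f))
  src_r <- seq_len(nrow(f)); src_c <- seq_len(ncol(f))
  dst_r <- src_r + dr; dst_c <- src_c + dc
  ok_r <- dst_r >= 1L & dst_r <= nrow(f); ok_c <- dst_c >= 1L & dst_c <= ncol(f)
  out[dst_r[ok_r], dst_c[ok_c]] <- f[src_r[ok_r], src_c[ok_c]]
  out
}

# sample() treats a length-1 vector as 1:n; this never does.
shuffle <- function(x) x[sample.int(length(x))]

permute_labels <- function(f, perm) {
  # perm: named integer vector old -> new
  out <- f
  for (old in names(perm)) out[f == as.integer(old)] <- perm[[old]]
  out
}

# Tracking oracle ------------------------------------------------------------
# Naive re-statement of the assignment rule, written with per-label pixel
# sets and explicit loops, independent of the package implementation.
oracle_track_pair <- function(prev, curr, thr = 0.4) {
  pids <- sort(unique(prev[prev > 0L])); cids <- sort(unique(curr[curr > 0L]))
  ioa <- function(y, x) sum(curr == y & prev == x) / sum(prev == x)
  M <- matrix(0, length(cids), length(pids))
  for (i in seq_along(cids)) for (j in seq_along(pids))
    M[i, j] <- ioa(cids[i], pids[j])
  new_ids <- integer(0)
  assignments <- stats::setNames(integer(0), character(0))
  non_new <- integer(0)
  for (i in seq_along(cids)) {
    best <- if (length(pids)) max(M[i, ]) else 0
    if (best < thr) new_ids <- c(new_ids, cids[i]) else non_new <- c(non_new, i)
  }
  argmax_first <- function(i) which(M[i, ] == max(M[i, ]))[1L]
  for (i in non_new) {
    j <- argmax_first(i)
    blocked <- FALSE
    for (i2 in setdiff(non_new, i)) {
      if (M[i2, j] > M[i, j]) blocked <- TRUE
      if (M[i2, j] == M[i, j] && argmax_first(i2) == j && cids[i2] < cids[i])
        blocked <- TRUE
    }
    if (blocked) new_ids <- c(new_ids, cids[i])
    else { assignments[as.character(cids[i])] <- pids[j] }
  }
  list(assignments = assignments, new_ids = sort(new_ids))
}

# Canonical "curr -> prev" pairs for comparing assignment maps.
assign_pairs <- function(x) {
  if (length(x) == 0L) return(character(0))
  sort(paste(names(x), unname(x)))
}

# Exhaustive minimum-cost matching oracle ------------------------------------
# All injective assignments of rows to columns (rows <= cols), recursively.
exhaustive_lsap <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  best <- list(total = Inf, sol = NULL)
  rec <- function(row, used, total, sol) {
    if (total >= best$total) return()
    if (row > n) { best <<- list(total = total, sol = sol); return() }
    for (j in seq_len(m)) if (!used[j]) {
      used[j] <- TRUE
      rec(row + 1L, used, total + cost[row, j], c(sol, j))
      used[j] <- FALSE
    }
  }
  rec(1L, logical(m), 0, integer(0))
  best
}

# Toy annotation tables ------------------------------------------------------

# One mother (1) paired with a bud (2) in S/G2/M from frame f0 to the end;
# a bystander G1 cell (3) present throughout.
toy_pair_table <- function(f0 = 2L, last = 9L) {
  rows <- list()
  for (f in 0:last) {
    if (f < f0) {
      rows <- c(rows, list(annotation_row(f, 1L, "G1", 2L, -1L, "mother", -1L,
                                          -1L, FALSE)))
    } else {
      rows <- c(rows, list(
        annotation_row(f, 1L, "S/G2/M", 2L, 2L, "mother", -1L, -1L, FALSE),
        annotation_row(f, 2L, "S/G2/M", 0L, 1L, "bud", f0, -1L, TRUE)))
    }
    rows <- c(rows, list(annotation_row(f, 3L, "G1", 2L, -1L, "mother", -1L,
                                        -1L, FALSE)))
  }
  do.call(rbind, rows)
}

# Small colony for state-machine and end-to-end tests.
small_colony <- function(seed = 3L, frames = 14L, founders = 1L) {
  grow_colony(colony_config(n_founders = founders, frames = frames,
                            frame_shape = c(96L, 96L), seed = seed))
}

# Division events (frame, cell) of a truth table: the bud-side transition
# generation 0 -> 1 happens exactly once per division.
truth_divisions <- function(truth) {
  post <- truth[truth$frame_i == truth$division_frame_i &
                  truth$generation_num == 1L &
                  truth$relationship == "mother", , drop = FALSE]
  unique(data.frame(frame_i = post$division_frame_i, Cell_ID = post$Cell_ID))
}

# First bud -> mother links of a table, named by bud label.
mother_links <- function(table) {
  b <- table[table$relationship == "bud", , drop = FALSE]
  b <- b[!duplicated(b$Cell_ID), , drop = FALSE]
  stats::setNames(b$relative_ID, b$Cell_ID)
}
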