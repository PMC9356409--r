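#' Configuration for a synthetic budding-yeast colony
#'
#' The generator emulates the geometry that tracking, pairing and
#' annotation operate on: ellipse-shaped cells that grow exponentially,
#' emit a tangent bud after a G1 period, and divide a fixed number of
#' frames after bud emergence, with small random centroid jitter and
#' collision pushes between neighbours. Defaults approximate a budding
#' yeast cycle imaged every few minutes: roughly five frames of G1, eight
#' frames of budded (S/G2/M) growth, a bud emerging at 15% of the mother's
#' area, and ~3% area growth per frame.
#'
#' @param n_founders number of founder cells at frame 0.
#' @param frames number of time points.
#' @param frame_shape image size, `c(rows, cols)`.
#' @param growth_rate fractional area increase per frame (buds grow at
#'   twice this rate until division).
#' @param bud_period frames between bud emergence and division.
#' @param bud_initial_ratio bud/mother area ratio at emergence, in (0, 0.5).
#' @param jitter_px standard deviation of per-frame centroid jitter.
#' @param seed RNG seed; identical seeds give bit-identical datasets.
#' @param g1_period frames a cell spends in G1 before it may bud again.
#' @param founder_radius founder cell radius in pixels.
#' @param mother_min_area_frac size-control threshold: a cell buds only
#'   once its area reaches this fraction of the founder area (new-born
#'   daughters grow at twice `growth_rate` until they reach it), mirroring
#'   the size checkpoint at Start.
#' @return list of class `colony_config`.
#' @export
colony_config <- function(n_founders = 3L, frames = 30L,
                          frame_shape = c(160L, 160L), growth_rate = 0.03,
                          bud_period = 8L, bud_initial_ratio = 0.15,
                          jitter_px = 0.3, seed = 1L, g1_period = 4L,
                          founder_radius = 8, mother_min_area_frac = 0.8) {
  stopifnot(n_founders >= 1L, frames >= 1L, length(frame_shape) == 2L,
            all(frame_shape >= 16L), growth_rate > 0, bud_period >= 1L,
            bud_initial_ratio > 0, bud_initial_ratio < 0.5, jitter_px >= 0,
            g1_period >= 1L, founder_radius > 1, mother_min_area_frac > 0)
  structure(list(n_founders = as.integer(n_founders), frames = as.integer(frames),
                 frame_shape = as.integer(frame_shape), growth_rate = growth_rate,
                 bud_period = as.integer(bud_period),
                 bud_initial_ratio = bud_initial_ratio, jitter_px = jitter_px,
                 seed = as.integer(seed), g1_period = as.integer(g1_period),
                 founder_radius = founder_radius,
                 mother_min_area_frac = mother_min_area_frac),
            class = "colony_config")
}

# Support radius of an ellipse (semi-axes a >= b, major axis at `angle`)
# along direction `phi`.
ellipse_support <- function(a, b, angle, phi) {
  d <- phi - angle
  (a * b) / sqrt((b * cos(d))^2 + (a * sin(d))^2)
}

# Rasterize one ellipse: pixel centers inside (center-in-ellipse test).
ellipse_pixels <- function(center, a, b, angle, shape) {
  r0 <- max(1L, floor(center[1L] - a)); r1 <- min(shape[1L], ceiling(center[1L] + a))
  c0 <- max(1L, floor(center[2L] - a)); c1 <- min(shape[2L], ceiling(center[2L] + a))
  if (r0 > r1 || c0 > c1) return(matrix(integer(0), 0L, 2L))
  gr <- expand.grid(r = r0:r1, c = c0:c1)
  x <- gr$r - center[1L]; y <- gr$c - center[2L]
  u <- x * cos(angle) + y * sin(angle)
  v <- -x * sin(angle) + y * cos(angle)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  cbind(gr$r[inside], gr$c[inside])
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Grow a synthetic colony with ground truth
#'
#' Simulates a budding-yeast colony under the rules of [colony_config()]
#' and returns the label movie together with the ground-truth annotation
#' table (which always passes [validate_annotations()]) and the per-cell
#' track list. Labels are stable over time, so the movie is its own
#' ground-truth tracking.
#'
#' @param config a [colony_config()].
#' @param pixel_size_um pixel size stored in the movie.
#' @return list of class `synthetic_dataset` with `movie` ([label_movie]),
#'   `truth_table` (annotation data frame), `truth_tracks` (named list,
#'   id -> integer vector of 0-based frames present), and `config`.
#' @export
grow_colony <- function(config, pixel_size_um = 1.0) {
  stopifnot(inherits(config, "colony_config"))
  with_seed(config$seed, {
    shape <- config$frame_shape
    # cell state
    cells <- data.frame(id = integer(0), r = numeric(0), c = numeric(0),
                        area = numeric(0), aspect = numeric(0), angle = numeric(0),
                        stage = character(0), gen = integer(0), relative = integer(0),
                        relationship = character(0), emerg = integer(0),
                        division = integer(0), history = logical(0),
                        g1_timer = integer(0), bud_age = integer(0),
                        bud_phi = numeric(0), stringsAsFactors = FALSE)
    add_cell <- function(df, id, r, c, area, stage, gen, relative, relationship,
                         emerg, history, bud_phi = 0) {
      rbind(df, data.frame(id = id, r = r, c = c, area = area,
                           aspect = stats::runif(1, 1.02, 1.25),
                           angle = stats::runif(1, 0, pi),
                           stage = stage, gen = gen, relative = relative,
                           relationship = relationship, emerg = emerg,
                           division = -1L, history = history, g1_timer = 0L,
                           bud_age = 0L, bud_phi = bud_phi,
                           stringsAsFactors = FALSE))
    }
    # founders on a loose grid around the center
    n <- config$n_founders
    cx <- shape[1L] / 2; cy <- shape[2L] / 2
    ring_r <- config$founder_radius * 2.6 * max(1, sqrt(n / 2))
    for (k in seq_len(n)) {
      ang <- 2 * pi * (k - 1) / max(1L, n) + stats::runif(1, -0.2, 0.2)
      rr <- if (n == 1L) cx else cx + ring_r * cos(ang) / 2 + stats::runif(1, -1, 1)
      cc <- if (n == 1L) cy else cy + ring_r * sin(ang) / 2 + stats::runif(1, -1, 1)
      cells <- add_cell(cells, k, rr, cc, pi * config$founder_radius^2,
                        "G1", 2L, -1L, "mother", -1L, FALSE)
    }
    next_id <- n + 1L
    semi_axes <- function(i) {
      re <- sqrt(cells$area[i] / pi)
      c(a = re * sqrt(cells$aspect[i]), b = re / sqrt(cells$aspect[i]))
    }
    place_bud <- function(i) {
      # tangent position along the stored budding direction, slight overlap
      j <- which(cells$id == cells$relative[i])
      sm <- semi_axes(j); sb <- semi_axes(i)
      phi <- cells$bud_phi[i]
      d <- ellipse_support(sm["a"], sm["b"], cells$angle[j], phi) +
           ellipse_support(sb["a"], sb["b"], cells$angle[i], phi + pi) - 0.8
      cells$r[i] <<- cells$r[j] + d * cos(phi)
      cells$c[i] <<- cells$c[j] + d * sin(phi)
    }
    resolve_collisions <- function() {
      # anchors: every cell that is not an attached bud; net displacement per
      # frame is capped so identities remain trackable by overlap (residual
      # contact is resolved over the following frames instead)
      start_r <- cells$r; start_c <- cells$c
      names(start_r) <- names(start_c) <- cells$id
      for (iter in seq_len(50L)) {
        moved <- FALSE
        anchors <- which(cells$relationship != "bud")
        for (ai in seq_along(anchors)) {
          i <- anchors[ai]
          if (ai < length(anchors)) for (bi in seq(ai + 1L, length(anchors))) {
            j <- anchors[bi]
            dr <- cells$r[j] - cells$r[i]; dc <- cells$c[j] - cells$c[i]
            d <- sqrt(dr^2 + dc^2); if (d < 1e-6) { dr <- 1; dc <- 0; d <- 1 }
            phi <- atan2(dc, dr)
            si <- semi_axes(i); sj <- semi_axes(j)
            need <- ellipse_support(si["a"], si["b"], cells$angle[i], phi) +
                    ellipse_support(sj["a"], sj["b"], cells$angle[j], phi + pi) + 1.2
            # attached buds enlarge the footprint of their anchor
            for (idx in c(i, j)) {
              kb <- which(cells$relationship == "bud" & cells$relative == cells$id[idx])
              if (length(kb)) {
                sb <- semi_axes(kb[1L])
                need <- need + 0.6 * max(sb)
              }
            }
            if (d < need) {
              push <- (need - d) / 2
              cells$r[i] <<- cells$r[i] - push * cos(phi)
              cells$c[i] <<- cells$c[i] - push * sin(phi)
              cells$r[j] <<- cells$r[j] + push * cos(phi)
              cells$c[j] <<- cells$c[j] + push * sin(phi)
              moved <- TRUE
            }
          }
        }
        # clamp anchors inside the frame
        for (i in anchors) {
          s <- semi_axes(i); marg <- s["a"] + 2
          if (marg * 2 > min(shape))
            stop("overcrowded geometry: cells no longer fit; use a larger frame_shape")
          old_r <- cells$r[i]; old_c <- cells$c[i]
          cells$r[i] <<- min(max(cells$r[i], marg), shape[1L] - marg)
          cells$c[i] <<- min(max(cells$c[i], marg), shape[2L] - marg)
          if (cells$r[i] != old_r || cells$c[i] != old_c) moved <- TRUE
        }
        # cap each anchor's net displacement this frame at a fraction of its
        # own radius (new cells, absent from start_*, are uncapped)
        for (i in anchors) {
          key <- as.character(cells$id[i])
          if (is.na(start_r[key])) next
          dr <- cells$r[i] - start_r[key]; dc <- cells$c[i] - start_c[key]
          d <- sqrt(dr^2 + dc^2)
          cap <- max(1.5, 0.50 * sqrt(cells$area[i] / pi))
          if (d > cap) {
            cells$r[i] <<- start_r[key] + dr * cap / d
            cells$c[i] <<- start_c[key] + dc * cap / d
          }
        }
        # re-attach buds to their (possibly moved) mothers
        for (i in which(cells$relationship == "bud")) place_bud(i)
        if (!moved) return(invisible(TRUE))
      }
      invisible(FALSE)
    }
    rasterize <- function() {
      frame <- matrix(0L, shape[1L], shape[2L])
      for (i in order(cells$id)) {
        s <- semi_axes(i)
        px <- ellipse_pixels(c(cells$r[i], cells$c[i]), s["a"], s["b"],
                             cells$angle[i], shape)
        if (nrow(px) == 0L)
          stop("overcrowded geometry: cell ", cells$id[i],
               " rasterized to zero pixels; use a larger frame_shape")
        keep <- frame[px] == 0L
        if (!any(keep))
          stop("overcrowded geometry: cell ", cells$id[i],
               " fully covered; use a larger frame_shape")
        frame[px[keep, , drop = FALSE]] <- cells$id[i]
      }
      frame
    }
    snapshot_rows <- function(t) {
      do.call(rbind, lapply(seq_len(nrow(cells)), function(i)
        annotation_row(t, cells$id[i], cell_cycle_stage = cells$stage[i],
                       generation_num = cells$gen[i],
                       relative_ID = cells$relative[i],
                       relationship = cells$relationship[i],
                       emerg_frame_i = cells$emerg[i],
                       division_frame_i = cells$division[i],
                       is_history_known = cells$history[i])))
    }

    frames_out <- vector("list", config$frames)
    table_rows <- list()
    resolve_collisions()
    frames_out[[1L]] <- rasterize()
    table_rows[[1L]] <- snapshot_rows(0L)

    if (config$frames > 1L) for (t in seq_len(config$frames - 1L)) {
      # growth: buds and under-sized daughters grow at twice the base rate
      is_bud <- cells$relationship == "bud"
      min_area <- config$mother_min_area_frac * pi * config$founder_radius^2
      fast <- is_bud | cells$area < min_area
      cells$area <- cells$area * (1 + config$growth_rate * ifelse(fast, 2, 1))
      # divisions: buds reaching bud_period
      cells$bud_age[is_bud] <- cells$bud_age[is_bud] + 1L
      for (i in which(cells$relationship == "bud" & cells$bud_age >= config$bud_period)) {
        j <- which(cells$id == cells$relative[i])
        cells$stage[c(i, j)] <- "G1"
        cells$division[c(i, j)] <- t
        cells$relationship[i] <- "mother"
        cells$gen[i] <- 1L
        cells$gen[j] <- cells$gen[j] + 1L
        cells$g1_timer[c(i, j)] <- 0L
        cells$bud_age[i] <- 0L
      }
      # G1 progression and bud emergence
      in_g1 <- cells$stage == "G1"
      cells$g1_timer[in_g1] <- cells$g1_timer[in_g1] + 1L
      for (i in which(cells$stage == "G1" & cells$g1_timer >= config$g1_period &
                      cells$area >= min_area)) {
        bud_id <- next_id; next_id <- next_id + 1L
        # buds point outward, away from the colony's area centroid, with
        # angular jitter -- keeps emergence sites in free space as in a
        # radially growing colony
        w <- cells$area / sum(cells$area)
        ctr <- c(sum(cells$r * w), sum(cells$c * w))
        off <- c(cells$r[i] - ctr[1L], cells$c[i] - ctr[2L])
        phi <- if (sqrt(sum(off^2)) < 1e-6) stats::runif(1, 0, 2 * pi)
               else atan2(off[2L], off[1L]) + stats::runif(1, -0.7, 0.7)
        cells <- add_cell(cells, bud_id, cells$r[i], cells$c[i],
                          config$bud_initial_ratio * cells$area[i],
                          "S/G2/M", 0L, cells$id[i], "bud", t, TRUE, phi)
        i2 <- which(cells$id == cells$id[i])  # row index unchanged, be explicit
        cells$stage[i2] <- "S/G2/M"
        cells$relative[i2] <- bud_id
        cells$relationship[i2] <- "mother"
        place_bud(which(cells$id == bud_id))
      }
      # jitter on anchors
      anchors <- which(cells$relationship != "bud")
      cells$r[anchors] <- cells$r[anchors] + stats::rnorm(length(anchors), 0, config$jitter_px)
      cells$c[anchors] <- cells$c[anchors] + stats::rnorm(length(anchors), 0, config$jitter_px)
      for (i in which(cells$relationship == "bud")) place_bud(i)
      resolve_collisions()
      frames_out[[t + 1L]] <- rasterize()
      table_rows[[t + 1L]] <- snapshot_rows(t)
    }

    movie <- label_movie(frames_out, pixel_size_um = pixel_size_um)
    truth <- normalize_annotations(do.call(rbind, table_rows))
    tracks <- lapply(split(truth$frame_i, truth$Cell_ID), sort)
    structure(list(movie = movie, truth_table = truth, truth_tracks = tracks,
                   config = config), class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d frame(s), %d cell(s), seed %d\n",
              n_frames(x$movie), length(x$truth_tracks), x$config$seed))
  invisible(x)
}

#' Inject controlled errors into a synthetic dataset
#'
#' Produces a perturbed copy of the movie while keeping the original
#' ground truth, so tracking and metric code can be exercised against
#' known error counts:
#'
#' * `drop`: deletes `drop` random object-frames (false negatives);
#' * `spurious`: adds `spurious` small background blobs with fresh labels
#'   (false positives);
#' * `swap`: permanently relabels `swap` random trajectories to a fresh
#'   identity from a random mid-life frame on (exactly one first-time
#'   identity switch each);
#' * `merge_pairs`: replaces the bud's label by the mother's in one frame
#'   for `merge_pairs` mother-bud pairs (inputs for [split_object()]).
#'
#' The perturbed (frame, id) sets are disjoint across operators.
#'
#' @param data a `synthetic_dataset` from [grow_colony()].
#' @param drop,spurious,swap,merge_pairs non-negative counts.
#' @param seed RNG seed for the perturbation choices.
#' @return a `synthetic_dataset` whose `movie` is perturbed; ground truth
#'   untouched; the injected changes are recorded under `$perturbations`.
#' @export
perturb_dataset <- function(data, drop = 0L, spurious = 0L, swap = 0L,
                            merge_pairs = 0L, seed = 1L) {
  stopifnot(inherits(data, "synthetic_dataset"))
  with_seed(seed, {
    frames <- data$movie$frames
    t_n <- length(frames)
    used <- character(0)   # "frame id" keys already touched
    pert <- list(dropped = NULL, spurious = NULL, swapped = NULL, merged = NULL)

    # merge mother-bud pairs first (needs intact buds)
    if (merge_pairs > 0L) {
      tt <- data$truth_table
      buds <- tt[tt$relationship == "bud", , drop = FALSE]
      cand <- buds[!duplicated(buds$Cell_ID), , drop = FALSE]  # emergence rows
      if (nrow(cand) < merge_pairs)
        stop("not enough mother-bud pairs to merge (", nrow(cand), " available)")
      pick <- cand[sample.int(nrow(cand), merge_pairs), , drop = FALSE]
      for (q in seq_len(nrow(pick))) {
        f <- pick$frame_i[q] + 1L
        bud <- pick$Cell_ID[q]; mom <- pick$relative_ID[q]
        frames[[f]][frames[[f]] == bud] <- mom
        used <- c(used, paste(f, bud), paste(f, mom))
        pert$merged <- rbind(pert$merged,
                             data.frame(frame_i = f - 1L, mother = mom, bud = bud))
      }
    }

    obj_frames <- do.call(rbind, lapply(seq_len(t_n), function(f) {
      ids <- frame_labels(frames[[f]])
      if (length(ids)) data.frame(f = f, id = ids) else NULL
    }))
    key <- paste(obj_frames$f, obj_frames$id)

    if (swap > 0L) {
      ids <- names(data$truth_tracks)[vapply(data$truth_tracks, length, 1L) >= 2L]
      if (length(ids) < swap) stop("not enough long trajectories to swap")
      pick <- sample(ids, swap)
      fresh <- max(vapply(frames, max, integer(1))) + seq_len(swap)
      for (q in seq_along(pick)) {
        id <- as.integer(pick[q])
        fr <- data$truth_tracks[[pick[q]]]
        f0 <- fr[sample.int(length(fr) - 1L, 1L) + 1L]  # never the first frame
        for (f in fr[fr >= f0]) {
          frames[[f + 1L]][frames[[f + 1L]] == id] <- fresh[q]
          used <- c(used, paste(f + 1L, id), paste(f + 1L, fresh[q]))
        }
        pert$swapped <- rbind(pert$swapped,
                              data.frame(id = id, new_id = fresh[q], from_frame_i = f0))
      }
    }

    if (drop > 0L) {
      avail <- which(!(key %in% used))
      if (length(avail) < drop) stop("not enough objects to drop")
      pick <- sample(avail, drop)
      for (q in pick) {
        f <- obj_frames$f[q]; id <- obj_frames$id[q]
        frames[[f]][frames[[f]] == id] <- 0L
        used <- c(used, paste(f, id))
        pert$dropped <- rbind(pert$dropped,
                              data.frame(frame_i = f - 1L, id = id))
      }
    }

    if (spurious > 0L) {
      fresh <- max(vapply(frames, max, integer(1)), 0L) + seq_len(spurious)
      shape <- dim(frames[[1L]])
      placed <- 0L; tries <- 0L
      while (placed < spurious) {
        tries <- tries + 1L
        if (tries > 5000L) stop("could not place spurious blobs (frame too full)")
        f <- sample.int(t_n, 1L)
        r <- sample(5:(shape[1L] - 5L), 1L); c <- sample(5:(shape[2L] - 5L), 1L)
        nb <- frames[[f]][(r - 3L):(r + 3L), (c - 3L):(c + 3L)]
        if (any(nb != 0L)) next
        placed <- placed + 1L
        px <- ellipse_pixels(c(r, c), 2.2, 2.2, 0, shape)
        frames[[f]][px] <- fresh[placed]
        pert$spurious <- rbind(pert$spurious,
                               data.frame(frame_i = f - 1L, id = fresh[placed]))
      }
    }

    out <- data
    out$movie <- label_movie(frames, pixel_size_um = data$movie$pixel_size_um)
    out$perturbations <- pert
    out
  })
}
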