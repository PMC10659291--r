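# Fixture builders shared across test files. Everything is generated in
# code; no image files are stored.

# A standard three-disc scene (non-overlapping, fully visible).
make_three_disc_scene <- function(noise_sd = 0, seed = 11) {
  vesicle_scene_spec(
    image_shape = c(260, 260),
    shapes = list(disc_shape(c(60.5, 60.5), 25),
                  disc_shape(c(70.5, 190.5), 30),
                  disc_shape(c(190.5, 120.5), 35)),
    noise_sd = noise_sd, seed = seed)
}

# Random blob-shaped pixel region grown from a seed pixel (8-connected
# random aggregation), for Feret oracle comparisons.
random_polyomino <- function(n_pixels, seed) {
  set.seed(seed)
  px <- matrix(c(0L, 0L), 1, 2)
  occupied <- new.env(parent = emptyenv())
  assign("0,0", TRUE, envir = occupied)
  moves <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  while (nrow(px) < n_pixels) {
    base <- px[sample(nrow(px), 1), ]
    step <- moves[sample(8, 1), ]
    cand <- base + step
    key <- paste(cand, collapse = ",")
    if (!exists(key, envir = occupied)) {
      assign(key, TRUE, envir = occupied)
      px <- rbind(px, cand)
    }
  }
  # shift to positive 1-based coordinates
  px[, 1] <- px[, 1] - min(px[, 1]) + 1L
  px[, 2] <- px[, 2] - min(px[, 2]) + 1L
  colnames(px) <- c("row", "col")
  px
}

# Rasterize a disc/spherocylinder at fine resolution and count pixels:
# an independent area oracle for the closed-form expressions.
rasterized_area <- function(shape, oversample = 10) {
  bb <- evquant:::shape_bbox(shape)
  step <- 1 / oversample
  rr <- seq(bb["rmin"], bb["rmax"], by = step)
  cc <- seq(bb["cmin"], bb["cmax"], by = step)
  sd <- outer(rr, cc, function(r, c) {
    if (inherits(shape, "disc_shape")) {
      sqrt((r - shape$center[1])^2 + (c - shape$center[2])^2) - shape$radius
    } else {
      half <- (shape$axis_length - shape$width) / 2
      dr <- cos(shape$orientation); dc <- sin(shape$orientation)
      a1 <- shape$center[1] - half * dr; a2 <- shape$center[2] - half * dc
      vr <- 2 * half * dr; vc <- 2 * half * dc
      len2 <- vr^2 + vc^2
      t <- if (len2 == 0) 0 else pmin(pmax(((r - a1) * vr + (c - a2) * vc) / len2, 0), 1)
      sqrt((r - (a1 + t * vr))^2 + (c - (a2 + t * vc))^2) - shape$width / 2
    }
  })
  sum(sd < 0) * step^2
}

# 50-bead scene on a grid with known ratios plus one of each planted
# artifact class (non-round, border, saturated, signal-only).
make_fifty_bead_scene <- function(noise_sd = 50, seed = 21) {
  set.seed(seed)
  grid <- expand.grid(row = seq(40, 40 + 9 * 45, by = 45)[1:10],
                      col = seq(40, 40 + 4 * 45, by = 45)[1:5])
  beads <- data.frame(row = grid$row, col = grid$col, radius = 12,
                      reference_intensity = 1000,
                      ratio = stats::runif(50, 0.5, 2.5))
  # saturated bead: reference intensity beyond the 4000-count
  # saturation value used by the tests
  beads$reference_intensity[7] <- 5000
  # border bead
  beads$row[13] <- 4
  artifacts <- data.frame(
    row = 250, col = 252, radius = 12,
    channel = "signal", intensity = 3000)
  # elongated reference-channel artifact built from overlapping discs
  bar <- data.frame(row = 150 + seq(-30, 30, by = 5), col = 248, radius = 6,
                    channel = "reference", intensity = 1200)
  artifacts <- rbind(artifacts, bar)
  spec <- bead_scene_spec(c(470, 270), beads, artifacts = artifacts,
                          background_reference = 100, background_signal = 50,
                          noise_sd = noise_sd, seed = seed)
  list(spec = spec, beads = beads,
       saturated_id = 7L, border_id = 13L)
}

# Synthetic 5-TM prominin-style topology (N-terminus outside) with the
# given inter-TM loop lengths (ic1, ec1, ic2, ec2) in residues.
make_prominin_topology <- function(ic1 = 10, ec1 = 350, ic2 = 15, ec2 = 400,
                                   n_tail = 30, c_tail = 50, tm_len = 21,
                                   n_tm = 5) {
  loops <- c(ic1, ec1, ic2, ec2)
  segs <- data.frame(kind = "outside", start = 1L, end = n_tail)
  pos <- n_tail
  for (i in seq_len(n_tm)) {
    segs <- rbind(segs, data.frame(kind = "TM", start = pos + 1L,
                                   end = pos + tm_len))
    pos <- pos + tm_len
    if (i < n_tm) {
      len <- loops[min(i, length(loops))]
      kind_i <- if (i %% 2 == 1) "inside" else "outside"  # N-term outside
      segs <- rbind(segs, data.frame(kind = kind_i,
                                     start = pos + 1L, end = pos + len))
      pos <- pos + len
    }
  }
  last_kind <- if (n_tm %% 2 == 0) "outside" else "inside"
  segs <- rbind(segs, data.frame(kind = last_kind, start = pos + 1L,
                                 end = pos + c_tail))
  topology_annotation(segs)
}
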