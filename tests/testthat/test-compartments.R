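test_that("ring voxels lie exactly in the configured distance band (oracle check)", {
  # single sphere, anisotropic voxels, reduced radii to keep the brute
  # force oracle small
  d <- c(40, 40, 12)
  sp <- c(z = 1, y = 0.4, x = 0.4)
  ai <- arrayInd(seq_len(prod(d)), d)
  pos <- sweep(ai - 1, 2, unname(sp[c("y", "x", "z")]), `*`)
  ctr <- c(8, 8, 5.5)
  labels <- array(0L, d)
  labels[sqrt(colSums((t(pos) - ctr)^2)) <= 2] <- 1L
  prm <- ring_params(outer_um = 4, inner_um = 1.5)
  ring <- cytoplasm_mask(labels, 1L, sp, prm)
  eps <- 1e-6 # oracle floating-point slack at exact band boundaries
  dist <- brute_force_distance(labels == 1L, sp, subset = which(ring))
  expect_true(all(dist > prm$inner_um - eps & dist <= prm$outer_um + eps))
  # completeness: every voxel strictly inside the band is included
  dist_all <- brute_force_distance(labels == 1L, sp)
  must <- dist_all > prm$inner_um + eps & dist_all <= prm$outer_um - eps &
    labels == 0L
  expect_true(all(ring[must]))
})

test_that("rings exclude neighbouring nuclei and their halos, symmetrically", {
  d <- c(60, 40, 10)
  sp <- c(z = 1, y = 0.5, x = 0.5)
  ai <- arrayInd(seq_len(prod(d)), d)
  pos <- sweep(ai - 1, 2, unname(sp[c("y", "x", "z")]), `*`)
  c1 <- c(10, 10, 4.5); c2 <- c(18, 10, 4.5) # surface gap 4 um (r = 2)
  labels <- array(0L, d)
  labels[sqrt(colSums((t(pos) - c1)^2)) <= 2] <- 1L
  labels[sqrt(colSums((t(pos) - c2)^2)) <= 2] <- 2L
  prm <- ring_params(outer_um = 5, inner_um = 1.8)
  r1 <- cytoplasm_mask(labels, 1L, sp, prm)
  r2 <- cytoplasm_mask(labels, 2L, sp, prm)
  expect_false(any(r1 & labels > 0))
  expect_false(any(r2 & labels > 0))
  d_to_2 <- brute_force_distance(labels == 2L, sp, subset = which(r1))
  expect_true(all(d_to_2 > prm$inner_um)) # the other nucleus' halo too
  # overlap of the two rings is allowed and identical from both calls
  expect_gt(sum(r1 & r2), 0)
  r1b <- cytoplasm_mask(labels, 1L, sp, prm)
  expect_identical(r1, r1b)
})

test_that("inner exclusion zero makes ring plus nucleus a connected dilation", {
  d <- c(30, 30, 8)
  sp <- c(z = 1, y = 0.5, x = 0.5)
  ai <- arrayInd(seq_len(prod(d)), d)
  pos <- sweep(ai - 1, 2, unname(sp[c("y", "x", "z")]), `*`)
  labels <- array(0L, d)
  labels[sqrt(colSums((t(pos) - c(7, 7, 3.5))^2)) <= 2] <- 1L
  ring <- cytoplasm_mask(labels, 1L, sp, ring_params(3.5, 0))
  expect_false(any(ring & labels > 0))
  union <- ring | labels > 0
  expect_equal(max(label_components(union)), 1) # one connected blob
})

test_that("N/C ratio reproduces exact hand-computed compartment values", {
  cm <- constructed_compartment_movie() # nucleus 300, cyto 100, bg 50
  nc <- measure_nc(cm$movie, cm$tracks, cm$labels,
                   ring = ring_params(8.3, 3.3), min_cyto_voxels = 10)
  expect_equal(nrow(nc), 1)
  expect_equal(nc$background, 50)
  expect_equal(nc$nuc_mean, 300)
  expect_equal(nc$cyto_mean, 100)
  expect_equal(nc$nc_ratio, 5)
  # uniform compartments: ratio 1 regardless of geometry
  cu <- constructed_compartment_movie(nuc_value = 100)
  ncu <- measure_nc(cu$movie, cu$tracks, cu$labels, min_cyto_voxels = 10)
  expect_equal(ncu$nc_ratio, 1)
})

test_that("N/C ratio is invariant under affine intensity transforms", {
  cm <- constructed_compartment_movie()
  nc0 <- measure_nc(cm$movie, cm$tracks, cm$labels, min_cyto_voxels = 10)
  aff <- cm$movie
  aff$channels$ch <- aff$channels$ch * 7L + 33L # a I + b, a > 0
  nc1 <- measure_nc(aff, cm$tracks, cm$labels, min_cyto_voxels = 10)
  expect_equal(nc1$nc_ratio, nc0$nc_ratio, tolerance = 1e-12)
})

test_that("starved rings are reported but carry no ratio", {
  cm <- constructed_compartment_movie()
  nc <- measure_nc(cm$movie, cm$tracks, cm$labels,
                   min_cyto_voxels = 1e6)
  expect_equal(nrow(nc), 1)
  expect_true(is.na(nc$nc_ratio))
  expect_gt(nc$n_cyto_voxels, 0)
})

test_that("stage normalisation anchors the reference stage at 1", {
  base <- data.frame(
    embryo_id = "e1", track_id = 1L, frame = 1:10, time_s = 1:10,
    channel = "ch", nuc_mean = 1, cyto_mean = 1,
    nc_ratio = c(rep(1.2, 5), rep(3.0, 5)), background = 0,
    n_cyto_voxels = 500L,
    stage_label = rep(c("32-cell", "1k-cell"), each = 5))
  tab <- measurement_table(base, "nc_ratio")
  rel <- normalize_to_stage(tab, "32-cell")
  expect_equal(mean(rel$relative_nc[rel$stage_label == "32-cell"]), 1)
  expect_equal(unique(rel$relative_nc[rel$stage_label == "1k-cell"]), 2.5)
  # constant series: relative ratio identically 1
  cst <- base; cst$nc_ratio <- 2
  relc <- normalize_to_stage(measurement_table(cst, "nc_ratio"), "32-cell")
  expect_true(all(relc$relative_nc == 1))
  # reference stage absent: the offending pair is named
  none <- base; none$stage_label <- "64-cell"
  expect_error(normalize_to_stage(measurement_table(none, "nc_ratio"),
                                  "32-cell"),
               "missing-reference.*e1.*ch")
})

test_that("embryo-level aggregation treats the embryo as the replicate", {
  mk <- function(id, val) data.frame(
    embryo_id = id, track_id = 1:4, frame = 1L, time_s = 0,
    channel = "ch", nuc_mean = 1, cyto_mean = 1,
    nc_ratio = val + c(-.5, -.1, .1, .5), # nucleus spread must not matter
    background = 0, n_cyto_voxels = 500L, stage_label = "64-cell")
  agg <- aggregate_embryos(list(
    measurement_table(mk("e1", 2.0), "nc_ratio"),
    measurement_table(mk("e2", 2.5), "nc_ratio"),
    measurement_table(mk("e3", 3.0), "nc_ratio")))
  expect_equal(agg$n_embryos, 3L)
  expect_equal(agg$mean, 2.5)
  expect_equal(agg$sd, 0.5)
  one <- aggregate_embryos(list(measurement_table(mk("e1", 2), "nc_ratio")))
  expect_true(is.na(one$sd))
})

test_that("static single-frame measurement recovers per-nucleus means", {
  sim <- small_division_sim(noise = FALSE)
  st <- measure_static(sim$movie, frame = 2, dna_channel = "marker",
                       signal_channels = "signal")
  expect_equal(length(unique(st$label)), 4)
  # zero-noise signal nuclei at bg + nc * (cyto - bg)
  t_s <- 30 # frame 2
  want <- 50 + (1 + (3 - 1) * t_s / 450) * 150
  expect_true(all(abs(st$mean_intensity - want) / want < 0.02))
  # blank image: empty table
  blank <- multichannel_movie(
    list(dna = array(10L, c(32, 32, 3, 1)),
         sig = array(10L, c(32, 32, 3, 1))),
    spacing = c(z = 2, y = 0.5, x = 0.5), frame_interval = 1)
  expect_equal(nrow(measure_static(blank, 1, "dna", "sig")), 0)
})
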