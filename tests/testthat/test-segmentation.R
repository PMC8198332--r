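test_that("primary object identification applies the diameter range", {
  # five well-separated discs of diameter 8
  m <- matrix(FALSE, 100, 100)
  centers <- cbind(c(15, 15, 50, 85, 85), c(15, 85, 50, 15, 85))
  for (k in 1:5) m <- m | raster_disc(4, 100, centers[k, ])
  labs <- identify_primary_objects(m, 4, 20)
  expect_equal(max(labs), 5L)

  tiny <- raster_disc(1, 32)
  expect_equal(max(identify_primary_objects(tiny, 4, 20)), 0L)

  expect_error(identify_primary_objects(m, 20, 4), "diameter")
  expect_equal(max(identify_primary_objects(matrix(FALSE, 8, 8), 1, 5)), 0L)
})

test_that("objects touching the image border are discarded by default", {
  m <- raster_disc(6, 60, c(30, 30)) | raster_disc(6, 60, c(3, 30))
  labs <- identify_primary_objects(m, 2, 30)
  expect_equal(max(labs), 1L)  # only the interior disc
  labs2 <- identify_primary_objects(m, 2, 30, discard_border = FALSE)
  expect_equal(max(labs2), 2L)
  # the inverted-tissue background component can never become a lumen
  bg <- !raster_disc(10, 64)
  expect_equal(max(identify_primary_objects(bg, 2, 100)), 0L)
})

test_that("labels are contiguous 1..K after filtering", {
  m <- raster_disc(3, 64, c(10, 10)) | raster_disc(10, 64, c(40, 40)) |
    raster_disc(3, 64, c(10, 50))
  labs <- identify_primary_objects(m, 12, 50)  # only the big disc survives
  expect_equal(sort(unique(as.vector(labs))), c(0L, 1L))
})

test_that("touching nuclei are split by watershed declumping", {
  m <- raster_disc(4, 40, c(20, 16)) | raster_disc(4, 40, c(20, 25))
  expect_equal(count_components8(m), 1L)  # they touch
  labs <- identify_primary_objects(m, 4, 20, kind = "nuclei")
  expect_equal(max(labs), 2L)
})

test_that("form factor matches analytic values for standard shapes", {
  disc <- identify_primary_objects(raster_disc(64, 256), 100, 200)
  ff_disc <- measure_shape(disc)$form_factor
  expect_equal(ff_disc, 1.0, tolerance = 0.05)

  sq <- matrix(FALSE, 40, 40); sq[11:30, 11:30] <- TRUE
  ff_sq <- measure_shape(identify_primary_objects(sq, 5, 50))$form_factor
  expect_equal(ff_sq, pi / 4, tolerance = 0.05)  # analytic 4*pi*s^2/(4s)^2

  bar <- matrix(FALSE, 20, 20); bar[10, 5:14] <- TRUE
  ff_bar <- measure_shape(identify_primary_objects(bar, 1, 50))$form_factor
  expect_lt(abs(ff_bar - 4 * pi * 10 / 22^2), 0.05)  # analytic ~0.260
})

test_that("form factor of discs approaches 1 from radius 16 up", {
  for (r in c(16, 24, 40)) {
    labs <- identify_primary_objects(raster_disc(r, 4 * r), r, 4 * r)
    expect_lt(abs(measure_shape(labs)$form_factor - 1), 0.05)
  }
})

test_that("perimeter estimator agrees with polygon oracle on convex shapes", {
  # axis-aligned rectangles have exact polygon perimeters
  for (sides in list(c(10, 20), c(5, 5), c(3, 30))) {
    m <- matrix(FALSE, 50, 50)
    m[10:(9 + sides[1]), 10:(9 + sides[2])] <- TRUE
    p <- measure_shape(identify_primary_objects(m, 1, 60))$perimeter_px
    expect_equal(p, 2 * sum(sides), tolerance = 0.05 * 2 * sum(sides))
  }
  # disc: analytic circumference
  d <- measure_shape(identify_primary_objects(raster_disc(30, 100), 30, 90))
  expect_equal(d$perimeter_px, 2 * pi * 30, tolerance = 0.05 * 2 * pi * 30)
})

test_that("area units convert by pixel_size squared", {
  labs <- identify_primary_objects(raster_disc(10, 40), 10, 30)
  s1 <- measure_shape(labs, pixel_size = 1)
  s2 <- measure_shape(labs, pixel_size = 0.5)
  expect_equal(s2$area_um2, s1$area_um2 * 0.25)
  expect_equal(s2$area_px, s1$area_px)
})

test_that("roundness filter keeps discs, drops bars, and is inclusive", {
  m <- raster_disc(10, 60, c(20, 20))
  m[50, 10:50] <- TRUE  # 1 x 41 bar
  labs <- identify_primary_objects(m, 1, 50)
  shapes <- measure_shape(labs)
  expect_equal(max(labs), 2L)
  kept <- filter_by_form_factor(labs, shapes, 0.3)
  expect_equal(max(kept), 1L)
  ff_kept <- measure_shape(kept)$form_factor
  expect_gt(ff_kept, 0.3)

  # boundary rule: an object at exactly min_ff is retained
  ff_disc <- shapes$form_factor[which.max(shapes$form_factor)]
  at_exact <- filter_by_form_factor(labs, shapes, min_ff = ff_disc)
  expect_equal(max(at_exact), 1L)

  expect_error(filter_by_form_factor(labs, shapes, 0), "0, 1.2")
  expect_error(filter_by_form_factor(labs, shapes, 1.5), "0, 1.2")
})

test_that("object count is non-increasing in the roundness threshold", {
  set.seed(99)
  m <- matrix(runif(120 * 120) < 0.35, 120, 120)
  m <- EBImage::imageData(EBImage::closing(EBImage::Image(m * 1),
                                           EBImage::makeBrush(3, "box"))) > 0.5
  labs <- identify_primary_objects(m, 2, 100)
  shapes <- measure_shape(labs)
  counts <- vapply(seq(0.1, 0.9, by = 0.1), function(t) {
    max(filter_by_form_factor(labs, shapes, t), 0L)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("propagation stops at a barrier ring", {
  n <- 101
  lumen <- label_map(raster_disc(10, n) * 1L)
  boundary <- !raster_ring(24.5, 25.5, n)  # barrier ring at radius 25
  fol <- propagate_follicles(lumen, boundary, max_expansion = 30)
  area <- sum(fol == 1L)
  expect_gt(area, pi * 24^2)
  expect_lt(area, pi * 26.5^2)
  expect_true(all(fol[unclass(lumen) == 1L] == 1L))  # superset of its lumen
})

test_that("without a barrier, growth caps at the expansion distance", {
  n <- 121
  lumen <- label_map(raster_disc(10, n) * 1L)
  fol <- propagate_follicles(lumen, matrix(TRUE, n, n), max_expansion = 30)
  area <- sum(fol == 1L)
  # chamfer-geodesic cap of 30 px from a radius-10 disc: a near-disc of
  # radius ~40 (exact along the axes, chamfer octagon error on diagonals)
  expect_gt(area, pi * 38^2)
  expect_lt(area, pi * 42^2)
  mid <- (n + 1) / 2
  seed_edge <- max(which(unclass(lumen)[mid, ] > 0L))
  expect_equal(fol[mid, seed_edge + 30], 1L)  # exactly 30 px along the axis
  expect_equal(fol[mid, seed_edge + 31], 0L)  # and no further
})

test_that("contested pixels go to the nearer seed, ties to the lower label", {
  seeds <- matrix(0L, 11, 15)
  seeds[6, 4] <- 1L; seeds[6, 12] <- 2L
  fol <- propagate_follicles(label_map(seeds), matrix(TRUE, 11, 15),
                             max_expansion = 10)
  expect_equal(fol[6, 8], 1L)   # equidistant -> lower label
  expect_equal(fol[6, 7], 1L)   # nearer to seed 1
  expect_equal(fol[6, 9], 2L)   # nearer to seed 2
  expect_error(propagate_follicles(label_map(seeds),
                                   matrix(TRUE, 5, 5), 10), "shape")
})

test_that("epithelium subtraction gives the annulus", {
  n <- 101
  fol <- label_map(raster_disc(20, n) * 1L, "follicle")
  lum <- label_map(raster_disc(10, n) * 1L, "lumen")
  epi <- derive_epithelium(fol, lum)
  expect_equal(sum(epi == 1L), pi * (400 - 100), tolerance = 0.03)
  expect_equal(sum(epi > 0L & unclass(lum) > 0L), 0L)  # disjoint from lumen

  # follicle == lumen: empty epithelium, flagged
  epi2 <- derive_epithelium(lum, lum)
  expect_equal(sum(epi2), 0L)
  expect_equal(attr(epi2, "empty_labels"), 1L)

  # lumen outside its follicle is a consistency error naming the label
  shifted <- label_map(raster_disc(10, n, c(80, 80)) * 1L, "lumen")
  expect_error(derive_epithelium(fol, shifted), "1",
               class = "thyromorph_consistency_error")
})

test_that("children are assigned to the parent containing their centroid", {
  parents <- matrix(0L, 60, 60)
  parents[raster_disc(15, 60, c(20, 20))] <- 3L
  kids <- matrix(0L, 60, 60)
  kids[raster_disc(2, 60, c(20, 20))] <- 1L   # inside parent 3
  kids[raster_disc(2, 60, c(50, 50))] <- 2L   # on background
  rel <- relate_objects(label_map(kids, "nuclei"),
                        label_map(parents, "follicle"))
  expect_equal(rel$parent[rel$child == 1L], 3L)
  expect_equal(rel$parent[rel$child == 2L], 0L)
  expect_equal(nrow(rel), 2L)  # every child exactly once
})

test_that("intraluminal masking keeps only nuclei with centroids in lumina", {
  lumina <- matrix(0L, 60, 60)
  lumina[raster_disc(12, 60, c(30, 30))] <- 5L
  nuc <- matrix(0L, 60, 60)
  nuc[raster_disc(2, 60, c(30, 30))] <- 1L   # in lumen 5
  nuc[raster_disc(2, 60, c(30, 45))] <- 2L   # outside (epithelium position)
  dead <- mask_intraluminal_nuclei(label_map(nuc, "nuclei"),
                                   label_map(lumina, "lumen"))
  expect_equal(nrow(dead), 1L)
  expect_equal(dead$parent, 5L)
  expect_equal(dead$child, 1L)
})

test_that("label overrides drop listed objects reproducibly", {
  m <- raster_disc(5, 60, c(15, 15)) | raster_disc(5, 60, c(45, 45))
  labs <- identify_primary_objects(m, 2, 30)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(drop = 1L), path, row.names = FALSE)
  edited <- apply_label_overrides(labs, path)
  expect_equal(max(edited), 1L)
})

test_that("the full pipeline recovers phantom geometry and counts", {
  ph <- small_phantom()
  sec <- analyze_section(ph$channels, heatmap = FALSE)
  tr <- ph$truth
  expect_equal(nrow(sec$records), nrow(tr))
  lab <- match_truth_labels(sec, tr)
  expect_true(all(lab > 0L))
  rec <- sec$records[match(lab, sec$records$follicle_id), ]
  expect_equal(rec$lumen_area, tr$lumen_area, tolerance = 0.05)
  expect_equal(rec$epithelium_area, tr$epithelium_area, tolerance = 0.05)
  expect_equal(rec$n_cells,
               tr$n_epithelial_nuclei + tr$n_intraluminal_nuclei)
  expect_equal(rec$n_dead_cells, tr$n_intraluminal_nuclei)
  # follicle is a pixelwise superset of its lumen
  expect_true(all(sec$follicles[sec$lumina > 0L] ==
                    sec$lumina[sec$lumina > 0L]))
})
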