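make_follicle_maps <- function(r_fol, r_lum, n = 101) {
  fol <- label_map(raster_disc(r_fol, n) * 1L, "follicle")
  lum <- label_map(raster_disc(r_lum, n) * 1L, "lumen")
  epi <- derive_epithelium(fol, lum)
  list(fol = fol, lum = lum, epi = epi)
}

empty_rel <- tibble::tibble(child = integer(0), parent = integer(0))

test_that("epithelial extension is the equivalent-disc radius difference", {
  maps <- make_follicle_maps(20, 10)
  rel <- tibble::tibble(child = 1:4, parent = c(1L, 1L, 1L, 1L))
  rec <- follicle_metrics(maps$fol, maps$lum, maps$epi, rel, empty_rel,
                          pixel_size = 1)
  # analytic: sqrt(400*pi/pi) - sqrt(100*pi/pi) = 10
  expect_equal(rec$eext, 10, tolerance = 0.02)
  expect_equal(rec$follicle_area, rec$lumen_area + rec$epithelium_area)
  expect_equal(rec$n_cells, 4L)
  expect_equal(rec$thyrocyte_area, rec$epithelium_area / 4)

  # follicle == lumen -> EExt 0
  rec0 <- follicle_metrics(maps$lum, maps$lum,
                           derive_epithelium(maps$lum, maps$lum),
                           rel, empty_rel, pixel_size = 1)
  expect_equal(rec0$eext, 0)
  expect_true(is.na(follicle_metrics(maps$fol, maps$lum, maps$epi, empty_rel,
                                     empty_rel, 1)$thyrocyte_area))
})

test_that("EExt scales linearly with pixel size and ignores position", {
  maps1 <- make_follicle_maps(20, 10)
  rec1 <- follicle_metrics(maps1$fol, maps1$lum, maps1$epi, empty_rel,
                           empty_rel, pixel_size = 1)
  rec2 <- follicle_metrics(maps1$fol, maps1$lum, maps1$epi, empty_rel,
                           empty_rel, pixel_size = 0.62)
  expect_equal(rec2$eext, rec1$eext * 0.62)

  # integer shift preserves the rasterization exactly
  shifted_fol <- label_map(raster_disc(20, 101, c(30.5, 60.5)) * 1L, "follicle")
  shifted_lum <- label_map(raster_disc(10, 101, c(30.5, 60.5)) * 1L, "lumen")
  rec3 <- follicle_metrics(shifted_fol, shifted_lum,
                           derive_epithelium(shifted_fol, shifted_lum),
                           empty_rel, empty_rel, pixel_size = 1)
  expect_equal(rec3$eext, rec1$eext, tolerance = 1e-6)
})

test_that("section summary computes densities and dead-cell percentages", {
  rec <- tibble::tibble(follicle_id = 1L, lumen_area = 1000,
                        follicle_area = 4000, epithelium_area = 3000,
                        eext = 5, n_cells = 12L, thyrocyte_area = 250,
                        n_dead_cells = 0L)
  s <- section_summary(rec, total_nuclei = 12)
  expect_equal(s$cells_per_1000um2, 3.0)

  rec$n_dead_cells <- 5L
  s2 <- section_summary(rec, total_nuclei = 200)
  expect_equal(s2$dead_cell_pct, 2.5)
  expect_error(section_summary(rec, total_nuclei = 4), "dead")

  s3 <- section_summary(rec[0, ], total_nuclei = 10)
  expect_equal(s3$n_follicles, 0L)
  expect_true(is.na(s3$mean_lumen_area))
})

test_that("cell density is invariant to pooling sub-images", {
  ph <- small_phantom()
  sec <- analyze_section(ph$channels, heatmap = FALSE)
  full <- section_summary(sec$records, n_labels(sec$nuclei))
  half1 <- sec$records[1:2, ]; half2 <- sec$records[-(1:2), ]
  pooled <- 1000 * (sum(half1$n_cells) + sum(half2$n_cells)) /
    (sum(half1$follicle_area) + sum(half2$follicle_area))
  expect_equal(full$cells_per_1000um2, pooled)
})

test_that("section summary matches phantom truth", {
  ph <- small_phantom()
  sec <- analyze_section(ph$channels, heatmap = FALSE)
  tr <- ph$truth
  s <- glance(sec)
  n_truth <- sum(tr$n_epithelial_nuclei + tr$n_intraluminal_nuclei)
  expect_equal(s$n_follicles, nrow(tr))
  expect_equal(s$mean_lumen_area, mean(tr$lumen_area), tolerance = 0.05)
  expect_equal(s$mean_follicle_area, mean(tr$follicle_area), tolerance = 0.05)
  expect_equal(s$mean_eext, mean(tr$true_eext), tolerance = 0.05)
  expect_equal(s$cells_per_1000um2,
               1000 * n_truth / sum(tr$follicle_area), tolerance = 0.05)
  expect_equal(s$dead_cell_pct,
               100 * sum(tr$n_intraluminal_nuclei) / n_truth,
               tolerance = 1e-8)
})

test_that("lumen heat map clips, orders and maps linearly", {
  lum <- matrix(0L, 40, 60)
  lum[raster_disc(5, 40, c(12, 12))] <- 1L
  lum[10:20, 40:55] <- 2L
  records <- tibble::tibble(follicle_id = 1:2,
                            lumen_area = c(1500, 4000))
  hm <- lumen_heatmap(label_map(lum, "lumen"), records, vmax_area = 3000)
  leg <- attr(hm, "legend")
  expect_equal(leg$value, c(0.5, 1))          # linear position, clipped at 1
  expect_lt(leg$value[1], leg$value[2])       # smaller area -> smaller value
  # background stays black
  expect_equal(unname(hm[1, 1, ]), c(0, 0, 0))
  # pure function: identical inputs give identical rasters
  hm2 <- lumen_heatmap(label_map(lum, "lumen"), records, vmax_area = 3000)
  expect_identical(hm, hm2)
  expect_error(lumen_heatmap(label_map(lum, "lumen"), records, -1), "> 0")
})

test_that("tidy and autoplot interfaces work on a section", {
  ph <- small_phantom()
  sec <- analyze_section(ph$channels)
  expect_identical(tidy(sec), sec$records)
  expect_identical(glance(sec), sec$summary)
  expect_s3_class(autoplot(sec), "ggplot")
  expect_s3_class(plot_lumen_heatmap(sec$heatmap), "ggplot")
})
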