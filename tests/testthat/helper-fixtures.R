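# fixtures are built in code; no binary data ships with the package

# rasterized filled disc on an n x n grid, center at (n/2, n/2)
raster_disc <- function(radius, n, center = c(n / 2, n / 2)) {
  x <- matrix(rep(seq_len(n), n), n)
  y <- t(x)
  (x - center[1])^2 + (y - center[2])^2 <= radius^2
}

# annular ring mask of given inner/outer radius
raster_ring <- function(r_in, r_out, n, center = c(n / 2, n / 2)) {
  raster_disc(r_out, n, center) & !raster_disc(r_in, n, center)
}

# independent 8-connectivity component counter (breadth-first search),
# used as an oracle against the package's own labelling
count_components8 <- function(mask) {
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  n <- 0L
  idx <- which(mask & !seen)
  while (length(idx)) {
    n <- n + 1L
    queue <- idx[1]
    seen[queue] <- TRUE
    nr <- nrow(mask)
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      i <- (cur - 1L) %% nr + 1L; j <- (cur - 1L) %/% nr + 1L
      for (di in -1:1) for (dj in -1:1) {
        ni <- i + di; nj <- j + dj
        if (ni >= 1 && ni <= nr && nj >= 1 && nj <= ncol(mask) &&
            mask[ni, nj] && !seen[ni, nj]) {
          seen[ni, nj] <- TRUE
          queue <- c(queue, ni + (nj - 1L) * nr)
        }
      }
    }
    idx <- which(mask & !seen)
  }
  n
}

# 4-connectivity component counter for background/complement topology
count_components4 <- function(mask) {
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  n <- 0L
  nr <- nrow(mask)
  idx <- which(mask & !seen)
  while (length(idx)) {
    n <- n + 1L
    queue <- idx[1]
    seen[queue] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      i <- (cur - 1L) %% nr + 1L; j <- (cur - 1L) %/% nr + 1L
      for (step in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ni <- i + step[1]; nj <- j + step[2]
        if (ni >= 1 && ni <= nr && nj >= 1 && nj <= ncol(mask) &&
            mask[ni, nj] && !seen[ni, nj]) {
          seen[ni, nj] <- TRUE
          queue <- c(queue, ni + (nj - 1L) * nr)
        }
      }
    }
    idx <- which(mask & !seen)
  }
  n
}

# endpoints of a skeleton: pixels with exactly one 8-neighbour
count_endpoints <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  nn <- matrix(0L, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nn <- nn + pad[2:(nr + 1) + di, 2:(nc + 1) + dj]
  }
  sum(mask & nn == 1L)
}

# small phantoms are reused across test files; cache by call signature
.phantom_cache <- new.env(parent = emptyenv())

cached_phantom <- function(...) {
  key <- paste(deparse(list(...)), collapse = "")
  if (is.null(.phantom_cache[[key]])) {
    .phantom_cache[[key]] <- generate_phantom(phantom_spec(...))
  }
  .phantom_cache[[key]]
}

small_phantom <- function() {
  cached_phantom(image_size = c(512, 512), n_follicles = 5, seed = 7,
                 noise_sd = 0)
}

# synthetic animal cohort for the statistics layer
make_cohort <- function(genotypes, n_per, means, sds = 0.1, cohort = "c1",
                        metric = "lumen_area", seed = 1) {
  set.seed(seed)
  rows <- purrr::map2(genotypes, seq_along(genotypes), function(g, i) {
    tibble::tibble(
      animal_id = paste0(g, "_", seq_len(n_per)),
      genotype = g, cohort = cohort, metric_name = metric,
      value = stats::rnorm(n_per, means[i],
                           if (length(sds) > 1) sds[i] else sds))
  })
  dplyr::bind_rows(rows)
}

# match truth rows to segmented follicle labels via the truth centers
match_truth_labels <- function(section, truth) {
  section$follicles[cbind(round(truth$center_row), round(truth$center_col))]
}
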