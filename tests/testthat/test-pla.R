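planted_block_stack <- function() {
  vox <- array(0, dim = c(10, 32, 32))
  vox[2:4, 3:5, 3:5] <- 100   # 27 voxels
  vox[6:8, 20:22, 20:22] <- 100
  spot_stack(vox)
}

test_that("count_spots finds planted blocks and applies the size filter", {
  st <- planted_block_stack()
  res <- count_spots(st, threshold = 50, min_size_vox = 2, connectivity = 26)
  expect_equal(res$count, 2L)
  expect_equal(res$volumes_vox, c(27L, 27L))
  expect_equal(res$centroids[order(res$centroids[, "z"]), "z"], c(3, 7),
               ignore_attr = TRUE)
  # a size filter above the block volume removes both
  expect_equal(count_spots(st, 50, min_size_vox = 28)$count, 0L)
  expect_error(count_spots(st, 50, min_size_vox = 0),
               class = "iccscoloc_validation_error")
  expect_error(count_spots(spot_stack(array(3, c(4, 8, 8))), "otsu"),
               class = "iccscoloc_degenerate_error")
})

test_that("an roi restricts counting to its pixels", {
  st <- planted_block_stack()
  roi <- matrix(FALSE, 32, 32); roi[1:10, 1:10] <- TRUE
  res <- count_spots(st, threshold = 50, roi = roi)
  expect_equal(res$count, 1L)
  expect_lt(res$centroids[1, "y"], 10)
})

test_that("count is monotone non-increasing in threshold and min_size", {
  sim <- simulate_pla_stack(n_spots = 12, seed = 5)
  thr <- c(30, 60, 90, 120, 150)
  counts_thr <- vapply(thr, function(t) count_spots(sim$stack, t)$count, integer(1))
  expect_true(all(diff(counts_thr) <= 0))
  sizes <- c(1, 4, 16, 64, 256)
  counts_sz <- vapply(sizes, function(s) count_spots(sim$stack, 60, s)$count,
                      integer(1))
  expect_true(all(diff(counts_sz) <= 0))
})

test_that("splitting a stack across a clean plane preserves the count", {
  st <- planted_block_stack() # objects live in z 2:4 and 6:8; cut at z = 5
  whole <- count_spots(st, 50, min_size_vox = 2)$count
  lower <- count_spots(spot_stack(st$voxels[1:5, , ]), 50, min_size_vox = 2)$count
  upper <- count_spots(spot_stack(st$voxels[6:10, , ]), 50, min_size_vox = 2)$count
  expect_equal(lower + upper, whole)
})

test_that("26-connectivity never yields more components than 6-connectivity", {
  set.seed(51)
  for (k in 1:5) {
    vox <- array(stats::runif(6 * 20 * 20) < 0.2, dim = c(6, 20, 20))
    st <- spot_stack(array(as.numeric(vox) * 100, dim = dim(vox)))
    c26 <- count_spots(st, 50, min_size_vox = 1, connectivity = 26)$count
    c6 <- count_spots(st, 50, min_size_vox = 1, connectivity = 6)$count
    expect_lte(c26, c6)
  }
})

test_that("planted well-separated puncta are recovered exactly", {
  sim <- simulate_pla_stack(n_spots = 15, seed = 8)
  res <- count_spots(sim$stack)
  expect_equal(res$count, 15L)
  # every centroid sits near a planted spot
  d <- as.matrix(stats::dist(rbind(sim$truth$planted_spot_coords, res$centroids)))
  nearest <- apply(d[1:15, 16:30, drop = FALSE], 1, min)
  expect_lt(max(nearest), 1.5)
  expect_true(all(res$volumes_vox >= 4))
})

test_that("summarize_counts produces a tidy per-cell table", {
  sim_counts <- lapply(c(5, 7, 9), function(n) {
    structure(list(count = as.integer(n), centroids = matrix(0, 0, 3),
                   volumes_vox = integer(0), threshold_used = 50),
              class = "spot_count")
  })
  tab <- summarize_counts(sim_counts, rep("g1", 3))
  expect_equal(tab$count, c(5L, 7L, 9L))
  expect_equal(tab$cell_id, 1:3)
  empty <- summarize_counts(list(), character(0))
  expect_equal(nrow(empty), 0)
  expect_error(summarize_counts(sim_counts, "g1"),
               class = "iccscoloc_validation_error")
})

test_that("cohort-sampled counts match generator means within 2 SEM", {
  groups <- cohort_preset_h3k9ac(n_cells = 60)
  coh <- simulate_cohort(groups, seed = 17)
  for (g in groups) {
    vals <- coh$pla_count[coh$group == g$name]
    sem <- g$pla_sd / sqrt(g$n_cells)
    expect_lt(abs(mean(vals) - g$pla_mean), 2 * sem + 0.5) # 0.5 for rounding
  }
})
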