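test_that("area filter keeps the closed interval [40, 200] um^2", {
  m <- make_rect_mask(c(30, 40, 120, 200, 250), pixel_size = 1)
  kept <- filter_nuclei_by_area(m)
  expect_identical(nrow(kept), 3L)
  expect_setequal(kept$area_um2, c(40, 120, 200))
  expect_error(filter_nuclei_by_area(m, min_area = 5, max_area = 5),
               "smaller")
  empty <- labeled_mask(matrix(0L, 10, 10), 1)
  expect_identical(nrow(filter_nuclei_by_area(empty)), 0L)
})

test_that("area filter equals brute-force pixel counting on random fields", {
  for (s in 1:3) {
    f <- generate_nuclei_field(30, seed = s, area_range = c(25, 260))
    kept <- filter_nuclei_by_area(f$mask)
    counts <- table(f$mask$labels[f$mask$labels > 0])
    ps2 <- f$mask$pixel_size^2
    bf <- as.integer(names(counts))[as.vector(counts) * ps2 >= 40 &
                                    as.vector(counts) * ps2 <= 200]
    expect_identical(kept$label, bf)
  }
})

test_that("two nuclei with a 5 um gap are isolated singletons", {
  m <- matrix(0L, 40, 60)
  m <- paint_ellipse(m, 1L, 20, 12, 6, 6, 0)
  m <- paint_ellipse(m, 2L, 20, 29, 6, 6, 0)   # centres 17 px apart
  mask <- labeled_mask(m, 1)                   # border gap = 5 px = 5 um
  asg <- cluster_nuclei(mask, max_gap = 3)
  expect_identical(length(unique(asg$cluster_id)), 2L)
  expect_true(all(asg$is_isolated))
})

test_that("single linkage chains A-B-C into one cluster", {
  # gaps: A-B 2 px, B-C 2 px, A-C spans > 3 px -> one transitive cluster
  m <- matrix(0L, 30, 80)
  m <- paint_ellipse(m, 1L, 15, 10, 5, 5, 0)
  m <- paint_ellipse(m, 2L, 15, 22, 5, 5, 0)
  m <- paint_ellipse(m, 3L, 15, 34, 5, 5, 0)
  mask <- labeled_mask(m, 1)
  asg <- cluster_nuclei(mask, max_gap = 3)
  expect_identical(length(unique(asg$cluster_id)), 1L)
  expect_identical(unique(asg$cluster_size), 3L)
  expect_false(any(asg$is_isolated))
  # and a single nucleus is one isolated cluster of size 1
  single <- labeled_mask(paint_ellipse(matrix(0L, 20, 20), 1L, 10, 10, 4, 4, 0), 1)
  asg1 <- cluster_nuclei(single)
  expect_identical(asg1$cluster_size, 1L)
  expect_true(asg1$is_isolated)
})

test_that("clustering rejects records whose label is absent", {
  f <- generate_nuclei_field(5, seed = 1)
  bad <- rbind(f$truth, f$truth[1, ])
  bad$label[nrow(bad)] <- 99L
  expect_error(cluster_nuclei(f$mask, bad), "absent")
})

test_that("the neighbour rule is strict: a gap equal to the threshold splits", {
  # two 1-px-wide bars exactly 3 um apart border-to-border
  m <- matrix(0L, 10, 12)
  m[3:7, 4] <- 1L; m[3:7, 7] <- 2L          # border gap = 3 px
  mask <- labeled_mask(m, 1)
  expect_identical(length(unique(cluster_nuclei(mask, max_gap = 3)$cluster_id)), 2L)
  expect_identical(length(unique(cluster_nuclei(mask, max_gap = 3.01)$cluster_id)), 1L)
})

test_that("cluster topology is invariant under joint rescaling", {
  f <- generate_nuclei_field(30, seed = 9)
  a1 <- cluster_nuclei(f$mask, max_gap = 3)
  doubled <- labeled_mask(f$mask$labels, f$mask$pixel_size * 2)
  a2 <- cluster_nuclei(doubled, max_gap = 6)
  expect_identical(a1$cluster_id, a2$cluster_id)
  # areas scale with the square of the pixel size
  expect_equal(label_areas(doubled), 4 * label_areas(f$mask))
})

test_that("fusion index counts centroids inside myotubes", {
  f <- generate_nuclei_field(10, seed = 4, cluster_size_prob = 1)
  rec <- nucleus_records(f$mask)
  none <- labeled_mask(matrix(0L, nrow(f$mask$labels), ncol(f$mask$labels)),
                       f$mask$pixel_size)
  expect_identical(fusion_index(f$mask, none, rec), 0)
  all_in <- labeled_mask(matrix(1L, nrow(f$mask$labels), ncol(f$mask$labels)),
                         f$mask$pixel_size)
  expect_identical(fusion_index(f$mask, all_in, rec), 1)
  # cover exactly the centroids of 6 of the 10 nuclei
  ps <- f$mask$pixel_size
  tube <- matrix(0L, nrow(f$mask$labels), ncol(f$mask$labels))
  for (i in 1:6) {
    r <- round(rec$centroid_y_um[i] / ps) + 1L
    c <- round(rec$centroid_x_um[i] / ps) + 1L
    tube[r, c] <- 1L
  }
  expect_equal(fusion_index(f$mask, labeled_mask(tube, ps), rec), 0.6)
  empty_rec <- rec[0, ]
  expect_error(fusion_index(f$mask, none, empty_rec),
               class = "myoquant_undefined")
  expect_error(fusion_index(f$mask, labeled_mask(matrix(0L, 2, 2), ps)),
               "shape")
})

test_that("marker fraction is positives over retained nuclei", {
  f <- generate_nuclei_field(20, seed = 8)
  rec <- nucleus_records(f$mask)
  expect_identical(marker_fraction(rec, rep(TRUE, 20)), 1)
  expect_identical(marker_fraction(rec, rep(FALSE, 20)), 0)
  expect_equal(marker_fraction(rec, rep(c(TRUE, FALSE), c(7, 13))), 0.35)
  expect_error(marker_fraction(rec[0, ]), class = "myoquant_undefined")
  expect_error(marker_fraction(rec, c(TRUE, FALSE)), "one non-missing flag")
})

test_that("field summary takes medians over the defined populations", {
  # synthetic assignment: cluster sizes {1, 1, 3, 5}
  asg <- data.frame(label = 1:10,
                    cluster_id = c(1L, 2L, 3L, 3L, 3L, 4L, 4L, 4L, 4L, 4L))
  asg$cluster_size <- c(1L, 1L, 3L, 3L, 3L, 5L, 5L, 5L, 5L, 5L)
  asg$is_isolated <- asg$cluster_size == 1L
  rec <- data.frame(label = 1:10, eccentricity = seq(0.05, 0.95, by = 0.1),
                    orientation_deg = rep(0, 10), degenerate = FALSE)
  s <- summarize_field(rec, asg)
  expect_identical(s$median_cluster_size, 2)          # median of {1,1,3,5}
  s2 <- summarize_field(rec, asg, include_singletons = FALSE)
  expect_identical(s2$median_cluster_size, 4)         # median of {3,5}
  # eccentricity median over isolated nuclei only (labels 1, 2)
  expect_equal(s$median_eccentricity, mean(c(0.05, 0.15)))
  # all isolated -> median cluster size 1
  asg1 <- data.frame(label = 1:3, cluster_id = 1:3,
                     cluster_size = 1L, is_isolated = TRUE)
  rec1 <- data.frame(label = 1:3, eccentricity = c(0.2, 0.8, 0.9),
                     orientation_deg = 0, degenerate = FALSE)
  s3 <- summarize_field(rec1, asg1)
  expect_identical(s3$median_cluster_size, 1L)
  expect_equal(s3$median_eccentricity, 0.8)
  # no isolated nuclei -> undefined median eccentricity, signalled
  asg2 <- data.frame(label = 1:2, cluster_id = 1L, cluster_size = 2L,
                     is_isolated = FALSE)
  expect_warning(s4 <- summarize_field(rec1[1:2, ], asg2),
                 class = "myoquant_undefined_warning")
  expect_true(is.na(s4$median_eccentricity))
})

test_that("aligned generator parameters are recovered by the summary", {
  pars <- nuclei_condition_params("nanopattern")
  f <- do.call(generate_nuclei_field,
               c(list(n_nuclei = 60, seed = 12), pars))
  rec <- nucleus_records(f$mask)
  asg <- cluster_nuclei(f$mask, rec)
  s <- summarize_field(rec, asg)
  h <- s$orientation_histogram
  # orientation mass concentrates in the central bins around 0 degrees
  central <- sum(h[c("[-20,-10)", "[-10,0)", "[0,10)", "[10,20)")])
  expect_gt(central / sum(h), 0.6)
  # singleton-only generator: every nucleus isolated
  f1 <- generate_nuclei_field(25, cluster_size_prob = 1, seed = 3)
  asg1 <- cluster_nuclei(f1$mask)
  expect_true(all(asg1$is_isolated))
})
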