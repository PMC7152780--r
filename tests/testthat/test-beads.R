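test_that("blank noisy images count zero beads", {
  im <- synth_bead_image(0, image_size = 128, rng_seed = 50)
  res <- count_beads(im$image)
  expect_equal(res$count, 0)
  expect_true(all(res$label_map == 0))
})

test_that("disjoint disks are counted exactly across bead numbers", {
  for (n in c(1, 5, 20, 50)) {
    im <- synth_bead_image(n, image_size = 300, bead_radius = 4,
                           min_separation = 16, rng_seed = 50 + n)
    res <- count_beads(im$image, min_distance = 4)
    expect_equal(res$count, n, info = paste("n_beads =", n))
  }
})

test_that("small separations produce touching pairs for watershed tests", {
  im <- synth_bead_image(12, image_size = 128, bead_radius = 6,
                         min_separation = 9, rng_seed = 61)
  d <- as.matrix(dist(im$centers))
  diag(d) <- Inf
  expect_true(any(d < 12))  # at least one overlapping pair
})

test_that("the watershed splits an overlapping pair into two beads", {
  img <- matrix(0, 96, 96)
  xs <- row(img); ys <- col(img)
  img[(xs - 40)^2 + (ys - 48)^2 <= 64] <- 1
  img[(xs - 53.6)^2 + (ys - 48)^2 <= 64] <- 1  # centres 1.7 radii apart
  set.seed(62)
  img <- img + matrix(rnorm(96 * 96, sd = 0.02), 96, 96)
  res <- count_beads(img, min_distance = 8)
  expect_equal(res$count, 2)
})

test_that("counts are invariant to rotation and intensity rescaling", {
  im <- synth_bead_image(15, image_size = 160, bead_radius = 5,
                         min_separation = 20, rng_seed = 63)
  r0 <- count_beads(im$image)
  rot <- count_beads(t(im$image)[ncol(im$image):1, ])  # 90 degree rotation
  expect_equal(rot$count, r0$count)
  scl <- count_beads(im$image * 7.3)
  expect_equal(scl$count, r0$count)
})

test_that("count equals the number of retained markers and labels", {
  im <- synth_bead_image(10, image_size = 128, bead_radius = 5,
                         min_separation = 20, rng_seed = 64)
  res <- count_beads(im$image)
  expect_equal(res$count, nrow(res$centers))
  expect_equal(res$count, length(setdiff(unique(as.vector(res$label_map)), 0L)))
})

test_that("fixed thresholds and input guards work", {
  im <- synth_bead_image(5, image_size = 96, bead_radius = 5,
                         min_separation = 20, rng_seed = 65)
  res <- count_beads(im$image, threshold = 0.5)
  expect_equal(res$count, 5)
  expect_equal(res$parameters_used$threshold_method, "fixed")
  expect_error(count_beads(array(0, c(4, 4, 2))), "2-D")
})

test_that("infeasible bead placements raise an error", {
  expect_error(synth_bead_image(50, image_size = 64, bead_radius = 6,
                                min_separation = 40, rng_seed = 66,
                                max_tries = 500),
               "Could not place")
})

test_that("per-condition summaries aggregate counts and fold changes", {
  counts <- tibble::tibble(
    condition = rep(c("DMSO", "CytoD"), each = 3),
    count = c(10, 10, 10, 31, 30, 29))
  out <- summarize_fields(counts, reference = "DMSO")
  expect_equal(out$mean[out$condition == "DMSO"], 10)
  expect_equal(out$sd[out$condition == "DMSO"], 0)
  expect_equal(out$fold_change[out$condition == "CytoD"], 3)
  expect_equal(out$n, c(3L, 3L))
  expect_error(summarize_fields(counts, reference = "LatB"), "Unknown")
  expect_error(summarize_fields(counts[0, ]), "No counts")
})

test_that("bead images survive a 16-bit TIFF round trip", {
  skip_if_not_installed("tiff")
  im <- synth_bead_image(6, image_size = 96, bead_radius = 5,
                         min_separation = 20, rng_seed = 67)
  path <- withr::local_tempfile(fileext = ".tif")
  write_image_tiff(im$image, path)
  back <- read_image_tiff(path)
  expect_equal(dim(back), dim(im$image))
  expect_lt(max(abs(back - pmin(pmax(im$image, 0), 1))), 1e-4)
  expect_equal(count_beads(back)$count, 6)
})
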