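# Central crop, colour channel moments, co-occurrence matrices and the
# 16-descriptor texture battery, each checked against brute-force oracles.

test_that("central crop picks the documented index ranges", {
  img <- array(0, dim = c(1200, 1920, 3))
  img[401:800, 761:1160, 1] <- 1  # rows 400..799, cols 760..1159 0-based
  block <- crop_center_block(img, 400)
  expect_equal(dim(block), c(400, 400, 3))
  expect_true(all(block[, , 1] == 1))

  id <- array(runif(400 * 400 * 3), dim = c(400, 400, 3))
  expect_identical(crop_center_block(id, 400), id, ignore_attr = TRUE)

  expect_error(crop_center_block(array(0, c(399, 400, 3)), 400), "crop")
})

test_that("odd crop residuals go to the bottom/right", {
  img <- array(seq_len(5 * 6 * 3) / 90, dim = c(5, 6, 3))
  block <- crop_center_block(img, 4)
  expect_equal(block[, , 2], img[1:4 + 0, 2:5, 2])  # rows 1..4, cols 2..5
})

test_that("colour statistics hit closed-form values on degenerate blocks", {
  gray <- array(0.5, dim = c(8, 8, 3))
  st <- color_statistics(gray)
  expect_equal(unname(st[grepl("_std", names(st))]), rep(0, 9))
  expect_equal(unname(st[grepl("_skew|_kurt", names(st))]), rep(0, 18))
  expect_equal(unname(st["S_ave"]), 0)
  expect_equal(unname(st["V_ave"]), 0.5)

  red <- array(0, dim = c(4, 4, 3)); red[, , 1] <- 1
  str_ <- color_statistics(red)
  expect_equal(unname(str_["H_ave"]), 0)
  expect_equal(unname(str_["S_ave"]), 1)
  expect_equal(unname(str_["V_ave"]), 1)

  two <- array(0.5, dim = c(10, 10, 3))
  two[, , 1] <- rep(c(0, 1), each = 50)  # half 0 / half 1
  st2 <- color_statistics(two)
  expect_equal(unname(st2["R_kurt"]), 1, tolerance = 1e-12)
  expect_equal(unname(st2["R_skew"]), 0, tolerance = 1e-12)
})

test_that("channel moments match a per-pixel accumulation oracle", {
  set.seed(11)
  block <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  st <- color_statistics(block)
  for (ch in c("R", "G", "B")) {
    x <- as.vector(block[, , match(ch, c("R", "G", "B"))])
    expect_equal(unname(st[paste0(ch, c("_ave", "_std", "_skew", "_kurt"))]),
                 oracle_moments(x), tolerance = 1e-10)
  }
})

test_that("a two-row two-level image gives the textbook co-occurrence matrix", {
  g <- matrix(c(0, 0, 1, 1), nrow = 2, byrow = TRUE)  # rows [0,0] and [1,1]
  m <- compute_glcm(g, levels = 2, directions = "0")
  expect_equal(unclass(m), matrix(c(0.5, 0, 0, 0.5), 2), ignore_attr = TRUE)
})

test_that("a constant block concentrates all co-occurrence mass in one cell", {
  block <- array(0.5, dim = c(12, 12, 3))
  m <- compute_glcm(block, levels = 8)
  expect_equal(sum(m), 1, tolerance = 1e-12)
  expect_equal(max(m), 1, tolerance = 1e-12)
  expect_equal(sum(m > 0), 1)
})

test_that("GLCM matches the brute-force pair counter on random blocks", {
  set.seed(19)
  for (i in 1:12) {
    block <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
    m <- compute_glcm(block, levels = 8)
    expect_equal(unclass(m), oracle_glcm(block, 8), ignore_attr = TRUE)
  }
  # raw counts for a single offset also agree
  q <- oracle_quantize(array(runif(10 * 10 * 3), c(10, 10, 3)), 4)
  one <- compute_glcm(matrix((q - 1) / 4 + 1e-6, 10, 10), levels = 4,
                      directions = "45", normalize = FALSE)
  brute <- oracle_glcm_counts(q, -1, 1, 4)
  expect_equal(unclass(one), brute + t(brute), ignore_attr = TRUE)
})

test_that("GLCM normalization and symmetry invariants hold", {
  set.seed(23)
  for (i in 1:10) {
    block <- array(runif(20 * 20 * 3), dim = c(20, 20, 3))
    m <- compute_glcm(block, levels = 8)
    expect_lt(abs(sum(m) - 1), 1e-12)
    expect_lt(max(abs(m - t(m))), 1e-12)
    expect_true(all(m >= 0))
  }
})

test_that("texture descriptors of degenerate and two-cell matrices are exact", {
  block <- array(0.25, dim = c(8, 8, 3))
  f <- haralick16(compute_glcm(block, levels = 8))
  expect_equal(unname(f["Entropy"]), 0)
  expect_equal(unname(f["Energy"]), 1)
  expect_equal(unname(f["Inertia"]), 0)
  expect_equal(unname(f["Homogeneity"]), 1)
  expect_equal(unname(f["Maximum_probability"]), 1)
  expect_equal(unname(f["Correlation"]), 0)  # zero-variance convention

  p <- matrix(c(0.5, 0, 0, 0.5), 2)
  f2 <- haralick16(p)
  expect_equal(unname(f2["Entropy"]), 1)
  expect_equal(unname(f2["Energy"]), 0.5)
  expect_equal(unname(f2["Inertia"]), 0)
  expect_equal(unname(f2["Correlation"]), 1)
  expect_equal(unname(f2["Sum_average"]), 3)
  expect_equal(unname(f2["Maximum_probability"]), 0.5)
})

test_that("all 16 descriptors match the naive-loop oracle on random matrices", {
  set.seed(31)
  for (i in 1:10) {
    a <- matrix(runif(64), 8)
    p <- a + t(a)
    p <- p / sum(p)
    expect_equal(haralick16(p), oracle_haralick(p), tolerance = 1e-10)
  }
})

test_that("texture bounds hold and the battery is 90-degree invariant", {
  set.seed(37)
  block <- array(runif(24 * 24 * 3), dim = c(24, 24, 3))
  f <- haralick16(compute_glcm(block, levels = 8))
  expect_lte(unname(f["Energy"]), unname(f["Maximum_probability"]))
  expect_lte(unname(f["Maximum_probability"]), 1)
  expect_lte(unname(f["Entropy"]), 2 * log2(8))

  rot <- block
  for (ch in 1:3) rot[, , ch] <- t(block[, , ch])[, 24:1]  # 90-degree turn
  f_rot <- haralick16(compute_glcm(rot, levels = 8))
  expect_equal(f_rot, f, tolerance = 1e-12)
})

test_that("the image table emits exactly 52 named features", {
  ds <- small_dataset()
  tab <- image_feature_table(ds$images, labels = ds$labels)
  expect_length(feature_names(tab), 52)
  expect_equal(sum(grepl("_ave$|_std$|_skew$|_kurt$", names(tab))), 36)

  empty <- image_feature_table(list())
  expect_equal(nrow(empty), 0)
  expect_length(feature_names(empty), 52)

  perm <- image_feature_table(rev(ds$images),
                              labels = ds$labels[rev(seq_len(9)), ])
  expect_identical(names(perm), names(tab))
  expect_equal(as.matrix(perm[feature_names(perm)]),
               as.matrix(tab[feature_names(tab)])[rev(seq_len(9)), ],
               ignore_attr = TRUE)
})
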