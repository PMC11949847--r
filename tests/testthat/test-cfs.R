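# Correlation-based feature selection: MDL discretization, symmetrical
# uncertainty, the merit function and best-first search, against direct
# enumeration oracles.

test_that("MDL discretization cuts perfectly ordered classes exactly once", {
  v <- c(1, 2, 3, 11, 12, 13)
  y <- c("A", "A", "A", "B", "B", "B")
  cuts <- mdl_discretize(v, y)
  expect_length(cuts, 1)
  expect_gt(cuts, 3)
  expect_lt(cuts, 11)
})

test_that("MDL discretization accepts no split under the class-independent null", {
  zero <- 0
  n_trials <- 50
  for (s in seq_len(n_trials)) {
    set.seed(s)
    v <- rnorm(20)
    y <- sample(rep(c("A", "B"), 10))
    if (length(mdl_discretize(v, y)) == 0) zero <- zero + 1
  }
  expect_gte(zero / n_trials, 0.95)

  expect_length(mdl_discretize(rep(2, 10), rep(c("A", "B"), 5)), 0)
})

test_that("symmetrical uncertainty hits its closed-form anchors", {
  x <- c(1, 1, 2, 2, 3, 3)
  expect_equal(symmetrical_uncertainty(x, x), 1)
  expect_equal(symmetrical_uncertainty(rep(1, 6), x), 0)
  expect_error(symmetrical_uncertainty(1:3, 1:4), "equal length")

  set.seed(1)
  for (i in 1:10) {
    a <- sample(1:3, 40, TRUE); b <- sample(1:2, 40, TRUE)
    expect_identical(symmetrical_uncertainty(a, b),
                     symmetrical_uncertainty(b, a))
    expect_true(symmetrical_uncertainty(a, b) >= 0 &&
                  symmetrical_uncertainty(a, b) <= 1)
  }
})

test_that("symmetrical uncertainty vanishes for independent variables", {
  ok <- 0
  for (s in 1:20) {
    set.seed(s)
    x <- rbinom(1000, 1, 0.5); y <- rbinom(1000, 1, 0.5)
    if (symmetrical_uncertainty(x, y) < 0.02) ok <- ok + 1
  }
  expect_gte(ok / 20, 0.95)
})

test_that("merit collapses to r_cf for singletons and to forced arithmetic", {
  cache <- list(r_cf = c(f1 = 0.37, f2 = 1, f3 = 1),
                r_ff = matrix(1, 3, 3, dimnames = list(c("f1", "f2", "f3"),
                                                       c("f1", "f2", "f3"))))
  expect_equal(cfs_merit("f1", cache), 0.37)
  expect_equal(cfs_merit(c("f2", "f3"), cache), 2 / sqrt(4))
  expect_error(cfs_merit(character(0), cache), "non-empty")
})

test_that("merit matches direct evaluation on all small subsets of a random cache", {
  set.seed(7)
  nf <- 10
  feats <- paste0("f", 1:nf)
  r_cf <- setNames(runif(nf), feats)
  a <- matrix(runif(nf * nf), nf)
  r_ff <- (a + t(a)) / 2
  diag(r_ff) <- 1
  dimnames(r_ff) <- list(feats, feats)
  cache <- list(r_cf = r_cf, r_ff = r_ff)

  for (k in 1:4) {
    combos <- utils::combn(feats, k)
    for (ci in seq_len(ncol(combos))) {
      sub <- combos[, ci]
      expect_equal(cfs_merit(sub, cache),
                   oracle_merit(r_cf[sub], r_ff[sub, sub, drop = FALSE]),
                   tolerance = 1e-12)
    }
  }
})

test_that("adding an uninformative but correlated feature lowers merit", {
  feats <- c("g1", "g2", "junk")
  r_cf <- c(g1 = 0.8, g2 = 0.7, junk = 0)
  r_ff <- matrix(0.3, 3, 3, dimnames = list(feats, feats))
  diag(r_ff) <- 1
  cache <- list(r_cf = r_cf, r_ff = r_ff)
  expect_lt(cfs_merit(feats, cache), cfs_merit(c("g1", "g2"), cache))
})

test_that("best-first search isolates the single informative feature", {
  set.seed(5)
  n <- 30
  grade <- rep(grade_levels(), each = 10)
  tab <- tibble::tibble(sample_id = sprintf("s%02d", 1:n), grade = grade,
                        signal = match(grade, grade_levels()) + rnorm(n, 0, 0.01))
  for (j in 1:9) tab[[paste0("noise", j)]] <- rnorm(n)
  res <- best_first_select(tab)
  expect_identical(res$selected, "signal")
  expect_equal(res$merit, 1, tolerance = 1e-9)
})

test_that("a duplicated informative feature is not selected twice", {
  set.seed(6)
  n <- 30
  grade <- rep(grade_levels(), each = 10)
  tab <- tibble::tibble(sample_id = sprintf("s%02d", 1:n), grade = grade,
                        f1 = match(grade, grade_levels()) + rnorm(n, 0, 0.01))
  tab$f2 <- rnorm(n)
  tab$f3 <- tab$f1
  res <- best_first_select(tab)
  expect_length(intersect(res$selected, c("f1", "f3")), 1)
  expect_length(res$selected, 1)
})

test_that("best-first recovers the exhaustive optimum on complementary signals", {
  # two features carrying orthogonal class information plus pure noise;
  # the oracle enumerates every subset on the same discretized columns
  for (s in c(2, 3, 4)) {
    set.seed(s)
    n <- 30
    grade <- rep(grade_levels(), each = 10)
    is1 <- as.numeric(grade == "Grade1") + rnorm(n, 0, 0.01)
    is2 <- as.numeric(grade == "Grade2") + rnorm(n, 0, 0.01)
    tab <- tibble::tibble(sample_id = sprintf("s%02d", 1:n), grade = grade,
                          bit1 = is1, bit2 = is2)
    for (j in 1:4) tab[[paste0("noise", j)]] <- rnorm(n)
    res <- best_first_select(tab)

    disc <- lapply(feature_names(tab), function(f) {
      cuts <- mdl_discretize(tab[[f]], tab$grade)
      findInterval(tab[[f]], cuts) + 1L
    })
    names(disc) <- feature_names(tab)
    opt <- oracle_exhaustive_cfs(disc, tab$grade)
    expect_equal(res$merit, opt$merit, tolerance = 1e-9)
    expect_identical(sort(res$selected), opt$subset)
    # and the returned merit dominates every singleton
    singles <- vapply(feature_names(tab),
                      function(f) oracle_su(disc[[f]], tab$grade), numeric(1))
    expect_gte(res$merit, max(singles) - 1e-9)
  }
})

test_that("selection is invariant to feature column order", {
  set.seed(9)
  n <- 30
  grade <- rep(grade_levels(), each = 10)
  tab <- tibble::tibble(sample_id = sprintf("s%02d", 1:n), grade = grade,
                        a = as.numeric(grade == "Grade1") + rnorm(n, 0, 0.05),
                        b = as.numeric(grade == "Grade2") + rnorm(n, 0, 0.05),
                        c = rnorm(n), d = rnorm(n))
  res1 <- best_first_select(tab)
  tab2 <- tab[, c("sample_id", "grade", "d", "b", "a", "c")]
  res2 <- best_first_select(tab2)
  expect_identical(sort(res1$selected), sort(res2$selected))
  expect_equal(res1$merit, res2$merit, tolerance = 1e-12)
})

test_that("tidy and glance expose the selection and its merit", {
  set.seed(10)
  grade <- rep(grade_levels(), each = 10)
  tab <- tibble::tibble(sample_id = sprintf("s%02d", 1:30), grade = grade,
                        sig = match(grade, grade_levels()) + rnorm(30, 0, 0.01),
                        nz = rnorm(30))
  res <- best_first_select(tab)
  td <- tidy(res)
  expect_identical(td$feature, res$selected)
  gl <- glance(res)
  expect_equal(gl$n_selected, length(res$selected))
  expect_equal(gl$merit, res$merit)
  reduced <- apply_selection(tab, res)
  expect_identical(feature_names(reduced), res$selected)
})
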