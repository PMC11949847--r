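# Shared fixtures, generated in code. The full default dataset (15 samples
# per grade) is expensive, so it is built lazily once per test run and
# cached for every file that needs it.

.fixture_env <- new.env(parent = emptyenv())

# default-condition dataset for a given seed, memoised
default_dataset <- function(seed = 101L) {
  key <- paste0("ds_", seed)
  if (is.null(.fixture_env[[key]])) {
    cfg <- synthetic_config(seed = seed)
    .fixture_env[[key]] <- simulate_dataset(cfg)
  }
  .fixture_env[[key]]
}

# a small, fast dataset: 3 samples per grade, 400 px images
small_dataset <- function(seed = 55L) {
  key <- paste0("small_", seed)
  if (is.null(.fixture_env[[key]])) {
    cfg <- synthetic_config(seed = seed, n_samples_per_grade = 3,
                            image_size = 400)
    .fixture_env[[key]] <- simulate_dataset(cfg)
  }
  .fixture_env[[key]]
}

# hand-built normalized response for forced-arithmetic feature checks
manual_response <- function(y, dt = 1, window = NULL) {
  times <- seq_along(y) * dt
  out <- tibble::tibble(time = times, S1 = y)
  structure(out, class = c("normalized_response", class(tibble::tibble())),
            window = window %||% range(times))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# well-separated three-class Gaussian blobs in two features
blob_table <- function(n_per_class = 20, sep = 8, sd = 1, seed = 1) {
  set.seed(seed)
  centers <- matrix(c(0, 0, sep, 0, 0, sep), ncol = 2, byrow = TRUE)
  rows <- do.call(rbind, lapply(1:3, function(c) {
    cbind(rnorm(n_per_class, centers[c, 1], sd),
          rnorm(n_per_class, centers[c, 2], sd))
  }))
  tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(3 * n_per_class)),
    grade = rep(grade_levels(), each = n_per_class),
    f1 = rows[, 1], f2 = rows[, 2])
}
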