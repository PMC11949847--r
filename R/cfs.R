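# Correlation-based feature selection: entropy/MDL discretization,
# symmetrical-uncertainty correlations, the subset merit function, and
# forward best-first search with a patience-based stopping rule.

#' Entropy-based (MDL) discretization cut points
#'
#' Recursive binary splitting of a continuous feature supervised by the
#' class labels: at each step the boundary maximizing class-information
#' gain is taken, and accepted only if the gain exceeds the minimum
#' description length criterion
#' `gain > (log2(N-1) + log2(3^k - 2) - k*H(S) + k1*H(S1) + k2*H(S2)) / N`,
#' where `k`, `k1`, `k2` are the class counts of the node and its two
#' children. Features for which no split is accepted become single-bin
#' (and carry no class information downstream).
#'
#' @param values Numeric vector.
#' @param labels Class labels, same length.
#' @return Numeric vector of strictly increasing cut points (possibly
#'   empty); a value `v` falls in bin `findInterval(v, cuts) + 1`.
#' @export
mdl_discretize <- function(values, labels) {
  if (length(values) != length(labels)) abort("Lengths must match.")
  if (length(values) < 2) abort("Need at least 2 samples.")
  labels <- as.integer(factor(labels))
  ord <- order(values)
  cuts <- mdl_split(values[ord], labels[ord])
  sort(cuts)
}

# class entropy (bits) of an integer label vector
class_entropy <- function(y) {
  p <- tabulate(y)
  p <- p[p > 0] / length(y)
  -sum(p * log2(p))
}

# recursive splitter on (sorted values, aligned labels)
mdl_split <- function(v, y) {
  n <- length(v)
  if (n < 2) return(numeric(0))
  # candidate boundaries: midpoints between adjacent distinct values
  distinct <- which(diff(v) > 0)
  if (!length(distinct)) return(numeric(0))

  ent_all <- class_entropy(y)
  best_gain <- -Inf
  best_i <- NA_integer_
  for (i in distinct) {
    e1 <- class_entropy(y[seq_len(i)])
    e2 <- class_entropy(y[(i + 1):n])
    gain <- ent_all - (i * e1 + (n - i) * e2) / n
    if (gain > best_gain + 1e-12) {
      best_gain <- gain
      best_i <- i
      best_e <- c(e1, e2)
    }
  }
  if (!is.finite(best_gain)) return(numeric(0))

  k <- length(unique(y))
  k1 <- length(unique(y[seq_len(best_i)]))
  k2 <- length(unique(y[(best_i + 1):n]))
  delta <- log2(3^k - 2) - (k * ent_all - k1 * best_e[1] - k2 * best_e[2])
  if (best_gain <= (log2(n - 1) + delta) / n) return(numeric(0))

  cut <- (v[best_i] + v[best_i + 1]) / 2
  c(mdl_split(v[seq_len(best_i)], y[seq_len(best_i)]),
    cut,
    mdl_split(v[(best_i + 1):n], y[(best_i + 1):n]))
}

#' Symmetrical uncertainty between two discrete vectors
#'
#' `SU(x, y) = 2 * (H(x) + H(y) - H(x, y)) / (H(x) + H(y))`, a normalized
#' mutual information in `[0, 1]` (logs base 2). By convention `SU = 0`
#' when both entropies vanish.
#'
#' @param x,y Vectors of equal length, treated as categorical.
#' @return A value in `[0, 1]`.
#' @export
symmetrical_uncertainty <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  x <- as.integer(factor(x))
  y <- as.integer(factor(y))
  hx <- class_entropy(x)
  hy <- class_entropy(y)
  if (hx + hy == 0) return(0)
  hxy <- class_entropy(as.integer(factor(paste(x, y))))
  su <- 2 * (hx + hy - hxy) / (hx + hy)
  min(max(su, 0), 1)
}

# Discretize every feature of a table and build the correlation cache:
# r_cf (feature-class SU) eagerly, r_ff (pairwise SU) lazily.
build_correlation_cache <- function(table) {
  feats <- feature_names(table)
  y <- table$grade
  disc <- lapply(feats, function(f) {
    cuts <- mdl_discretize(table[[f]], y)
    findInterval(table[[f]], cuts) + 1L
  })
  names(disc) <- feats
  r_cf <- vapply(disc, symmetrical_uncertainty, numeric(1), y = y)
  env <- new.env(parent = emptyenv())
  list(features = feats, disc = disc, r_cf = r_cf, pair_env = env)
}

# pairwise feature-feature SU with memoisation
cache_r_ff <- function(cache, f1, f2) {
  if (f1 == f2) return(1)
  key <- paste(sort(c(f1, f2)), collapse = "\r")
  v <- cache$pair_env[[key]]
  if (is.null(v)) {
    v <- symmetrical_uncertainty(cache$disc[[f1]], cache$disc[[f2]])
    cache$pair_env[[key]] <- v
  }
  v
}

#' CFS merit of a feature subset
#'
#' `M_s = k * mean(r_cf) / sqrt(k + k*(k-1) * mean(r_ff))`, where `k` is the
#' subset size, `mean(r_cf)` the average feature-class correlation and
#' `mean(r_ff)` the average pairwise feature-feature correlation (0 for a
#' singleton), all correlations being symmetrical-uncertainty values.
#' High merit rewards subsets that correlate with the class while being
#' mutually non-redundant.
#'
#' @param subset Character vector of feature names (non-empty).
#' @param cache Correlation cache built internally by [best_first_select()];
#'   alternatively a list with entries `r_cf` (named numeric) and `r_ff`
#'   (named square matrix) for direct evaluation.
#' @return The merit, a non-negative scalar.
#' @export
cfs_merit <- function(subset, cache) {
  k <- length(subset)
  if (k == 0) abort("`subset` must be non-empty.")
  if (!is.null(cache$r_ff) && is.matrix(cache$r_ff)) {
    rcf <- mean(cache$r_cf[subset])
    rff <- if (k == 1) 0 else {
      m <- cache$r_ff[subset, subset]
      sum(m[upper.tri(m)]) / (k * (k - 1) / 2)
    }
  } else {
    rcf <- mean(cache$r_cf[subset])
    rff <- if (k == 1) 0 else {
      s <- 0
      for (a in seq_len(k - 1)) for (b in (a + 1):k) {
        s <- s + cache_r_ff(cache, subset[a], subset[b])
      }
      s / (k * (k - 1) / 2)
    }
  }
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

#' Correlation-based feature selection with best-first search
#'
#' Forward best-first search over feature subsets scored by [cfs_merit()]:
#' starting from the empty set, the highest-merit unexpanded subset on the
#' open list is expanded by adding each unused feature; the search stops
#' after `patience` consecutive expansions that fail to improve the global
#' best merit (strict improvement, tolerance `tol`). Ties are broken toward
#' smaller subsets, then lexicographic feature order.
#'
#' @param table A feature table (tibble with `sample_id`, `grade`, features).
#' @param patience Number of consecutive non-improving expansions tolerated
#'   before stopping (default 5).
#' @param tol Strict-improvement tolerance (default 1e-10).
#' @param max_expansions Safety cap on expansions (default 10000).
#' @return A `cfs_result` list: `selected` (feature names, selection order),
#'   `merit`, `search_trace` (tibble of expanded subsets and merits),
#'   `stop_reason`, and `r_cf` (the per-feature class correlations).
#' @export
best_first_select <- function(table, patience = 5L, tol = 1e-10,
                              max_expansions = 10000L) {
  check_feature_table(table)
  feats <- feature_names(table)
  if (length(feats) < 2) abort("Need at least 2 features.")
  if (length(unique(table$grade)) < 2) abort("Need at least 2 classes.")

  cache <- build_correlation_cache(table)

  subset_key <- function(s) paste(sort(s), collapse = "\r")

  # open list entries: list(subset, merit); closed set by key
  open <- list(list(subset = character(0), merit = 0))
  open_keys <- subset_key(character(0))
  closed <- character(0)

  best_subset <- character(0)
  best_merit <- 0
  stall <- 0L
  n_exp <- 0L
  trace_subsets <- list()
  trace_merits <- numeric(0)
  stop_reason <- "open list exhausted"

  better <- function(subset, merit) {
    if (merit > best_merit + tol) return(TRUE)
    if (abs(merit - best_merit) <= tol) {
      if (length(subset) < length(best_subset)) return(TRUE)
      if (length(subset) == length(best_subset) &&
          paste(sort(subset), collapse = ",") <
          paste(sort(best_subset), collapse = ",")) return(TRUE)
    }
    FALSE
  }

  while (length(open) > 0) {
    if (n_exp >= max_expansions) { stop_reason <- "expansion cap"; break }
    # pop the best unexpanded subset (highest merit; ties -> smaller, lexico)
    merits <- vapply(open, `[[`, numeric(1), "merit")
    sizes <- vapply(open, function(e) length(e$subset), integer(1))
    keys <- vapply(open, function(e) paste(sort(e$subset), collapse = ","),
                   character(1))
    idx <- order(-merits, sizes, keys)[1]
    node <- open[[idx]]
    open <- open[-idx]
    closed <- c(closed, subset_key(node$subset))

    n_exp <- n_exp + 1L
    improved <- FALSE
    for (f in setdiff(feats, node$subset)) {
      child <- c(node$subset, f)
      key <- subset_key(child)
      if (key %in% closed || key %in% open_keys) next
      m <- cfs_merit(child, cache)
      open[[length(open) + 1]] <- list(subset = child, merit = m)
      open_keys <- c(open_keys, key)
      if (m > best_merit + tol) {
        best_merit <- m
        best_subset <- child
        improved <- TRUE
      } else if (better(child, m)) {
        best_subset <- child
      }
    }
    trace_subsets[[n_exp]] <- node$subset
    trace_merits[n_exp] <- node$merit

    if (improved) stall <- 0L else stall <- stall + 1L
    if (stall >= patience) { stop_reason <- "patience exhausted"; break }
  }

  selected <- best_subset
  structure(
    list(selected = selected,
         merit = if (length(selected)) cfs_merit(selected, cache) else 0,
         search_trace = tibble(
           subset = vapply(trace_subsets, paste, character(1), collapse = ","),
           size = lengths(trace_subsets),
           merit = trace_merits),
         stop_reason = stop_reason,
         r_cf = cache$r_cf,
         n_features_in = length(feats)),
    class = "cfs_result")
}

#' Reduce a feature table to the CFS-selected columns
#'
#' @param table A feature table.
#' @param result A `cfs_result` from [best_first_select()].
#' @return The table restricted to `sample_id`, `grade` and the selected
#'   features (original column order).
#' @export
apply_selection <- function(table, result) {
  stopifnot(inherits(result, "cfs_result"))
  keep <- intersect(feature_names(table), result$selected)
  dplyr::select(table, "sample_id", "grade", all_of(keep))
}

#' @export
print.cfs_result <- function(x, ...) {
  cat("<cfs_result> ", length(x$selected), " of ", x$n_features_in,
      " features, merit ", signif(x$merit, 4),
      " (", x$stop_reason, ")\n", sep = "")
  cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a CFS result
#'
#' One row per selected feature with its feature-class correlation.
#'
#' @param x A `cfs_result`.
#' @param ... Unused.
#' @return A tibble with columns `feature`, `r_cf`.
#' @method tidy cfs_result
#' @export
tidy.cfs_result <- function(x, ...) {
  tibble(feature = x$selected, r_cf = unname(x$r_cf[x$selected]))
}

#' One-row summary of a CFS result
#'
#' @param x A `cfs_result`.
#' @param ... Unused.
#' @return A tibble with `n_selected`, `n_features_in`, `merit`,
#'   `stop_reason`.
#' @method glance cfs_result
#' @export
glance.cfs_result <- function(x, ...) {
  tibble(n_selected = length(x$selected),
         n_features_in = x$n_features_in,
         merit = x$merit,
         stop_reason = x$stop_reason)
}
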