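# Classifier families: kernel SVM (one-vs-one, kernlab backend, with the
# Pearson VII universal and normalized polynomial kernels authored here),
# discrete Bayesian-network classifiers (naive structure optionally
# augmented by K2 search), and gain-ratio decision trees with
# reduced-error pruning.

#' Specify a classifier
#'
#' @param family `"svm"`, `"bayes_net"` or `"tree"`.
#' @param kernel SVM kernel: `"polynomial"`, `"normalized_polynomial"`,
#'   `"puk"` or `"rbf"`.
#' @param C SVM regularization constant (default 1).
#' @param degree Polynomial degree (default 2).
#' @param gamma RBF inverse width (default 1 / n_features at fit time when
#'   `NULL`).
#' @param omega,sigma Pearson VII kernel shape and width (defaults 1, 1).
#' @param bn_search `"naive"` or `"k2"` (class-parent graph, K2 adds up to
#'   `max_parents` extra feature parents per node, candidate parents taken
#'   in column order).
#' @param max_parents Extra feature parents per node for K2 (default 1).
#' @param alpha Laplace-style smoothing for the conditional probability
#'   tables (default 0.5).
#' @param min_leaf Minimum samples per tree leaf (default 2).
#' @param pruning `"reduced_error"` or `"none"`.
#' @param seed Seed for any internal randomness (pruning holdout).
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(family = c("svm", "bayes_net", "tree"),
                            kernel = c("puk", "polynomial",
                                       "normalized_polynomial", "rbf"),
                            C = 1, degree = 2, gamma = NULL,
                            omega = 1, sigma = 1,
                            bn_search = c("k2", "naive"), max_parents = 1L,
                            alpha = 0.5,
                            min_leaf = 2L,
                            pruning = c("reduced_error", "none"),
                            seed = 1L) {
  family <- match.arg(family)
  kernel <- match.arg(kernel)
  bn_search <- match.arg(bn_search)
  pruning <- match.arg(pruning)
  if (C <= 0 || omega <= 0 || sigma <= 0 || alpha <= 0 || min_leaf < 1) {
    abort("Classifier parameters must be positive.")
  }
  structure(list(family = family, kernel = kernel, C = C, degree = degree,
                 gamma = gamma, omega = omega, sigma = sigma,
                 bn_search = bn_search, max_parents = as.integer(max_parents),
                 alpha = alpha, min_leaf = as.integer(min_leaf),
                 pruning = pruning, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Pearson VII function-based universal kernel
#'
#' `K(x, y) = 1 / (1 + (2 * ||x - y|| * sqrt(2^(1/omega) - 1) / sigma)^2)^omega`.
#' With `omega = 1` it behaves like a Cauchy kernel; as `omega` grows it
#' approaches a Gaussian. `K(x, x) = 1` for any parameters.
#'
#' @param x,y Numeric vectors of equal length.
#' @param omega Shape (tail weight) parameter, > 0.
#' @param sigma Width parameter, > 0.
#' @return Similarity in `(0, 1]`.
#' @export
puk_kernel <- function(x, y, omega = 1, sigma = 1) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (omega <= 0 || sigma <= 0) abort("`omega` and `sigma` must be positive.")
  d <- sqrt(sum((x - y)^2))
  1 / (1 + (2 * d * sqrt(2^(1 / omega) - 1) / sigma)^2)^omega
}

# kernlab kernel objects ------------------------------------------------

puk_dot <- function(omega, sigma) {
  rval <- function(x, y = NULL) {
    if (is.null(y)) return(1)
    puk_kernel(x, y, omega, sigma)
  }
  class(rval) <- "kernel"
  rval
}

normalized_poly_dot <- function(degree) {
  base <- function(x, y) (crossprod(x, y)[1] + 1)^degree
  rval <- function(x, y = NULL) {
    if (is.null(y)) return(1)
    base(x, y) / sqrt(base(x, x) * base(y, y))
  }
  class(rval) <- "kernel"
  rval
}

#' Train a grading classifier
#'
#' Fits the family requested by the spec on a feature table. SVM features
#' are standardized (zero mean, unit variance, fitted on the training data);
#' Bayesian-network features are MDL-discretized; trees consume the raw
#' features.
#'
#' @param spec A [classifier_spec()].
#' @param table A feature table with at least 2 classes present.
#' @return A `grader_model`; use [predict_proba()] or `predict()` on new
#'   feature tables.
#' @export
train_grader <- function(spec, table) {
  stopifnot(inherits(spec, "classifier_spec"))
  check_feature_table(table)
  classes <- sort(unique(table$grade))
  if (length(classes) < 2) abort("Training data must contain at least 2 classes.")
  feats <- feature_names(table)
  x <- feature_matrix(table)
  y <- factor(table$grade, levels = classes)

  fit <- switch(spec$family,
    svm = fit_svm(spec, x, y),
    bayes_net = fit_bayes_net(spec, x, y),
    tree = fit_tree(spec, x, y))

  structure(list(spec = spec, fit = fit, classes = classes,
                 features = feats),
            class = "grader_model")
}

#' Class-probability predictions
#'
#' @param model A `grader_model`.
#' @param table A feature table holding the model's feature columns.
#' @return Tibble with one probability column per class (rows sum to 1) and
#'   a `.pred_class` column (argmax, first-class tie-break).
#' @export
predict_proba <- function(model, table) {
  stopifnot(inherits(model, "grader_model"))
  x <- as.matrix(table[model$features])
  p <- switch(model$spec$family,
    svm = predict_svm(model$fit, x, model$classes),
    bayes_net = predict_bayes_net(model$fit, x, model$classes),
    tree = predict_tree_nodes(model$fit, x, model$classes))
  p <- p / rowSums(p)
  colnames(p) <- model$classes
  out <- as_tibble(p)
  out$.pred_class <- model$classes[max.col(p, ties.method = "first")]
  out
}

#' @export
predict.grader_model <- function(object, newdata, ...) {
  predict_proba(object, newdata)$.pred_class
}

#' @export
print.grader_model <- function(x, ...) {
  cat("<grader_model>", x$spec$family,
      if (x$spec$family == "svm") paste0("(", x$spec$kernel, ")") else
        if (x$spec$family == "bayes_net") paste0("(", x$spec$bn_search, ")") else
          paste0("(", x$spec$pruning, ")"),
      "on", length(x$features), "features,",
      length(x$classes), "classes\n")
  invisible(x)
}

# SVM --------------------------------------------------------------------

fit_svm <- function(spec, x, y) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl < 1e-12] <- 1
  xs <- scale(x, center = ctr, scale = scl)

  gamma <- spec$gamma %||% (1 / ncol(x))
  kern <- switch(spec$kernel,
    polynomial = kernlab::polydot(degree = spec$degree, scale = 1, offset = 1),
    normalized_polynomial = normalized_poly_dot(spec$degree),
    puk = puk_dot(spec$omega, spec$sigma),
    rbf = kernlab::rbfdot(sigma = gamma))

  set.seed(spec$seed)
  ks <- suppressWarnings(
    kernlab::ksvm(xs, y, kernel = kern, C = spec$C, prob.model = TRUE,
                  scaled = FALSE)
  )
  list(ksvm = ks, center = ctr, scale = scl)
}

predict_svm <- function(fit, x, classes) {
  xs <- scale(x, center = fit$center, scale = fit$scale)
  p <- kernlab::predict(fit$ksvm, xs, type = "probabilities")
  p <- as.matrix(p)
  p[, classes, drop = FALSE]
}

# Bayesian network --------------------------------------------------------

# Discretize each column by MDL; structure: class -> every feature, K2
# optionally adds up to max_parents feature parents (candidates: earlier
# columns, Cooper-Herskovits score with the class always included).
fit_bayes_net <- function(spec, x, y) {
  nfeat <- ncol(x)
  cuts <- lapply(seq_len(nfeat), function(j) mdl_discretize(x[, j], y))
  disc <- vapply(seq_len(nfeat), function(j) {
    findInterval(x[, j], cuts[[j]]) + 1L
  }, integer(nrow(x)))
  disc <- matrix(disc, nrow = nrow(x))
  nbins <- vapply(cuts, function(cc) length(cc) + 1L, integer(1))
  yi <- as.integer(y)
  nclass <- nlevels(y)

  parents <- vector("list", nfeat)      # extra feature parents per node
  if (spec$bn_search == "k2" && spec$max_parents > 0) {
    for (j in seq_len(nfeat)) {
      current <- integer(0)
      score0 <- k2_node_score(disc[, j], nbins[j],
                              parent_config(yi, nclass, disc, nbins, current))
      while (length(current) < spec$max_parents) {
        cand <- setdiff(seq_len(j - 1L), current)
        cand <- cand[nbins[cand] > 1L]
        if (!length(cand)) break
        scores <- vapply(cand, function(pj) {
          k2_node_score(disc[, j], nbins[j],
                        parent_config(yi, nclass, disc, nbins, c(current, pj)))
        }, numeric(1))
        best <- which.max(scores)
        if (scores[best] > score0 + 1e-9) {
          current <- c(current, cand[best])
          score0 <- scores[best]
        } else break
      }
      parents[[j]] <- current
    }
  }

  # CPTs with alpha smoothing
  a <- spec$alpha
  prior <- (tabulate(yi, nclass) + a) / (length(yi) + a * nclass)
  cpts <- vector("list", nfeat)
  for (j in seq_len(nfeat)) {
    pc <- parent_config(yi, nclass, disc, nbins, parents[[j]])
    tab <- matrix(a, nrow = pc$n_config, ncol = nbins[j])
    for (i in seq_along(yi)) {
      tab[pc$config[i], disc[i, j]] <- tab[pc$config[i], disc[i, j]] + 1
    }
    cpts[[j]] <- tab / rowSums(tab)
  }

  list(cuts = cuts, nbins = nbins, parents = parents, prior = prior,
       cpts = cpts, nclass = nclass)
}

# joint parent configuration index: class always first parent
parent_config <- function(yi, nclass, disc, nbins, extra) {
  config <- yi
  mult <- nclass
  for (pj in extra) {
    config <- config + (disc[, pj] - 1L) * mult
    mult <- mult * nbins[pj]
  }
  list(config = config, n_config = mult)
}

# Cooper-Herskovits K2 log-score of one node given a parent configuration
k2_node_score <- function(xj, r, pc) {
  counts <- matrix(0L, nrow = pc$n_config, ncol = r)
  for (i in seq_along(xj)) {
    counts[pc$config[i], xj[i]] <- counts[pc$config[i], xj[i]] + 1L
  }
  nj <- rowSums(counts)
  sum(lgamma(r) - lgamma(nj + r)) + sum(lgamma(counts + 1))
}

predict_bayes_net <- function(fit, x, classes) {
  n <- nrow(x)
  nclass <- fit$nclass
  nfeat <- length(fit$cuts)
  disc <- vapply(seq_len(nfeat), function(j) {
    findInterval(x[, j], fit$cuts[[j]]) + 1L
  }, integer(n))
  disc <- matrix(disc, nrow = n)

  logp <- matrix(rep(log(fit$prior), each = n), nrow = n)
  for (j in seq_len(nfeat)) {
    if (fit$nbins[j] == 1L) next
    for (c in seq_len(nclass)) {
      config <- rep(c, n)
      mult <- nclass
      for (pj in fit$parents[[j]]) {
        config <- config + (disc[, pj] - 1L) * mult
        mult <- mult * fit$nbins[pj]
      }
      logp[, c] <- logp[, c] +
        log(fit$cpts[[j]][cbind(config, disc[, j])])
    }
  }
  logp <- logp - apply(logp, 1, max)
  p <- exp(logp)
  p / rowSums(p)
}

# Decision tree ------------------------------------------------------------

# Gain-ratio threshold tree; optional reduced-error pruning on a stratified
# 25% holdout drawn with the spec seed.
fit_tree <- function(spec, x, y) {
  n <- nrow(x)
  if (spec$pruning == "reduced_error" && n >= 8) {
    set.seed(spec$seed)
    hold <- unlist(lapply(levels(y), function(cl) {
      idx <- which(y == cl)
      k <- max(1L, floor(length(idx) * 0.25))
      sample(idx, k)
    }))
    grow <- setdiff(seq_len(n), hold)
    tree <- grow_tree(x[grow, , drop = FALSE], y[grow], spec$min_leaf)
    tree <- rep_prune(tree, x[hold, , drop = FALSE], y[hold])
  } else {
    tree <- grow_tree(x, y, spec$min_leaf)
  }
  list(tree = tree, nclass = nlevels(y))
}

leaf_node <- function(y) {
  counts <- tabulate(as.integer(y), nlevels(y))
  list(leaf = TRUE, counts = counts,
       prob = (counts + 1) / (sum(counts) + length(counts)))
}

grow_tree <- function(x, y, min_leaf) {
  n <- length(y)
  if (n < 2 * min_leaf || length(unique(as.integer(y))) == 1L) {
    return(leaf_node(y))
  }
  ent <- class_entropy(as.integer(y))
  best <- list(gr = 0)
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    ord <- order(v)
    vs <- v[ord]; ys <- as.integer(y)[ord]
    distinct <- which(diff(vs) > 1e-12)
    for (i in distinct) {
      if (i < min_leaf || n - i < min_leaf) next
      e1 <- class_entropy(ys[seq_len(i)])
      e2 <- class_entropy(ys[(i + 1):n])
      gain <- ent - (i * e1 + (n - i) * e2) / n
      if (gain <= 1e-9) next
      pfrac <- i / n
      split_info <- -(pfrac * log2(pfrac) + (1 - pfrac) * log2(1 - pfrac))
      gr <- gain / split_info
      if (gr > best$gr + 1e-12) {
        best <- list(gr = gr, j = j, cut = (vs[i] + vs[i + 1]) / 2)
      }
    }
  }
  if (best$gr == 0) return(leaf_node(y))
  left <- x[, best$j] <= best$cut
  list(leaf = FALSE, j = best$j, cut = best$cut,
       counts = tabulate(as.integer(y), nlevels(y)),
       left = grow_tree(x[left, , drop = FALSE], y[left], min_leaf),
       right = grow_tree(x[!left, , drop = FALSE], y[!left], min_leaf))
}

# bottom-up reduced-error pruning against a holdout set
rep_prune <- function(node, xh, yh) {
  if (node$leaf || nrow(xh) == 0) return(node)
  left <- xh[, node$j] <= node$cut
  node$left <- rep_prune(node$left, xh[left, , drop = FALSE], yh[left])
  node$right <- rep_prune(node$right, xh[!left, , drop = FALSE], yh[!left])

  pred_sub <- tree_predict_class(node, xh)
  err_sub <- sum(pred_sub != as.integer(yh))
  err_leaf <- sum(which.max(node$counts) != as.integer(yh))
  if (err_leaf <= err_sub) {
    counts <- node$counts
    return(list(leaf = TRUE, counts = counts,
                prob = (counts + 1) / (sum(counts) + length(counts))))
  }
  node
}

tree_predict_class <- function(node, x) {
  apply_tree <- function(nd, xi) {
    while (!nd$leaf) {
      nd <- if (xi[nd$j] <= nd$cut) nd$left else nd$right
    }
    which.max(nd$prob)
  }
  vapply(seq_len(nrow(x)), function(i) apply_tree(node, x[i, ]), numeric(1))
}

predict_tree_nodes <- function(fit, x, classes) {
  probs <- t(vapply(seq_len(nrow(x)), function(i) {
    nd <- fit$tree
    xi <- x[i, ]
    while (!nd$leaf) {
      nd <- if (xi[nd$j] <= nd$cut) nd$left else nd$right
    }
    nd$prob
  }, numeric(fit$nclass)))
  matrix(probs, ncol = fit$nclass)
}
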