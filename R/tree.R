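#' Train an interpretable CART decision tree
#'
#' Greedy binary CART with the Gini impurity criterion, built for white-box
#' severity scoring: every internal node stores a canonical feature name and
#' threshold, and the whole model serializes to human-readable JSON
#' ([write_tree()]). At each node the (feature, threshold) pair minimizing
#' the weighted Gini impurity of the two children is chosen; candidate
#' thresholds are midpoints between consecutive distinct feature values. Ties
#' are broken by lower feature index, then lower threshold, so training is
#' fully deterministic - the `seed` argument exists for interface
#' compatibility and is unused. Growth stops at `max_depth`, when a node is
#' pure, when a child would fall below `min_leaf` samples, or when no split
#' reduces impurity.
#'
#' @param x matrix or data frame of feature vectors (columns named as in
#'   [tap_feature_names()], or any fixed schema).
#' @param y integer severity labels 0-4 (any integer labels work).
#' @param max_depth maximum tree depth (default 5; a depth-0 tree is a single
#'   leaf).
#' @param min_leaf minimum samples per leaf (default 2).
#' @param seed ignored (training is deterministic); accepted for interface
#'   stability.
#' @return An object of class `tap_tree`.
#' @export
train_tree <- function(x, y, max_depth = 5L, min_leaf = 2L, seed = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (any(!is.finite(x))) stop("missing feature values are not allowed",
                               call. = FALSE)
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop("x and y differ in length", call. = FALSE)
  classes <- sort(unique(y))
  yk <- match(y, classes)
  root <- grow_node(x, yk, seq_len(nrow(x)), depth = 0L,
                    max_depth = as.integer(max_depth),
                    min_leaf = as.integer(min_leaf), n_class = length(classes))
  structure(list(root = root, features = colnames(x), classes = classes,
                 config = list(max_depth = as.integer(max_depth),
                               min_leaf = as.integer(min_leaf),
                               criterion = "gini")),
            class = "tap_tree")
}

gini_impurity <- function(counts, n) 1 - sum((counts / n)^2)

make_leaf <- function(yk, idx, n_class) {
  counts <- tabulate(yk[idx], nbins = n_class)
  list(type = "leaf", class_index = which.max(counts), counts = counts)
}

grow_node <- function(x, yk, idx, depth, max_depth, min_leaf, n_class) {
  counts <- tabulate(yk[idx], nbins = n_class)
  n <- length(idx)
  if (depth >= max_depth || n < 2L * min_leaf || sum(counts > 0L) == 1L) {
    return(make_leaf(yk, idx, n_class))
  }
  parent_gini <- gini_impurity(counts, n)
  best <- NULL
  for (j in seq_len(ncol(x))) {
    xs <- x[idx, j]
    o <- order(xs)
    xo <- xs[o]
    yo <- yk[idx][o]
    cum <- vapply(seq_len(n_class), function(k) cumsum(yo == k),
                  numeric(length(yo)))
    cum <- matrix(cum, ncol = n_class)
    cut_ok <- which(diff(xo) > 0)
    cut_ok <- cut_ok[cut_ok >= min_leaf & (n - cut_ok) >= min_leaf]
    if (!length(cut_ok)) next
    for (i in cut_ok) {
      cl <- cum[i, ]
      cr <- counts - cl
      g <- (i * gini_impurity(cl, i) + (n - i) * gini_impurity(cr, n - i)) / n
      if (is.null(best) || g < best$gini - 1e-12) {
        best <- list(feature = j, threshold = (xo[i] + xo[i + 1L]) / 2,
                     gini = g, left_idx = idx[o[seq_len(i)]],
                     right_idx = idx[o[(i + 1L):n]])
      }
    }
  }
  # impure nodes split on the best candidate even at zero immediate Gini
  # gain (an XOR-style interaction only pays off one level deeper)
  if (is.null(best) || best$gini > parent_gini + 1e-12) {
    return(make_leaf(yk, idx, n_class))
  }
  list(type = "split", feature = best$feature, threshold = best$threshold,
       left = grow_node(x, yk, best$left_idx, depth + 1L, max_depth,
                        min_leaf, n_class),
       right = grow_node(x, yk, best$right_idx, depth + 1L, max_depth,
                         min_leaf, n_class))
}

#' Predict severity scores with a trained tree
#'
#' Root-to-leaf traversal: at each internal node the sample goes left when
#' its feature value is `<=` the node threshold.
#'
#' @param object a `tap_tree` from [train_tree()].
#' @param newdata named numeric vector (one recording) or matrix/data frame
#'   of feature vectors; must contain every feature the tree was trained on.
#' @param ... unused.
#' @return Integer vector of predicted scores.
#' @export
predict.tap_tree <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1,
                                               dimnames = list(NULL, names(newdata)))
  miss <- setdiff(object$features, colnames(newdata))
  if (length(miss)) {
    stop("unknown feature schema; missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.data.frame(newdata)) newdata <- newdata[, object$features, drop = FALSE]
  X <- as.matrix(newdata)[, object$features, drop = FALSE]
  storage.mode(X) <- "double"
  out <- integer(nrow(X))
  for (i in seq_len(nrow(X))) {
    node <- object$root
    while (node$type == "split") {
      node <- if (X[i, node$feature] <= node$threshold) node$left else
        node$right
    }
    out[i] <- object$classes[node$class_index]
  }
  out
}

#' @export
print.tap_tree <- function(x, ...) {
  cat(sprintf("<tap_tree> max depth %d, classes {%s}\n",
              x$config$max_depth, paste(x$classes, collapse = ", ")))
  print_node <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      cat(sprintf("%spredict %s  [%s]\n", pad, x$classes[node$class_index],
                  paste(node$counts, collapse = "/")))
    } else {
      cat(sprintf("%sif %s <= %.4g:\n", pad, x$features[node$feature],
                  node$threshold))
      print_node(node$left, indent + 1L)
      cat(sprintf("%selse:\n", pad))
      print_node(node$right, indent + 1L)
    }
  }
  print_node(x$root, 1L)
  invisible(x)
}

#' Serialize a tree to human-readable JSON
#'
#' The model is stored as a nested structure of feature names, thresholds,
#' and leaf class counts so the clinical logic can be read (and audited)
#' directly from the file. [read_tree()] restores a model that predicts
#' identically.
#'
#' @param model a `tap_tree`.
#' @param path destination (for `read_tree`, source) file.
#' @return `path` (invisibly); `read_tree()` returns the `tap_tree`.
#' @export
write_tree <- function(model, path) {
  stopifnot(inherits(model, "tap_tree"))
  as_json_node <- function(node) {
    if (node$type == "leaf") {
      list(type = "leaf",
           predict = model$classes[node$class_index],
           counts = as.list(stats::setNames(node$counts,
                                            as.character(model$classes))))
    } else {
      list(type = "split", feature = model$features[node$feature],
           threshold = node$threshold,
           left = as_json_node(node$left), right = as_json_node(node$right))
    }
  }
  jsonlite::write_json(
    list(model = "tap_tree", features = model$features,
         classes = model$classes, config = model$config,
         tree = as_json_node(model$root)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$model, "tap_tree")) stop("not a tap_tree file",
                                              call. = FALSE)
  features <- unlist(obj$features)
  classes <- as.integer(unlist(obj$classes))
  from_json_node <- function(node) {
    if (node$type == "leaf") {
      list(type = "leaf",
           class_index = match(as.integer(node$predict), classes),
           counts = as.integer(unlist(node$counts)))
    } else {
      list(type = "split", feature = match(node$feature, features),
           threshold = as.numeric(node$threshold),
           left = from_json_node(node$left),
           right = from_json_node(node$right))
    }
  }
  structure(list(root = from_json_node(obj$tree), features = features,
                 classes = classes,
                 config = list(max_depth = as.integer(obj$config$max_depth),
                               min_leaf = as.integer(obj$config$min_leaf),
                               criterion = obj$config$criterion)),
            class = "tap_tree")
}

#' Stratified train/test split
#'
#' Randomly assigns a fraction of recordings to a held-out test set while
#' preserving class proportions (at least one test sample per class whenever
#' a class has two or more members).
#'
#' @param labels vector of class labels.
#' @param test_frac fraction held out (default 0.2).
#' @param seed RNG seed for reproducibility.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, test_frac = 0.2, seed = NULL) {
  stopifnot(test_frac > 0, test_frac < 1)
  with_seed(seed, {
    test <- integer(0)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      n_test <- if (length(idx) >= 2L) max(1L, round(test_frac * length(idx)))
      else 0L
      if (n_test > 0L) test <- c(test, sample(idx, n_test))
    }
    test <- sort(test)
    list(train = setdiff(seq_along(labels), test), test = test)
  })
}
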