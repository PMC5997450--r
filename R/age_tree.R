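# Hair-cell age classification: four morphometric features and a CART
# decision tree (Gini impurity, axis-aligned splits) implemented directly
# so the model is fully specifiable and serializable.

#' Morphometric features for age classification
#'
#' Four features per hair cell: total traced membrane area (perimeter x
#' section thickness summed over sections), cell volume (polygon area x
#' section thickness summed), total ribbon volume, and apical contact
#' area.
#'
#' @param cell_id Hair-cell identifier.
#' @param conn A [neuromast_connectome()] with traces for the cell; ribbon
#'   volumes are read from a `ribbon_volume` column of `conn$ribbons` when
#'   present (0 otherwise).
#' @param config A [geometry_config()] with `apical_sections` set.
#' @return Named numeric vector: `cell_area`, `cell_volume`,
#'   `ribbon_volume_total`, `apical_contact_area`.
#' @export
extract_features <- function(cell_id, conn, config = geometry_config()) {
  polys <- cell_traces(conn, cell_id)
  if (!length(polys)) stop(sprintf("cell '%s' has no traces", cell_id))
  th <- config$section_thickness
  cell_area <- sum(vapply(polys, polygon_perimeter, numeric(1L))) * th
  cell_volume <- sum(vapply(polys, polygon_area, numeric(1L))) * th
  rib <- conn$ribbons[conn$ribbons$haircell_id == cell_id, , drop = FALSE]
  ribbon_volume_total <- if ("ribbon_volume" %in% names(rib) && nrow(rib)) {
    sum(rib$ribbon_volume, na.rm = TRUE)
  } else 0
  apical <- if (is.null(config$apical_sections)) 0 else
    apical_contact_area(cell_id, conn, config)
  c(cell_area = cell_area, cell_volume = cell_volume,
    ribbon_volume_total = ribbon_volume_total, apical_contact_area = apical)
}

# Gini impurity of a label vector (factor codes).
gini <- function(y) {
  p <- tabulate(y) / length(y)
  1 - sum(p^2)
}

# Best axis-aligned split of (x, y): returns NULL or
# list(feature, threshold, impurity).  Ties break toward the lowest
# feature index, then the smallest threshold, so fits are deterministic.
best_split <- function(x, y, min_leaf) {
  n <- nrow(x)
  n_classes <- max(y)
  best <- NULL
  for (j in seq_len(ncol(x))) {
    ord <- order(x[, j])
    vs <- x[ord, j]
    ys <- y[ord]
    # cumulative class counts left of each candidate cut i | i+1
    cum <- vapply(seq_len(n_classes), function(k) cumsum(ys == k),
                  numeric(n))
    i <- seq_len(n - 1L)
    valid <- vs[i] < vs[i + 1L] & i >= min_leaf & (n - i) >= min_leaf
    if (!any(valid)) next
    nl <- i
    left_cnt <- cum[i, , drop = FALSE]
    tot <- cum[n, ]
    right_cnt <- matrix(tot, length(i), n_classes, byrow = TRUE) - left_cnt
    gl <- 1 - rowSums((left_cnt / nl)^2)
    gr <- 1 - rowSums((right_cnt / (n - nl))^2)
    imp <- (nl * gl + (n - nl) * gr) / n
    imp[!valid] <- Inf
    k <- which.min(imp)
    if (is.finite(imp[k]) &&
        (is.null(best) || imp[k] < best$impurity - 1e-12)) {
      best <- list(feature = j, threshold = (vs[k] + vs[k + 1L]) / 2,
                   impurity = imp[k])
    }
  }
  best
}

grow_tree <- function(x, y, depth, max_depth, min_leaf, n_classes) {
  counts <- tabulate(y, nbins = n_classes)
  leaf <- list(leaf = TRUE, class = which.max(counts), counts = counts)
  if (depth >= max_depth || length(unique(y)) == 1L ||
      nrow(x) < 2L * min_leaf) {
    return(leaf)
  }
  sp <- best_split(x, y, min_leaf)
  if (is.null(sp) || sp$impurity >= gini(y) - 1e-12) return(leaf)
  left <- x[, sp$feature] < sp$threshold
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       counts = counts,
       left = grow_tree(x[left, , drop = FALSE], y[left], depth + 1L,
                        max_depth, min_leaf, n_classes),
       right = grow_tree(x[!left, , drop = FALSE], y[!left], depth + 1L,
                         max_depth, min_leaf, n_classes))
}

#' Fit a CART age classifier
#'
#' Splits the labelled cells into a training set (default 70%) and a test
#' set, then grows a binary classification tree by recursive axis-aligned
#' splitting minimizing Gini impurity.  The only randomness is the
#' train/test split, so the fit is deterministic given the seed.
#'
#' @param x Numeric feature matrix or data frame (cells x features).
#' @param y Age-class labels (factor or character).
#' @param split_fraction Fraction of cells assigned to the training set.
#' @param seed Integer seed for the random split.
#' @param max_depth Maximum tree depth (root = depth 0).  Default 3.
#' @param min_leaf Minimum cells per leaf.  Default 3.
#' @return An object of class `age_tree` with the fitted tree, class
#'   levels, feature names, split indices, and held-out test accuracy.
#' @examples
#' cohort <- generate_age_cohort(60, seed = 1)
#' fit <- age_tree(cohort$features, cohort$labels, seed = 1)
#' print(fit)
#' @export
age_tree <- function(x, y, split_fraction = 0.7, seed = 1L,
                     max_depth = 3L, min_leaf = 3L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- factor(y)
  y <- droplevels(y)
  stopifnot(nrow(x) == length(y), split_fraction > 0, split_fraction <= 1)
  n <- nrow(x)
  idx <- with_seed(seed, sample.int(n, size = round(split_fraction * n)))
  train_y <- y[idx]
  missing_cls <- setdiff(levels(y), levels(droplevels(train_y)))
  if (length(missing_cls)) {
    stop(sprintf("class(es) absent from the training split: %s",
                 paste(missing_cls, collapse = ", ")))
  }
  tab <- table(train_y)
  if (any(tab < 3L)) {
    nm_log("warn", sprintf("fewer than 3 training cells in class(es): %s",
                           paste(names(tab)[tab < 3L], collapse = ", ")))
  }
  tree <- grow_tree(x[idx, , drop = FALSE], as.integer(train_y), 0L,
                    max_depth, min_leaf, nlevels(y))
  fit <- structure(list(tree = tree, levels = levels(y),
                        features = colnames(x),
                        train_idx = sort(idx),
                        hyperparameters = list(split_fraction = split_fraction,
                                               seed = seed,
                                               max_depth = max_depth,
                                               min_leaf = min_leaf)),
                   class = "age_tree")
  test_idx <- setdiff(seq_len(n), idx)
  fit$test_accuracy <- if (length(test_idx)) {
    mean(predict(fit, x[test_idx, , drop = FALSE]) == y[test_idx])
  } else NA_real_
  fit
}

#' Predict age classes from a fitted tree
#'
#' Deterministic leaf lookup; cells classified this way carry
#' `age_source = "classified"` downstream.
#'
#' @param object An [age_tree()] fit.
#' @param newdata Feature matrix or data frame with the training columns.
#' @param ... Unused.
#' @return Factor of predicted age classes.
#' @export
predict.age_tree <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(x))) {
    x <- x[, object$features, drop = FALSE]
  }
  cls <- integer(nrow(x))
  for (i in seq_len(nrow(x))) {
    node <- object$tree
    while (!node$leaf) {
      node <- if (x[i, node$feature] < node$threshold) node$left else node$right
    }
    cls[i] <- node$class
  }
  factor(object$levels[cls], levels = object$levels)
}

#' @export
print.age_tree <- function(x, ...) {
  cat("CART age classifier (Gini impurity, axis-aligned splits)\n")
  cat(sprintf("  classes : %s\n", paste(x$levels, collapse = ", ")))
  cat(sprintf("  training cells: %d; held-out accuracy: %s\n",
              length(x$train_idx),
              if (is.na(x$test_accuracy)) "n/a" else
                sprintf("%.3f", x$test_accuracy)))
  print_node <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$leaf) {
      cat(sprintf("%s-> %s (%s)\n", pad, x$levels[node$class],
                  paste(node$counts, collapse = "/")))
    } else {
      feat <- if (!is.null(x$features)) x$features[node$feature] else
        paste0("x", node$feature)
      cat(sprintf("%sif %s < %.4g:\n", pad, feat, node$threshold))
      print_node(node$left, indent + 1L)
      cat(sprintf("%selse:\n", pad))
      print_node(node$right, indent + 1L)
    }
  }
  print_node(x$tree, 1L)
  invisible(x)
}

#' @export
summary.age_tree <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Serialize an age tree to JSON
#'
#' Nodes record feature index, threshold, children, and leaf class, so a
#' fitted model can be stored alongside the data it classified.
#'
#' @param fit An [age_tree()] fit.
#' @param path Optional path; when given, the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
age_tree_to_json <- function(fit, path = NULL) {
  strip <- function(node) {
    if (node$leaf) {
      list(leaf = TRUE, class = node$class, counts = node$counts)
    } else {
      list(leaf = FALSE, feature = node$feature, threshold = node$threshold,
           counts = node$counts, left = strip(node$left),
           right = strip(node$right))
    }
  }
  obj <- list(tree = strip(fit$tree), levels = fit$levels,
              features = fit$features,
              hyperparameters = fit$hyperparameters)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Deserialize an age tree from JSON
#'
#' @param json JSON string or path to a file written by
#'   [age_tree_to_json()].
#' @return An `age_tree` object giving identical predictions to the
#'   serialized fit.
#' @export
age_tree_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  fix <- function(node) {
    node$leaf <- isTRUE(node$leaf)
    if (!node$leaf) {
      node$left <- fix(node$left)
      node$right <- fix(node$right)
    }
    node
  }
  structure(list(tree = fix(obj$tree), levels = unlist(obj$levels),
                 features = unlist(obj$features), train_idx = NULL,
                 hyperparameters = obj$hyperparameters,
                 test_accuracy = NA_real_),
            class = "age_tree")
}

#' Classify unaged hair cells of a connectome
#'
#' Fits (or reuses) an age tree on the cells with known age and assigns
#' predicted classes, with `age_source = "classified"`, to the rest.
#'
#' @param conn A [neuromast_connectome()] with traces.
#' @param config A [geometry_config()] with `apical_sections` set.
#' @param fit Optional pre-trained [age_tree()].
#' @param ... Passed to [age_tree()] when fitting.
#' @return The connectome with `age_class` filled for previously unknown
#'   cells.
#' @export
classify_cell_ages <- function(conn, config = geometry_config(), fit = NULL,
                               ...) {
  hc <- conn$haircells
  unknown <- hc$cell_id[hc$age_class == "unknown"]
  if (!length(unknown)) return(conn)
  feats <- t(vapply(hc$cell_id, extract_features, numeric(4L), conn, config))
  if (is.null(fit)) {
    known <- hc$age_class != "unknown"
    if (sum(known) < 9L) stop("too few cells with known age to train a classifier")
    fit <- age_tree(feats[known, , drop = FALSE], hc$age_class[known], ...)
  }
  pred <- predict(fit, feats[hc$age_class == "unknown", , drop = FALSE])
  conn$haircells$age_class[hc$age_class == "unknown"] <- as.character(pred)
  conn$haircells$age_source[hc$cell_id %in% unknown] <- "classified"
  conn
}
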