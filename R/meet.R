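# MEET: mixture of class-partitioned extra-trees experts fused with a
# full-class gating ensemble through an elementwise (Hadamard) product.

#' Number of classifiers required by the mixture sizing rule
#'
#' A MEET model for `N` classes with `a` classes per expert consists of
#' `ceiling(N/a)` experts plus one gate, i.e. `ceiling(N/a) + 1` classifiers
#' in total. The additional classifier is the gate, which assigns weighted
#' probabilities over all classes.
#'
#' @param n_classes Number of classes `N` (>= 2).
#' @param a Classes assigned to each expert (>= 1).
#' @return Integer: total classifier count (experts + gate).
#' @examples
#' required_experts(6, 2)  # 3 experts + 1 gate = 4
#' @export
required_experts <- function(n_classes, a = 2L) {
  if (!is.numeric(n_classes) || length(n_classes) != 1L || n_classes < 2)
    stop("`n_classes` must be a single number >= 2", call. = FALSE)
  if (!is.numeric(a) || length(a) != 1L || a < 1)
    stop("`a` must be a single number >= 1", call. = FALSE)
  as.integer(ceiling(n_classes / a)) + 1L
}

#' Partition class codes across experts
#'
#' Splits the ascending class order into consecutive chunks of size `a` (the
#' last chunk may be smaller), one chunk per expert: with six classes and
#' `a = 2`, expert 1 owns classes {1,2}, expert 2 owns {3,4} and expert 3
#' owns {5,6}.
#'
#' @param class_order Vector of distinct class codes.
#' @param a Classes per expert.
#' @return A list of integer vectors (one per expert), with attribute
#'   `class_order` holding the ascending class order.
#' @export
partition_classes <- function(class_order, a = 2L) {
  class_order <- as.integer(class_order)
  if (length(class_order) == 0L) stop("`class_order` is empty", call. = FALSE)
  if (anyDuplicated(class_order))
    stop("duplicate class codes in `class_order`", call. = FALSE)
  a <- as.integer(a)
  if (a < 1L) stop("`a` must be >= 1", call. = FALSE)
  ord <- sort(class_order)
  subsets <- split(ord, ceiling(seq_along(ord) / a))
  names(subsets) <- NULL
  attr(subsets, "class_order") <- ord
  subsets
}

#' Hyperparameters of the tree ensembles
#'
#' Settings shared by the expert and gate extremely randomized trees
#' (extra-trees): 100 trees, Gini impurity with one random split point per
#' candidate feature, square-root feature subsampling, minimum node size 1,
#' and no bootstrap resampling (each tree sees the full training set).
#'
#' @param num_trees Number of trees per ensemble.
#' @param mtry Features tried per split; `NULL` means `floor(sqrt(p))`.
#' @param min_node_size Minimum terminal node size.
#' @param num_random_splits Random split points drawn per candidate feature.
#' @param replace,sample_fraction Resampling scheme per tree.
#' @return A list of class `meet_control`.
#' @export
meet_control <- function(num_trees = 100L, mtry = NULL, min_node_size = 1L,
                         num_random_splits = 1L, replace = FALSE,
                         sample_fraction = 1) {
  structure(list(num_trees = as.integer(num_trees), mtry = mtry,
                 min_node_size = as.integer(min_node_size),
                 num_random_splits = as.integer(num_random_splits),
                 replace = replace, sample_fraction = sample_fraction),
            class = "meet_control")
}

# Fit one extra-trees probability forest on a feature matrix.
fit_et_forest <- function(X, y, control, seed) {
  d <- as.data.frame(X)
  d$.class <- y
  ranger::ranger(
    dependent.variable.name = ".class", data = d, probability = TRUE,
    num.trees = control$num_trees,
    mtry = control$mtry %||% floor(sqrt(ncol(X))),
    min.node.size = control$min_node_size,
    splitrule = "extratrees", num.random.splits = control$num_random_splits,
    replace = control$replace, sample.fraction = control$sample_fraction,
    seed = seed, num.threads = 1L
  )
}

predict_et_forest <- function(forest, X) {
  # forests deserialised from disk need ranger's S3 methods registered
  requireNamespace("ranger", quietly = TRUE)
  predict(forest, as.data.frame(X), num.threads = 1L)$predictions
}

coerce_features <- function(features) {
  if (inherits(features, "feature_matrix"))
    list(X = features$values, y = as.integer(features$labels))
  else stop("`features` must be a feature_matrix (see featurize())",
            call. = FALSE)
}

#' Fit a MEET model
#'
#' Trains one extra-trees expert per class subset (each expert sees only the
#' rows whose label belongs to its subset) and a gate of the same family on
#' all rows. Experts are mutually independent: each receives its own seed
#' derived from the master seed, so training them in any order - or dropping
#' the data of other subsets - leaves an expert's fit unchanged.
#'
#' @param features A [featurize()] result (or [read_features()]).
#' @param a Classes per expert (default 2).
#' @param control A [meet_control()].
#' @param seed Master seed fanned out to per-expert and gate seeds.
#' @param fusion Fusion rule: `"per_class"` (normative) multiplies the stacked
#'   expert probability vector Z elementwise with the gate's length-N class
#'   probability vector M; `"per_expert"` instead weights each expert's block
#'   of Z by the gate's total probability mass on that expert's subset.
#' @return An object of class `meet_model`.
#' @examples
#' \donttest{
#' cfg <- synth_config(n_classes = 6, gesture_duration_s = 4, seed = 3)
#' fm <- featurize(segment_windows(notch_filter(bandpass_filter(
#'   generate_recording(cfg, 1)))))
#' m <- meet_fit(fm, a = 2, seed = 9)
#' table(predict(m, fm), fm$labels)
#' }
#' @export
meet_fit <- function(features, a = 2L, control = meet_control(), seed = 1L,
                     fusion = c("per_class", "per_expert")) {
  fusion <- match.arg(fusion)
  fd <- coerce_features(features)
  X <- fd$X; y <- fd$y
  class_order <- sort(unique(y))
  if (length(class_order) < 2L)
    stop("need at least 2 classes to fit a MEET model", call. = FALSE)
  counts <- table(factor(y, levels = class_order))
  if (any(counts < 2L))
    stop("class ", names(counts)[which(counts < 2L)[1]],
         " has fewer than 2 training rows", call. = FALSE)
  partition <- partition_classes(class_order, a)
  n_experts <- length(partition)
  seeds <- with_private_seed(seed, sample.int(.Machine$integer.max - 1L,
                                              n_experts + 1L))
  experts <- vector("list", n_experts)
  for (e in seq_len(n_experts)) {
    rows <- y %in% partition[[e]]
    experts[[e]] <- fit_et_forest(
      X[rows, , drop = FALSE],
      factor(y[rows], levels = partition[[e]]),
      control, seeds[e])
  }
  gate <- fit_et_forest(X, factor(y, levels = class_order), control,
                        seeds[n_experts + 1L])
  structure(
    list(experts = experts, gate = gate, partition = partition,
         class_order = class_order, a = as.integer(a),
         feature_schema = colnames(X), control = control,
         train_seed = as.integer(seed), fusion = fusion),
    class = "meet_model"
  )
}

#' @export
print.meet_model <- function(x, ...) {
  cat("<meet_model>", length(x$experts), "experts + 1 gate,",
      length(x$class_order), "classes (a =", x$a, ")\n")
  for (e in seq_along(x$partition))
    cat("  E", e, ": classes {", paste(x$partition[[e]], collapse = ","),
        "}\n", sep = "")
  invisible(x)
}

check_schema <- function(model, X) {
  if (is.null(colnames(X)) || !identical(colnames(X), model$feature_schema))
    stop("feature schema mismatch: expected columns ",
         paste(head(model$feature_schema, 3), collapse = ", "), ", ... (",
         length(model$feature_schema), " total)", call. = FALSE)
}

# Stacked expert probabilities (Z) and gate probabilities (M) for all rows.
meet_probability_stack <- function(model, X) {
  check_schema(model, X)
  N <- length(model$class_order)
  Z <- matrix(NA_real_, nrow = nrow(X), ncol = N,
              dimnames = list(NULL, model$class_order))
  for (e in seq_along(model$experts)) {
    pos <- match(model$partition[[e]], model$class_order)
    Z[, pos] <- predict_et_forest(model$experts[[e]], X)
  }
  M <- predict_et_forest(model$gate, X)
  if (model$fusion == "per_expert") {
    # collapse the gate's class mass onto each expert and spread it back
    # over the expert's block, so fusion stays an elementwise product
    W <- matrix(NA_real_, nrow = nrow(X), ncol = N)
    for (e in seq_along(model$partition)) {
      pos <- match(model$partition[[e]], model$class_order)
      W[, pos] <- rowSums(M[, pos, drop = FALSE])
    }
    M <- W
  }
  list(Z = Z, M = M)
}

#' Stacked expert and gate probability vectors for one observation
#'
#' Assembles the fusion inputs for a single feature row: `Z`, the length-N
#' stacked expert vector (position of class `c` holds the probability the
#' expert owning `c` assigns to it), and `M`, the gate's probability vector
#' over all N classes.
#'
#' @param model A [meet_fit()] result.
#' @param row A named numeric vector or 1-row matrix matching the model's
#'   feature schema.
#' @return List with numeric vectors `Z` and `M` (names = class codes).
#' @export
fusion_vectors <- function(model, row) {
  stopifnot(inherits(model, "meet_model"))
  if (is.null(dim(row))) row <- matrix(row, nrow = 1L,
                                       dimnames = list(NULL, names(row)))
  zm <- meet_probability_stack(model, row)
  list(Z = zm$Z[1L, ], M = zm$M[1L, ])
}

#' Fuse expert and gate probabilities into a class decision
#'
#' The MEET decision rule: the predicted class maximises the elementwise
#' (Hadamard) product of the stacked expert vector `Z` and the gate vector
#' `M`. Ties are broken toward the lowest class code.
#'
#' @param Z,M Numeric vectors of equal length N with entries in `[0, 1]`.
#' @param class_order Class codes corresponding to the positions of `Z`/`M`.
#' @return The predicted class code.
#' @examples
#' fuse_predict(c(0.9, 0.1, 0.6, 0.4, 0.5, 0.5),
#'              c(0.05, 0.05, 0.60, 0.10, 0.10, 0.10), 1:6)  # class 3
#' @export
fuse_predict <- function(Z, M, class_order) {
  if (length(Z) != length(M) || length(Z) != length(class_order))
    stop("Z, M and class_order must have equal length", call. = FALSE)
  if (any(Z < 0 | Z > 1) || any(M < 0 | M > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  p <- Z * M
  min(class_order[p == max(p)])
}

#' Predict gesture classes with a fitted MEET model
#'
#' Row-wise fused prediction: for every feature row the stacked expert vector
#' and gate vector are combined by [fuse_predict()].
#'
#' @param object A [meet_fit()] result.
#' @param features A [featurize()] result, or a numeric matrix matching the
#'   model's feature schema.
#' @param ... Unused.
#' @return Integer vector of predicted class codes (empty input gives an
#'   empty vector).
#' @export
predict.meet_model <- function(object, features, ...) {
  X <- if (inherits(features, "feature_matrix")) features$values
       else as.matrix(features)
  if (nrow(X) == 0L) return(integer(0))
  zm <- meet_probability_stack(object, X)
  P <- zm$Z * zm$M
  # ascending class_order: "first" maximum is the lowest class code
  object$class_order[max.col(P, ties.method = "first")]
}

#' Fit a plain extra-trees baseline
#'
#' A single extra-trees probability forest trained on all classes - the same
#' family as the MEET gate. Used as the baseline the mixture is compared
#' against.
#'
#' @inheritParams meet_fit
#' @return An object of class `et_model`.
#' @export
et_fit <- function(features, control = meet_control(), seed = 1L) {
  fd <- coerce_features(features)
  class_order <- sort(unique(fd$y))
  forest <- fit_et_forest(fd$X, factor(fd$y, levels = class_order), control,
                          with_private_seed(seed, sample.int(.Machine$integer.max - 1L, 1L)))
  structure(list(forest = forest, class_order = class_order,
                 feature_schema = colnames(fd$X), control = control,
                 train_seed = as.integer(seed)),
            class = "et_model")
}

#' @export
predict.et_model <- function(object, features, ...) {
  X <- if (inherits(features, "feature_matrix")) features$values
       else as.matrix(features)
  if (nrow(X) == 0L) return(integer(0))
  check_schema(object, X)
  P <- predict_et_forest(object$forest, X)
  object$class_order[max.col(P, ties.method = "first")]
}

#' Save / load a fitted model
#'
#' The model is persisted as an RDS bundle together with a JSON sidecar
#' (`<path>.json`) recording the class partition, class order, feature
#' schema, seed and hyperparameters for provenance.
#'
#' @param model A `meet_model` or `et_model`.
#' @param path File path for the binary bundle.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  side <- list(model_class = class(model)[1],
               class_order = model$class_order,
               feature_schema = model$feature_schema,
               train_seed = model$train_seed,
               control = unclass(model$control))
  if (inherits(model, "meet_model")) {
    side$partition <- lapply(model$partition, as.integer)
    side$a <- model$a
    side$fusion <- model$fusion
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
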