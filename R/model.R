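#' Assemble the full feature matrix for one target cell
#'
#' One row per labeled CpG site of the target cell on the requested
#' chromosomes; columns are the sequence block (84 n-gram frequencies), the
#' structural block (one column per annotation track) and the positional
#' block (`4m + 8(m-1)` cross-cell neighbour features), in that order. With
#' the full 175-track manifest and m = 25 cells this is 259 + 292 = 551
#' columns. Labels come from the profile's binarized states.
#'
#' @param dataset A [multicell_dataset()] (all cells, used for cross-cell
#'   features).
#' @param genome Named character vector from [read_genome()], or `NULL` to
#'   skip the sequence block.
#' @param tracks A [track_set()], or `NULL` to skip the structural block.
#' @param cell Target cell id.
#' @param chroms Chromosomes defining the partition (e.g.
#'   `split_spec()$train_chroms`).
#' @param features Which blocks to build: subset of
#'   `c("seq", "str", "pos")`.
#' @param flank Sequence window half-width (default 50).
#' @return An object of class `feature_matrix`: list with `x` (numeric
#'   matrix, named columns), `y` (0/1 labels), `keys` (cell_id, chrom, pos).
#' @export
build_matrix <- function(dataset, genome = NULL, tracks = NULL, cell,
                         chroms, features = c("seq", "str", "pos"),
                         flank = 50L) {
  stopifnot(inherits(dataset, "multicell_dataset"))
  features <- match.arg(features, c("seq", "str", "pos"), several.ok = TRUE)
  prof <- dataset$cells[[cell]]
  if (is.null(prof)) stop("unknown cell: ", cell)
  sites <- prof$sites[chrom %in% chroms & !is.na(state)]
  if (nrow(sites) == 0L) stop("empty partition: no labeled sites for cell ",
                              cell, " on the requested chromosomes")
  blocks <- list()
  if ("seq" %in% features) {
    if (is.null(genome)) stop("sequence features requested but genome is NULL")
    blocks$seq <- sequence_feature_matrix(genome, sites, flank = flank)
  }
  if ("str" %in% features) {
    if (is.null(tracks)) stop("structural features requested but tracks is NULL")
    blocks$str <- structural_feature_matrix(sites, tracks)
  }
  if ("pos" %in% features) {
    blocks$pos <- positional_feature_matrix(dataset, cell, sites)
  }
  x <- do.call(cbind, unname(blocks))
  structure(list(x = x, y = sites$state,
                 keys = data.table(cell_id = cell, chrom = sites$chrom,
                                   pos = sites$pos)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d sites x %d features (%d methylated)\n",
              nrow(x$x), ncol(x$x), sum(x$y)))
  invisible(x)
}

#' Gradient-boosting hyperparameter configuration
#'
#' Defaults: 110 trees, maximum depth 5, 22 leaves, learning rate 0.04.
#' `threads = 1` by default so training is bit-reproducible under a fixed
#' seed; raise it for speed on large data.
#'
#' @param n_trees Number of boosting rounds.
#' @param max_depth Maximum tree depth.
#' @param num_leaves Maximum leaves per tree (leaf-wise growth); must not
#'   exceed `2^max_depth`.
#' @param learning_rate Shrinkage per round.
#' @param threads Number of threads.
#' @param seed RNG seed for the booster.
#' @return A list of class `model_config`.
#' @export
model_config <- function(n_trees = 110L, max_depth = 5L, num_leaves = 22L,
                         learning_rate = 0.04, threads = 1L, seed = 1L) {
  stopifnot(n_trees >= 1L, max_depth >= 1L, num_leaves >= 2L,
            num_leaves <= 2^max_depth, learning_rate > 0)
  structure(list(n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 num_leaves = as.integer(num_leaves),
                 learning_rate = learning_rate,
                 threads = as.integer(threads),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Train a gradient-boosted tree classifier on a feature matrix
#'
#' Thin wrapper around xgboost's histogram-based leaf-wise booster (the
#' same GOSS/EFB-era tree-growing family the reference operations
#' [goss_select()] and [efb_bundle()] document). Missing feature values
#' (`NA`) are handled natively by the trees.
#'
#' @param fm A [build_matrix()] result, or a list with `x` and `y`.
#' @param config A [model_config()].
#' @return An object of class `trained_model`: the fitted booster, the
#'   feature-name manifest it was trained on, and the config.
#' @export
train_model <- function(fm, config = model_config()) {
  x <- fm$x; y <- fm$y
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class")
  dtrain <- xgboost::xgb.DMatrix(x, label = y, missing = NA, nthread = config$threads)
  params <- list(objective = "binary:logistic",
                 eval_metric = "logloss",
                 tree_method = "hist",
                 grow_policy = "lossguide",
                 max_depth = config$max_depth,
                 max_leaves = config$num_leaves,
                 eta = config$learning_rate,
                 nthread = config$threads,
                 seed = config$seed)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = config$n_trees, verbose = 0)
  structure(list(booster = booster, manifest = colnames(x), config = config),
            class = "trained_model")
}

#' Predict methylation probabilities and states
#'
#' Columns of `newdata` are aligned to the training manifest by name, so
#' column order does not matter; a missing manifest column is an error.
#'
#' @param object A [train_model()] result.
#' @param newdata A `feature_matrix` or a numeric matrix with named columns.
#' @param threshold Probability cut for the binary state (default 0.5).
#' @param ... Unused.
#' @return data.frame with `prob` and `state` columns.
#' @export
predict.trained_model <- function(object, newdata, threshold = 0.5, ...) {
  x <- if (inherits(newdata, "feature_matrix")) newdata$x else newdata
  missing_cols <- setdiff(object$manifest, colnames(x))
  if (length(missing_cols))
    stop("newdata lacks manifest columns: ",
         paste(head(missing_cols, 3), collapse = ", "))
  x <- x[, object$manifest, drop = FALSE]
  dm <- xgboost::xgb.DMatrix(x, missing = NA,
                             nthread = object$config$threads)
  prob <- predict(object$booster, dm)
  data.frame(prob = prob, state = as.integer(prob > threshold))
}

#' Per-feature split participation counts
#'
#' The importance of a feature is the number of tree nodes that split on it,
#' summed over all trees of the model. Features never used get 0.
#'
#' @param model A [train_model()] result.
#' @return Named integer vector over the full training manifest.
#' @export
split_importance <- function(model) {
  tr <- xgboost::xgb.model.dt.tree(model = model$booster)
  splits <- tr[Feature != "Leaf", .N, by = Feature]
  out <- setNames(integer(length(model$manifest)), model$manifest)
  feat <- splits$Feature
  if (is.numeric(feat) || all(grepl("^[0-9]+$", feat)))
    feat <- model$manifest[as.integer(feat) + 1L]
  out[feat] <- splits$N
  out
}

#' Sum split-count importances across per-cell models
#'
#' @param models List of [train_model()] results sharing one manifest.
#' @return data.frame with columns `feature` and `splits`, sorted by
#'   decreasing count; ties keep name order (stable).
#' @export
aggregate_importance <- function(models) {
  mans <- lapply(models, `[[`, "manifest")
  if (!all(vapply(mans, identical, logical(1), mans[[1L]])))
    stop("models have differing feature manifests")
  imp <- Reduce(`+`, lapply(models, split_importance))
  imp <- imp[order(-imp, names(imp), method = "radix")]
  data.frame(feature = names(imp), splits = as.integer(imp),
             row.names = NULL)
}

#' GOSS sampling configuration
#'
#' @param a_frac Top fraction of samples kept by absolute gradient.
#' @param b_frac Fraction of the *remaining* samples drawn uniformly.
#' @param amplify Up-weight the sampled remainder by the inverse sampling
#'   fraction so the expected total gradient mass is preserved.
#' @param seed RNG seed for the uniform draw.
#' @return A list of class `goss_config`.
#' @export
goss_config <- function(a_frac = 0.2, b_frac = 0.1, amplify = TRUE, seed = 1L) {
  stopifnot(a_frac >= 0, a_frac <= 1, b_frac >= 0, b_frac <= 1,
            a_frac + b_frac <= 1 + 1e-12)
  structure(list(a_frac = a_frac, b_frac = b_frac, amplify = isTRUE(amplify),
                 seed = as.integer(seed)),
            class = "goss_config")
}

#' Gradient-based one-side sampling (reference implementation)
#'
#' Keeps the `ceil(a * n)` samples with the largest absolute gradients, plus
#' a uniform draw of `ceil(b * r)` samples from the `r` remaining ones. With
#' `amplify` on, the sampled remainder is weighted by its inverse sampling
#' fraction `r / ceil(b * r)` (~ 1/b), which makes the expected weighted sum
#' of gradient magnitudes equal that of the full sample. This is a reference
#' operation for study; production training delegates sampling to the
#' booster.
#'
#' @param gradients Numeric vector of per-sample gradients.
#' @param config A [goss_config()].
#' @return List with `indices` (into `gradients`; top block first, in
#'   decreasing |gradient| order) and `weights` (parallel to `indices`).
#' @export
goss_select <- function(gradients, config = goss_config()) {
  n <- length(gradients)
  if (n == 0L) stop("empty gradient vector")
  ord <- order(-abs(gradients), seq_len(n), method = "radix")
  n_top <- ceiling(config$a_frac * n)
  top <- ord[seq_len(n_top)]
  rest <- ord[setdiff(seq_len(n), seq_len(n_top))]
  r <- length(rest)
  n_samp <- if (r > 0L) ceiling(config$b_frac * r) else 0L
  sampled <- if (n_samp > 0L) {
    set.seed(config$seed)
    sort(sample(rest, n_samp))
  } else integer(0)
  w_samp <- if (n_samp > 0L && config$amplify) r / n_samp else 1
  list(indices = c(top, sampled),
       weights = c(rep(1, n_top), rep(w_samp, n_samp)))
}

#' Conflict weight between two sparse feature columns
#'
#' The fraction of rows where both features are simultaneously non-zero:
#' `w = N_ij / L`. Features with small conflict are candidates for bundling.
#'
#' @param col_i,col_j Equal-length numeric vectors.
#' @return The conflict weight in \[0, 1\].
#' @export
efb_conflict <- function(col_i, col_j) {
  if (length(col_i) != length(col_j)) stop("columns differ in length")
  L <- length(col_i)
  if (L == 0L) stop("empty columns")
  sum(col_i != 0 & col_j != 0, na.rm = TRUE) / L
}

#' Greedy exclusive-feature-bundling plan (reference implementation)
#'
#' Builds the conflict graph over columns (edge weight = [efb_conflict()]),
#' sorts features by decreasing weighted degree, and greedily assigns each
#' feature to the first existing set whose total added conflict does not
#' exceed `d`, otherwise starts a new set. Ties in degree break by column
#' index, so the plan is deterministic.
#'
#' @param x Numeric matrix of feature columns.
#' @param d Maximum tolerated conflict between a feature and a set.
#' @return An object of class `bundle_plan`: list with `sets` (list of
#'   column-index vectors partitioning the columns) and `d`.
#' @export
efb_bundle <- function(x, d = 0.05) {
  stopifnot(is.matrix(x), d >= 0)
  p <- ncol(x)
  nz <- x != 0 & !is.na(x)
  W <- crossprod(nz) / nrow(x)     # conflict weights; diagonal unused
  diag(W) <- 0
  degree <- rowSums(W)
  ord <- order(-degree, seq_len(p), method = "radix")
  sets <- list()
  for (f in ord) {
    placed <- FALSE
    for (k in seq_along(sets)) {
      if (sum(W[f, sets[[k]]]) <= d) {
        sets[[k]] <- c(sets[[k]], f)
        placed <- TRUE
        break
      }
    }
    if (!placed) sets[[length(sets) + 1L]] <- f
  }
  structure(list(sets = sets, d = d), class = "bundle_plan")
}

#' Merge bundled features into composite columns
#'
#' Each set of the plan collapses to one column via an offset (mixed-radix)
#' encoding of the features' non-negative integer value ranges: feature f
#' with maximum value B_f occupies its own digit of base `B_f + 1`, so zero
#' stays the shared zero bin, exclusive columns land in disjoint value
#' ranges (two exclusive binaries x, y merge to \{0, 1, 2\} with y = 1 at 2),
#' and the original columns are exactly recoverable from the composite for
#' any plan via [unmerge_bundles()].
#'
#' @param x Numeric matrix of non-negative integer-valued columns.
#' @param plan A [efb_bundle()] plan built on `x`'s columns.
#' @return List of class `merged_matrix`: `x` (one column per set) and
#'   `codec` (per-set decode tables).
#' @export
merge_bundles <- function(x, plan) {
  stopifnot(inherits(plan, "bundle_plan"))
  if (any(x < 0, na.rm = TRUE) || any(x != floor(x), na.rm = TRUE))
    stop("merge_bundles requires non-negative integer-valued columns ",
         "(histogram bins)")
  cols <- lapply(plan$sets, function(set) {
    base <- apply(x[, set, drop = FALSE], 2L, max) + 1
    mult <- cumprod(c(1, head(base, -1L)))
    if (prod(base) > 2^53)
      stop("offset range overflow: bundle value range exceeds 2^53")
    merged <- as.vector(x[, set, drop = FALSE] %*% mult)
    list(merged = merged, set = set, base = base, mult = mult)
  })
  xm <- do.call(cbind, lapply(cols, `[[`, "merged"))
  colnames(xm) <- vapply(plan$sets, function(set) {
    nm <- colnames(x)[set]
    if (length(nm) == 1L) nm else paste0("bundle(", paste(nm, collapse = "+"), ")")
  }, character(1))
  codec <- lapply(cols, function(cc)
    list(set = cc$set, names = colnames(x)[cc$set],
         base = cc$base, mult = cc$mult))
  structure(list(x = xm, codec = codec, p_original = ncol(x)),
            class = "merged_matrix")
}

#' Recover the original columns from a merged matrix
#'
#' Exact inverse of [merge_bundles()].
#'
#' @param merged A [merge_bundles()] result.
#' @return Numeric matrix with the original columns in their original order.
#' @export
unmerge_bundles <- function(merged) {
  stopifnot(inherits(merged, "merged_matrix"))
  out <- matrix(NA_real_, nrow(merged$x), merged$p_original)
  nm <- character(merged$p_original)
  for (k in seq_along(merged$codec)) {
    cc <- merged$codec[[k]]
    v <- merged$x[, k]
    for (j in seq_along(cc$set)) {
      out[, cc$set[j]] <- (v %/% cc$mult[j]) %% cc$base[j]
      nm[cc$set[j]] <- cc$names[j]
    }
  }
  colnames(out) <- nm
  out
}
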