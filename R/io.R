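mb_header <- function(seed = NA) {
  sprintf("# methboost %s%s",
          as.character(utils::packageVersion("methboost")),
          if (is.na(seed)) "" else paste0(" seed=", seed))
}

# atomic write: assemble in a temp file, then rename into place
write_tsv_atomic <- function(df, path, header = NULL) {
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, "wt")
  if (!is.null(header)) writeLines(header, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

#' Write a feature matrix as headered TSV with a sidecar manifest
#'
#' The main file holds the row keys (cell_id, chrom, pos), the label and the
#' feature columns; `<path>.manifest.tsv` records each feature's name and
#' block (seq/str/pos/other) in column order so a model trained elsewhere
#' can check its inputs.
#'
#' @param fm A [build_matrix()] result.
#' @param path Output TSV path.
#' @param seed Optional seed recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path, seed = NA) {
  df <- cbind(as.data.frame(fm$keys), label = fm$y, as.data.frame(fm$x))
  write_tsv_atomic(df, path, header = mb_header(seed))
  block <- sub("_.*$", "", colnames(fm$x))
  block[!block %in% c("seq", "str", "pos", "skip")] <- "other"
  write_tsv_atomic(data.frame(feature = colnames(fm$x), block = block),
                   paste0(path, ".manifest.tsv"))
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#' @param path TSV path.
#' @return A `feature_matrix` object.
#' @export
read_feature_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE)
  keycols <- c("cell_id", "chrom", "pos", "label")
  if (!all(keycols %in% names(df))) stop("not a feature matrix file: ", path)
  x <- as.matrix(df[, setdiff(names(df), keycols), drop = FALSE])
  structure(list(x = x, y = as.integer(df$label),
                 keys = as.data.table(df[, c("cell_id", "chrom", "pos")])),
            class = "feature_matrix")
}

#' Save / load a trained model
#'
#' The booster is stored in the library's native JSON format next to a
#' manifest JSON holding feature names and the training config, so a loaded
#' model predicts on exactly the columns it was trained on.
#'
#' @param model A [train_model()] result.
#' @param dir Output directory.
#' @return `dir` (save) or a `trained_model` (load), invisibly for save.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  xgboost::xgb.save(model$booster, file.path(dir, "booster.json"))
  jsonlite::write_json(list(manifest = model$manifest,
                            config = unclass(model$config)),
                       file.path(dir, "model_meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model_meta.json"),
                              simplifyVector = TRUE)
  booster <- xgboost::xgb.load(file.path(dir, "booster.json"))
  cfg <- do.call(model_config, as.list(meta$config))
  structure(list(booster = booster, manifest = meta$manifest, config = cfg),
            class = "trained_model")
}
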