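#' @import data.table
#' @importFrom stats rbinom rgeom rpois runif setNames
#' @importFrom utils read.table write.table head tail
NULL

PROFILE_COLS <- c("chrom", "pos", "meth_reads", "total_reads", "state")

#' Construct a single-cell CpG profile
#'
#' A cell profile is the ordered per-chromosome set of CpG sites observed in
#' one cell. Each site carries its 1-based genomic position (the C of the CpG
#' dinucleotide, forward strand), optional read counts, and a binary
#' methylation state (1 = methylated, 0 = unmethylated, `NA` = unknown or
#' excluded by the coverage/tie filter).
#'
#' @param cell_id Character scalar identifying the cell.
#' @param sites A data.frame with columns `chrom`, `pos` and either read
#'   counts (`meth_reads`, `total_reads`), a `state` column, or both. Missing
#'   count columns are filled with `NA`; a missing `state` column is derived
#'   from the counts via [binarize()].
#' @param min_cov Minimum read depth used when deriving states from counts.
#' @return An object of class `cell_profile`: a list with `cell_id` and a
#'   `sites` data.table sorted by (chrom, pos), positions unique per
#'   chromosome.
#' @export
cell_profile <- function(cell_id, sites, min_cov = 4L) {
  stopifnot(is.character(cell_id), length(cell_id) == 1L, nchar(cell_id) > 0L)
  sites <- as.data.table(sites)
  if (!all(c("chrom", "pos") %in% names(sites)))
    stop("sites must have 'chrom' and 'pos' columns")
  if (!"meth_reads" %in% names(sites)) sites[, meth_reads := NA_integer_]
  if (!"total_reads" %in% names(sites)) sites[, total_reads := NA_integer_]
  if (!"state" %in% names(sites))
    sites[, state := binarize(meth_reads, total_reads, min_cov = min_cov)]
  sites <- sites[, PROFILE_COLS, with = FALSE]
  sites[, chrom := as.character(chrom)]
  sites[, pos := as.integer(pos)]
  sites[, state := as.integer(state)]
  if (any(sites$pos < 1L, na.rm = TRUE)) stop("positions must be >= 1")
  bad <- !is.na(sites$state) & !sites$state %in% c(0L, 1L)
  if (any(bad)) stop("states must be 0, 1 or NA")
  cmp <- !is.na(sites$meth_reads) & !is.na(sites$total_reads)
  if (any(sites$meth_reads[cmp] > sites$total_reads[cmp]))
    stop("meth_reads exceeds total_reads")
  setorder(sites, chrom, pos)
  dup <- sites[, any(duplicated(pos)), by = chrom]$V1
  if (any(dup)) stop("duplicate positions within a chromosome in cell ", cell_id)
  structure(list(cell_id = cell_id, sites = sites[]), class = "cell_profile")
}

#' @export
print.cell_profile <- function(x, ...) {
  ns <- nrow(x$sites)
  nl <- sum(!is.na(x$sites$state))
  cat(sprintf("<cell_profile> %s: %d sites (%d labeled) on %d chromosome(s)\n",
              x$cell_id, ns, nl, length(unique(x$sites$chrom))))
  invisible(x)
}

#' Bundle cell profiles into a multi-cell dataset
#'
#' @param cells A list of [cell_profile()] objects with unique cell ids.
#' @return An object of class `multicell_dataset`; cells are stored in
#'   lexicographic `cell_id` order, the order used for positional feature
#'   blocks.
#' @export
multicell_dataset <- function(cells) {
  if (inherits(cells, "cell_profile")) cells <- list(cells)
  stopifnot(is.list(cells), length(cells) >= 1L)
  ok <- vapply(cells, inherits, logical(1), "cell_profile")
  if (!all(ok)) stop("all elements must be cell_profile objects")
  ids <- vapply(cells, `[[`, character(1), "cell_id")
  if (anyDuplicated(ids)) stop("cell ids must be unique")
  cells <- cells[order(ids)]
  names(cells) <- sort(ids)
  structure(list(cells = cells), class = "multicell_dataset")
}

#' @export
print.multicell_dataset <- function(x, ...) {
  cat(sprintf("<multicell_dataset> %d cell(s): %s\n", length(x$cells),
              paste(names(x$cells), collapse = ", ")))
  invisible(x)
}

#' Number of cells in a dataset
#' @param dataset A `multicell_dataset`.
#' @return Integer m.
#' @export
n_cells <- function(dataset) length(dataset$cells)

#' Binarize methylation read counts by majority vote
#'
#' A site is labeled methylated (1) when more than half of its reads are
#' methylated, unmethylated (0) when fewer than half are, and excluded (`NA`)
#' when coverage is below `min_cov` reads or the reads split exactly in half.
#' Ties are excluded because a site that is neither mostly methylated nor
#' mostly unmethylated has no usable binary label.
#'
#' @param meth_reads,total_reads Non-negative integer vectors of equal length.
#' @param min_cov Minimum total read count; sites below it are excluded.
#'   Default 4.
#' @return Integer vector in \{0, 1, NA\}.
#' @export
binarize <- function(meth_reads, total_reads, min_cov = 4L) {
  meth_reads <- as.numeric(meth_reads)
  total_reads <- as.numeric(total_reads)
  if (any(meth_reads < 0, na.rm = TRUE) || any(total_reads < 0, na.rm = TRUE))
    stop("read counts must be non-negative")
  if (any(meth_reads > total_reads, na.rm = TRUE))
    stop("meth_reads exceeds total_reads")
  out <- ifelse(meth_reads * 2 > total_reads, 1L, 0L)
  out[total_reads < min_cov | meth_reads * 2 == total_reads] <- NA_integer_
  out[is.na(meth_reads) | is.na(total_reads)] <- NA_integer_
  as.integer(out)
}

#' Read a per-cell CpG profile from a TSV file
#'
#' Two dialects are supported: `counts` files have columns
#' (chrom, pos, meth_reads, total_reads); `states` files have
#' (chrom, pos, state). Positions are 1-based. Lines starting with `#` are
#' skipped. Files ending in `.gz` are decompressed transparently. Input rows
#' may be unsorted (they are sorted on load) but duplicate positions within a
#' chromosome are an error.
#'
#' @param path Path to the TSV file.
#' @param dialect `"counts"` or `"states"`.
#' @param cell_id Cell identifier; defaults to the file name without
#'   extension.
#' @param min_cov Coverage threshold forwarded to [binarize()] for the counts
#'   dialect.
#' @return A [cell_profile()].
#' @export
read_profile <- function(path, dialect = c("counts", "states"),
                         cell_id = NULL, min_cov = 4L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(cell_id))
    cell_id <- sub("\\.(tsv|txt|bed)(\\.gz)?$", "", basename(path))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty profile file: ", path)
  fields <- strsplit(lines, "[\t ]+")
  ncol_need <- if (dialect == "counts") 4L else 3L
  nf <- lengths(fields)
  if (any(nf < ncol_need))
    stop("malformed row at line ", lineno[which(nf < ncol_need)[1L]],
         ": expected >= ", ncol_need, " fields")
  m <- do.call(rbind, lapply(fields, `[`, seq_len(ncol_need)))
  num <- function(col, name) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v))
      stop("malformed row at line ", lineno[which(is.na(v))[1L]],
           ": non-numeric ", name)
    v
  }
  if (dialect == "counts") {
    sites <- data.table(chrom = m[, 1L], pos = num(2L, "pos"),
                        meth_reads = as.integer(num(3L, "meth_reads")),
                        total_reads = as.integer(num(4L, "total_reads")))
    bad <- sites$meth_reads > sites$total_reads
    if (any(bad))
      stop("malformed row at line ", lineno[which(bad)[1L]],
           ": meth_reads exceeds total_reads")
  } else {
    st <- as.integer(num(3L, "state"))
    if (any(!st %in% c(0L, 1L)))
      stop("malformed row at line ", lineno[which(!st %in% c(0L, 1L))[1L]],
           ": state must be 0 or 1")
    sites <- data.table(chrom = m[, 1L], pos = num(2L, "pos"), state = st)
  }
  cell_profile(cell_id, sites, min_cov = min_cov)
}

#' Write a cell profile as TSV
#'
#' Mirror of [read_profile()]: the `counts` dialect writes
#' (chrom, pos, meth_reads, total_reads), the `states` dialect writes
#' (chrom, pos, state) for labeled sites only. A `.gz` suffix triggers gzip
#' compression.
#'
#' @param profile A [cell_profile()].
#' @param path Output path.
#' @param dialect `"counts"` or `"states"`.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, dialect = c("counts", "states")) {
  dialect <- match.arg(dialect)
  s <- profile$sites
  out <- if (dialect == "counts") {
    s[, c("chrom", "pos", "meth_reads", "total_reads"), with = FALSE]
  } else {
    s[!is.na(state), c("chrom", "pos", "state"), with = FALSE]
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Chromosome hold-out split specification
#'
#' Defaults follow the standard chromosome hold-out protocol for methylation
#' models: odd autosomes 1-11 for training, even autosomes 2-12 for testing,
#' chromosomes 13-19 for validation.
#'
#' @param train_chroms,test_chroms,val_chroms Pairwise disjoint character
#'   vectors of chromosome names.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_chroms = paste0("chr", c(1, 3, 5, 7, 9, 11)),
                       test_chroms = paste0("chr", c(2, 4, 6, 8, 10, 12)),
                       val_chroms = paste0("chr", 13:19)) {
  all <- c(train_chroms, test_chroms, val_chroms)
  if (anyDuplicated(all))
    stop("split chromosome lists must be pairwise disjoint")
  structure(list(train_chroms = as.character(train_chroms),
                 test_chroms = as.character(test_chroms),
                 val_chroms = as.character(val_chroms)),
            class = "split_spec")
}

restrict_profile <- function(profile, chroms) {
  structure(list(cell_id = profile$cell_id,
                 sites = profile$sites[chrom %in% chroms]),
            class = "cell_profile")
}

#' Split a dataset into train/test/validation partitions by chromosome
#'
#' Every site is assigned to at most one partition according to its
#' chromosome; sites on chromosomes absent from all three lists are dropped
#' (their count is reported via a message).
#'
#' @param dataset A [multicell_dataset()].
#' @param spec A [split_spec()].
#' @return A list with elements `train`, `test`, `val` (each a
#'   `multicell_dataset`, or `NULL` for an empty chromosome list) and
#'   `n_dropped`, the number of dropped (cell, site) records.
#' @export
split_dataset <- function(dataset, spec = split_spec()) {
  stopifnot(inherits(dataset, "multicell_dataset"), inherits(spec, "split_spec"))
  listed <- c(spec$train_chroms, spec$test_chroms, spec$val_chroms)
  n_tot <- sum(vapply(dataset$cells, function(p) nrow(p$sites), integer(1)))
  part <- function(chroms) {
    if (length(chroms) == 0L) return(NULL)
    multicell_dataset(lapply(dataset$cells, restrict_profile, chroms = chroms))
  }
  out <- list(train = part(spec$train_chroms),
              test = part(spec$test_chroms),
              val = part(spec$val_chroms))
  n_kept <- sum(vapply(dataset$cells,
                       function(p) sum(p$sites$chrom %in% listed), integer(1)))
  out$n_dropped <- n_tot - n_kept
  if (out$n_dropped > 0L)
    message(out$n_dropped, " site record(s) on unlisted chromosomes dropped")
  out
}

labeled_sites <- function(dataset) {
  rbindlist(lapply(dataset$cells, function(p)
    cbind(cell_id = p$cell_id, p$sites[!is.na(state)])))
}

#' Cross-cell overlap statistics of known CpG sites
#'
#' Summarizes how often methylation states are known at the same genomic
#' position in more than one cell. Counts are over (cell, site) records with
#' a known (0/1) state:
#' \itemize{
#'   \item `N`: total number of known records.
#'   \item `N1`: records whose position has a known state in at least two
#'     cells.
#'   \item `N2`: records whose own state is shared by at least one other cell
#'     at the same position.
#'   \item `N3`: records at positions where the state is known in every cell
#'     of the dataset and identical across all of them (default rule; see
#'     `n3_rule`).
#' }
#' `Pk = 100 * Nk / N`. The `N3` column of published overlap tables is
#' ambiguous; the default interpretation (known in all m cells, unanimous) is
#' exposed as a replaceable predicate.
#'
#' @param dataset A [multicell_dataset()].
#' @param chroms Optional chromosome filter (default: all chromosomes).
#' @param n3_rule Function `(n_known, n_distinct_states, m)` returning whether
#'   a position qualifies for `N3`; vectorized over its first two arguments.
#' @return A list of class `overlap_stats` with N, N1-N3 and P1-P3 (percent).
#' @export
overlap_stats <- function(dataset, chroms = NULL,
                          n3_rule = function(n_known, n_distinct, m)
                            n_known == m & n_distinct == 1L) {
  stopifnot(inherits(dataset, "multicell_dataset"))
  m <- n_cells(dataset)
  sites <- labeled_sites(dataset)
  if (!is.null(chroms)) sites <- sites[chrom %in% chroms]
  if (nrow(sites) == 0L) stop("no labeled sites in the requested chromosomes")
  sites[, n_known := .N, by = .(chrom, pos)]
  sites[, n_same_state := .N, by = .(chrom, pos, state)]
  sites[, n_distinct := uniqueN(state), by = .(chrom, pos)]
  N <- nrow(sites)
  N1 <- sites[n_known >= 2L, .N]
  N2 <- sites[n_same_state >= 2L, .N]
  N3 <- sites[n3_rule(n_known, n_distinct, m), .N]
  structure(list(N = N, N1 = N1, N2 = N2, N3 = N3,
                 P1 = 100 * N1 / N, P2 = 100 * N2 / N, P3 = 100 * N3 / N),
            class = "overlap_stats")
}

#' @export
print.overlap_stats <- function(x, ...) {
  cat(sprintf(paste0("<overlap_stats> N=%d  N1=%d (%.2f%%)  N2=%d (%.2f%%)  ",
                     "N3=%d (%.2f%%)\n"),
              x$N, x$N1, x$P1, x$N2, x$P2, x$N3, x$P3))
  invisible(x)
}
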