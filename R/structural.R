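#' Construct an annotation track
#'
#' Binary tracks answer "is this position inside any interval" (CGIs, TFBS,
#' chromatin states, histone marks, DHS); score tracks attach a real value to
#' covered positions (iHS, evolutionary constraint). All coordinates are held
#' internally as 1-based closed `GRanges`; BED input is converted at load
#' time and nowhere else.
#'
#' @param name Track name, unique within a [track_set()].
#' @param kind `"binary_intervals"` or `"position_scores"`.
#' @param gr A `GRanges`; for score tracks it must carry a numeric `score`
#'   metadata column. Overlapping intervals of a binary track are merged
#'   (with a warning, since well-formed tracks are disjoint).
#' @return An object of class `annotation_track`.
#' @export
annotation_track <- function(name, kind = c("binary_intervals", "position_scores"),
                             gr) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, methods::is(gr, "GRanges"))
  if (kind == "binary_intervals") {
    red <- GenomicRanges::reduce(gr)
    if (length(red) != length(gr))
      warning("track '", name, "': overlapping intervals merged")
    gr <- red
  } else {
    if (!"score" %in% names(S4Vectors::mcols(gr)))
      stop("score track '", name, "' needs a 'score' metadata column")
  }
  structure(list(name = name, kind = kind, gr = gr),
            class = "annotation_track")
}

#' Load an annotation track from BED or bedGraph
#'
#' BED intervals are 0-based half-open and become 1-based closed internally;
#' bedGraph rows carry a fourth score column. Lines starting with `#`,
#' `track` or `browser` are skipped.
#'
#' @param path File path (optionally gzipped).
#' @param name Track name; defaults to the file name without extension.
#' @param kind `"binary_intervals"` (BED) or `"position_scores"` (bedGraph).
#' @return An [annotation_track()].
#' @export
load_track <- function(path, name = NULL,
                       kind = c("binary_intervals", "position_scores")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(name))
    name <- sub("\\.(bed|bedgraph|bedGraph|wig|txt)(\\.gz)?$", "", basename(path))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    gr <- GenomicRanges::GRanges()
    if (kind == "position_scores") S4Vectors::mcols(gr)$score <- numeric(0)
    return(annotation_track(name, kind, gr))
  }
  f <- strsplit(lines, "[\t ]+")
  need <- if (kind == "position_scores") 4L else 3L
  if (any(lengths(f) < need))
    stop("malformed line in ", path, ": fewer than ", need, " fields")
  chrom <- vapply(f, `[`, character(1), 1L)
  start0 <- suppressWarnings(as.numeric(vapply(f, `[`, character(1), 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(f, `[`, character(1), 3L)))
  if (anyNA(start0) || anyNA(end0) || any(start0 < 0) || any(end0 < start0))
    stop("bad coordinates in ", path)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0))
  if (kind == "position_scores") {
    sc <- suppressWarnings(as.numeric(vapply(f, `[`, character(1), 4L)))
    if (anyNA(sc)) stop("bad score value in ", path)
    S4Vectors::mcols(gr)$score <- sc
  }
  annotation_track(name, kind, gr)
}

#' Write a binary track as BED (or a score track as bedGraph)
#' @param track An [annotation_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  gr <- track$gr
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  if (track$kind == "position_scores") df$score <- S4Vectors::mcols(gr)$score
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Ordered collection of annotation tracks
#'
#' The track order fixes the structural feature column order; it comes from
#' the manifest, never from load order.
#'
#' @param tracks List of [annotation_track()] objects with unique names.
#' @return An object of class `track_set`.
#' @export
track_set <- function(tracks) {
  ok <- vapply(tracks, inherits, logical(1), "annotation_track")
  if (!all(ok)) stop("all elements must be annotation_track objects")
  nm <- vapply(tracks, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("track names must be unique")
  names(tracks) <- nm
  structure(tracks, class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  kinds <- vapply(x, `[[`, character(1), "kind")
  cat(sprintf("<track_set> %d tracks (%d binary, %d score)\n", length(x),
              sum(kinds == "binary_intervals"), sum(kinds == "position_scores")))
  invisible(x)
}

#' Load a track set from a manifest file
#'
#' The manifest is a headered TSV with columns `name`, `kind`, `path`
#' (paths relative to the manifest location unless absolute). Row order
#' defines feature order. The conventional full manifest has 175 tracks:
#' CGI + shore + shelf, 144 TFBS, 15 chromatin states, 10 histone marks and
#' DHS as binary tracks, plus iHS and constraint as score tracks.
#'
#' @param path Manifest path.
#' @return A [track_set()].
#' @export
load_manifest <- function(path) {
  man <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("name", "kind", "path") %in% names(man)))
    stop("manifest needs columns name, kind, path")
  base <- dirname(path)
  tracks <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!grepl("^/", p)) p <- file.path(base, p)
    load_track(p, name = man$name[i], kind = man$kind[i])
  })
  track_set(tracks)
}

#' Derive CpG-island shore and shelf intervals
#'
#' Shores are the 2-kb intervals flanking each CpG island and shelves the
#' next 2-kb further out (2-4 kb from the island), with island/shore
#' territory subtracted so the three classes are disjoint.
#'
#' @param cgi A `GRanges` of CpG island intervals.
#' @param shore_width,shelf_width Flank widths in bp (defaults 2000 each).
#' @return A list with `shore` and `shelf` `GRanges`.
#' @export
derive_shores_shelves <- function(cgi, shore_width = 2000L, shelf_width = 2000L) {
  cgi <- GenomicRanges::reduce(cgi)
  near <- GenomicRanges::reduce(GenomicRanges::resize(
    cgi, GenomicRanges::width(cgi) + 2L * shore_width, fix = "center"))
  far <- GenomicRanges::reduce(GenomicRanges::resize(
    cgi, GenomicRanges::width(cgi) + 2L * (shore_width + shelf_width),
    fix = "center"))
  shore <- GenomicRanges::setdiff(near, cgi)
  shelf <- GenomicRanges::setdiff(far, near)
  GenomicRanges::start(shore) <- pmax(1L, GenomicRanges::start(shore))
  GenomicRanges::start(shelf) <- pmax(1L, GenomicRanges::start(shelf))
  list(shore = shore, shelf = shelf)
}

#' Structural feature matrix for a set of CpG sites
#'
#' One column per track, in manifest order. Binary tracks contribute 1 when
#' the site lies inside any interval, 0 otherwise. Score tracks contribute
#' the score covering the position, or `NA` where the track is undefined —
#' boosted trees handle missing values natively and 0 would be a meaningful
#' score.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based).
#' @param tracks A [track_set()].
#' @return Numeric matrix, one row per site, columns named `str_<track>`.
#' @export
structural_feature_matrix <- function(sites, tracks) {
  stopifnot(inherits(tracks, "track_set"))
  sites <- as.data.table(sites)
  q <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, sites$pos))
  out <- matrix(NA_real_, nrow(sites), length(tracks),
                dimnames = list(NULL, paste0("str_", names(tracks))))
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]
    if (tr$kind == "binary_intervals") {
      out[, i] <- as.numeric(GenomicRanges::countOverlaps(q, tr$gr) > 0L)
    } else {
      hits <- GenomicRanges::findOverlaps(q, tr$gr, select = "first")
      out[, i] <- S4Vectors::mcols(tr$gr)$score[hits]
    }
  }
  out
}

#' Structural feature vector for a single site
#' @param chrom,pos Site coordinates (1-based).
#' @param tracks A [track_set()].
#' @return Named numeric vector of length `length(tracks)`.
#' @export
structural_vector <- function(chrom, pos, tracks) {
  structural_feature_matrix(data.frame(chrom = chrom, pos = pos), tracks)[1L, ]
}
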