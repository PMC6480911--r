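#' Load a reference genome from FASTA
#'
#' @param path Path to a (possibly gzipped) FASTA file.
#' @return A named uppercase character vector, one element per chromosome.
#'   Sequence names are truncated at the first whitespace, matching common
#'   FASTA header usage.
#' @export
read_genome <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(dss))
  names(seqs) <- sub("\\s.*$", "", names(dss))
  seqs
}

#' Write a genome as FASTA
#' @param genome Named character vector of chromosome sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  dss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(dss, path, width = 70L)
  invisible(path)
}

#' Extract the fixed-width sequence window around a CpG site
#'
#' The window is centered on the C of the CpG dinucleotide and spans
#' `flank` bases on each side (default 50, i.e. a 101-bp window). Windows
#' running past a chromosome end are padded with `N` so that every window has
#' length `2 * flank + 1`.
#'
#' @param genome Named character vector from [read_genome()].
#' @param chrom Chromosome name.
#' @param pos 1-based position (vectorized).
#' @param flank Number of bases on each side of the site.
#' @return Character vector of windows, all of length `2 * flank + 1`.
#' @export
extract_window <- function(genome, chrom, pos, flank = 50L) {
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  if (any(pos < 1L)) stop("positions must be >= 1")
  seq <- genome[[chrom]]
  len <- nchar(seq)
  start <- pos - flank
  end <- pos + flank
  left_pad <- pmax(0L, 1L - start)
  right_pad <- pmax(0L, end - len)
  core <- substring(seq, pmax(start, 1L), pmin(end, len))
  core[pmax(start, 1L) > pmin(end, len)] <- ""
  paste0(strrep("N", left_pad), core, strrep("N", right_pad))
}

ngram_alphabet <- function(n) {
  do.call(paste0, rev(expand.grid(rep(list(c("A", "C", "G", "T")), n),
                                  stringsAsFactors = FALSE)))
}

ngram_colnames <- function(n_set = 1:3) {
  unlist(lapply(sort(n_set), function(n) paste0("seq_", sort(ngram_alphabet(n)))))
}

#' n-gram frequency features of DNA windows
#'
#' For each n in `n_set`, every n-mer over \{A,C,G,T\} becomes one feature
#' whose value is the count of its overlapping occurrences divided by
#' `L - (n - 1)`, the number of length-n windows in a sequence of length L.
#' With `n_set = 1:3` this yields 4 + 16 + 64 = 84 features. Windows that
#' contain an ambiguous base (N) count toward no n-mer while the denominator
#' stays nominal, so feature scale is constant across sites, including
#' N-padded windows at chromosome ends.
#'
#' @param seqs Character vector of DNA sequences (uppercase A/C/G/T/N).
#' @param n_set Integer set of n-gram orders; default `1:3`.
#' @return A numeric matrix, one row per sequence, columns named
#'   `seq_<mer>` in lexicographic order within each n.
#' @export
ngram_features <- function(seqs, n_set = 1:3) {
  stopifnot(length(seqs) >= 1L, all(nzchar(seqs)))
  n_set <- sort(unique(as.integer(n_set)))
  L <- nchar(seqs)
  if (length(unique(L)) != 1L)
    stop("all sequences must have equal length")
  L <- L[1L]
  if (any(L - (n_set - 1L) <= 0L))
    stop("sequence length ", L, " too short for n = ", max(n_set))
  dss <- Biostrings::DNAStringSet(seqs)
  blocks <- lapply(n_set, function(n) {
    counts <- Biostrings::oligonucleotideFrequency(dss, width = n)
    counts / (L - (n - 1L))
  })
  out <- do.call(cbind, blocks)
  colnames(out) <- ngram_colnames(n_set)
  out
}

#' Sequence feature matrix for a set of CpG sites
#'
#' Convenience wrapper: extracts the window around every site and computes
#' its n-gram features.
#'
#' @param genome Named character vector from [read_genome()].
#' @param sites data.frame with columns `chrom`, `pos` (1-based).
#' @param flank Window half-width (default 50).
#' @param n_set n-gram orders (default `1:3`, 84 features).
#' @return Numeric matrix, one row per site.
#' @export
sequence_feature_matrix <- function(genome, sites, flank = 50L, n_set = 1:3) {
  sites <- as.data.table(sites)
  out <- matrix(NA_real_, nrow(sites), length(ngram_colnames(n_set)),
                dimnames = list(NULL, ngram_colnames(n_set)))
  for (cr in unique(sites$chrom)) {
    idx <- which(sites$chrom == cr)
    win <- extract_window(genome, cr, sites$pos[idx], flank = flank)
    out[idx, ] <- ngram_features(win, n_set = n_set)
  }
  out
}
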