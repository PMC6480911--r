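# Fixture builders and independent oracles shared across test files.
# Oracles are deliberately naive (linear scans, brute-force counting) and
# never call the code paths they check.

suppressMessages({
  library(data.table)
  library(GenomicRanges)
})

# profile from a compact (pos, state) spec on one chromosome
mk_profile <- function(cell_id, pos, state, chrom = "chr1") {
  cell_profile(cell_id, data.frame(chrom = chrom, pos = pos, state = state))
}

# random labeled profile across chroms
random_profile <- function(cell_id, n = 200, chroms = c("chr1", "chr2"),
                           span = 1e5) {
  sites <- rbindlist(lapply(chroms, function(cr) {
    pos <- sort(sample.int(span, n))
    data.table(chrom = cr, pos = pos,
               total_reads = 4L + rpois(n, 6),
               meth_reads = 0L)
  }))
  sites[, meth_reads := rbinom(.N, total_reads, 0.4)]
  cell_profile(cell_id, sites)
}

random_dataset <- function(m = 5, n = 200, span = 1e5) {
  multicell_dataset(lapply(seq_len(m), function(i)
    random_profile(sprintf("c%02d", i), n = n, span = span)))
}

# brute-force n-gram frequency scanner (independent of Biostrings)
oracle_ngram <- function(seq, n_set = 1:3) {
  L <- nchar(seq)
  out <- numeric(0)
  for (n in sort(n_set)) {
    mers <- sort(do.call(paste0, rev(expand.grid(
      rep(list(c("A", "C", "G", "T")), n), stringsAsFactors = FALSE))))
    counts <- setNames(numeric(length(mers)), mers)
    for (i in seq_len(L - n + 1)) {
      w <- substr(seq, i, i + n - 1)
      if (w %in% mers) counts[w] <- counts[w] + 1
    }
    out <- c(out, counts / (L - (n - 1)))
  }
  unname(out)
}

# naive interval membership: is pos inside any [start, end] (1-based closed)?
oracle_member <- function(pos, starts, ends) {
  vapply(pos, function(p) any(p >= starts & p <= ends), logical(1))
}

# linear-scan k-th neighbour on labeled (pos, state) pairs
oracle_neighbors <- function(pos_v, state_v, q, k) {
  left <- order(q - pos_v)          # not used; explicit scans below
  lp <- pos_v[pos_v < q]; ls <- state_v[pos_v < q]
  rp <- pos_v[pos_v > q]; rs <- state_v[pos_v > q]
  lo <- order(q - lp); ro <- order(rp - q)
  c(left_pos = if (k <= length(lp)) lp[lo][k] else NA_real_,
    left_state = if (k <= length(lp)) ls[lo][k] else NA_real_,
    right_pos = if (k <= length(rp)) rp[ro][k] else NA_real_,
    right_state = if (k <= length(rp)) rs[ro][k] else NA_real_)
}

# pairwise-comparison AUC: P(score+ > score-) + 0.5 P(tie)
oracle_auc <- function(labels, scores) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# random sparse non-negative integer matrix for EFB tests
random_sparse_int <- function(nrow = 60, ncol = 12, density = 0.15,
                              max_val = 5) {
  x <- matrix(0, nrow, ncol)
  nz <- matrix(runif(nrow * ncol) < density, nrow, ncol)
  x[nz] <- sample.int(max_val, sum(nz), replace = TRUE)
  colnames(x) <- sprintf("f%02d", seq_len(ncol))
  x
}

# small cached simulated study for pipeline tests (built once per run)
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_study(sim_config(m = 4, n_chrom = 2,
                                          chrom_len = 2e5, seed = 42))
    cache
  }
})
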