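# Positional features: methylation states and base-pair distances of
# neighbouring CpG sites, within the target cell and across the other cells
# of the dataset. Distances are signed offsets exactly as defined
# (upstream negative); missing neighbours (chromosome boundary, position
# absent, cell without sites) are encoded as NA, never as sentinels.

labeled_chrom <- function(profile, chr) {
  s <- profile$sites[chrom == chr & !is.na(state)]
  list(pos = s$pos, state = s$state)
}

# v[i] with NA for out-of-range or NA indices
idx_get <- function(v, i) {
  out <- rep(NA_real_, length(i))
  ok <- !is.na(i) & i >= 1L & i <= length(v)
  out[ok] <- v[i[ok]]
  out
}

#' k-th nearest labeled neighbours of a position
#'
#' Finds the k-th nearest site with a known state strictly upstream and
#' strictly downstream of `pos` in one cell's profile. A site located exactly
#' at `pos` is never its own neighbour. Sides without a k-th site yield `NA`.
#'
#' @param profile A [cell_profile()].
#' @param chrom Chromosome name.
#' @param pos 1-based query position(s); vectorized.
#' @param k Neighbour rank (k = 1 is the nearest site on each side).
#' @return data.frame with columns `left_pos`, `left_state`, `right_pos`,
#'   `right_state`, one row per query.
#' @export
neighbors <- function(profile, chrom, pos, k = 1L) {
  stopifnot(k >= 1L)
  lc <- labeled_chrom(profile, chrom)
  p <- lc$pos; s <- lc$state
  idx <- findInterval(pos, p)
  present <- idx >= 1L & idx_get(p, idx) == pos
  present[is.na(present)] <- FALSE
  n_left <- idx - as.integer(present)        # count of sites strictly left
  li <- n_left - k + 1L
  ri <- idx + k                              # first strictly-right index is idx+1
  data.frame(left_pos = idx_get(p, li), left_state = idx_get(s, li),
             right_pos = idx_get(p, ri), right_state = idx_get(s, ri))
}

#' Flanking-neighbour feature block of one cell for a target site
#'
#' For target site (cell i, chrom, pos), the block from cell j holds the
#' signed distances and states of the sites flanking the target position in
#' cell j. When the position itself is a labeled site of cell j at index l,
#' the flanks are the (l-1)-th and (l+1)-th sites, so the target's own state
#' never enters its feature vector even for j = i. When the position is
#' absent from cell j, the flanks are the nearest labeled sites on each side.
#'
#' @param dataset A [multicell_dataset()].
#' @param cell_i,cell_j Cell ids (j may equal i).
#' @param chrom Chromosome.
#' @param pos Query position(s), vectorized.
#' @return Numeric matrix with 4 columns: `P_left`, `S_left`, `P_right`,
#'   `S_right` (distances signed, upstream negative).
#' @export
feature_F <- function(dataset, cell_i, cell_j, chrom, pos) {
  lc <- labeled_chrom(dataset$cells[[cell_j]], chrom)
  p <- lc$pos; s <- lc$state
  idx <- findInterval(pos, p)
  present <- idx >= 1L & idx_get(p, idx) == pos
  present[is.na(present)] <- FALSE
  li <- ifelse(present, idx - 1L, idx)
  li[li < 1L] <- NA_integer_
  ri <- idx + 1L
  cbind(P_left = idx_get(p, li) - pos, S_left = idx_get(s, li),
        P_right = idx_get(p, ri) - pos, S_right = idx_get(s, ri))
}

#' Consecutive-gap feature block of another cell for a target site
#'
#' The 8-value block from cell j (j != i) describes the local CpG spacing
#' and states around the target position in cell j: consecutive inter-site
#' distances and the states at their endpoints. With the position present in
#' cell j at index l the block is
#' (p^{l-1}-p^{l-2}, s^{l-2}, p^l-p^{l-1}, s^l, p^{l+1}-p^l, s^l,
#'  p^{l+2}-p^{l+1}, s^{l+2}); with the position absent and l the nearest
#' site upstream it is
#' (p^l-p^{l-1}, s^{l-1}, p^{l+1}-p^l, s^{l+1}, p^{l+1}-p^l, s^l,
#'  p^{l+2}-p^{l+1}, s^{l+2}) — the duplicated gap is kept verbatim so the
#' block width is constant. Out-of-range indices give NA. For j = i the
#' block would contain the target's own state, so it is an error.
#'
#' @param dataset A [multicell_dataset()].
#' @param cell_i Target cell id.
#' @param cell_j Source cell id, must differ from `cell_i`.
#' @param chrom Chromosome.
#' @param pos Query position(s), vectorized.
#' @return Numeric matrix with 8 columns `P1,S1,P2,S2,P3,S3,P4,S4`.
#' @export
feature_D <- function(dataset, cell_i, cell_j, chrom, pos) {
  if (identical(cell_i, cell_j))
    stop("feature_D requires different cells: the i = j block would leak ",
         "the target site's own state")
  lc <- labeled_chrom(dataset$cells[[cell_j]], chrom)
  p <- lc$pos; s <- lc$state
  idx <- findInterval(pos, p)
  present <- idx >= 1L & idx_get(p, idx) == pos
  present[is.na(present)] <- FALSE
  l <- idx
  gap <- function(a, b) idx_get(p, b) - idx_get(p, a)
  out <- matrix(NA_real_, length(pos), 8L,
                dimnames = list(NULL, c("P1", "S1", "P2", "S2",
                                        "P3", "S3", "P4", "S4")))
  pr <- present
  if (any(pr)) {
    lp <- l[pr]
    out[pr, ] <- cbind(gap(lp - 2L, lp - 1L), idx_get(s, lp - 2L),
                       gap(lp - 1L, lp),      idx_get(s, lp),
                       gap(lp, lp + 1L),      idx_get(s, lp),
                       gap(lp + 1L, lp + 2L), idx_get(s, lp + 2L))
  }
  if (any(!pr)) {
    la <- l[!pr]
    out[!pr, ] <- cbind(gap(la - 1L, la), idx_get(s, la - 1L),
                        gap(la, la + 1L), idx_get(s, la + 1L),
                        gap(la, la + 1L), idx_get(s, la),
                        gap(la + 1L, la + 2L), idx_get(s, la + 2L))
  }
  out
}

#' Full cross-cell positional feature block for target sites
#'
#' Concatenates the flanking blocks ([feature_F()], 4 values per cell, all m
#' cells, target cell first then the others in lexicographic id order) and
#' the consecutive-gap blocks ([feature_D()], 8 values per non-target cell),
#' for a total of `4m + 8(m - 1)` features — e.g. 292 for m = 25.
#'
#' @param dataset A [multicell_dataset()].
#' @param cell Target cell id.
#' @param chrom Chromosome.
#' @param pos Query position(s), vectorized.
#' @return Numeric matrix with `4m + 8(m-1)` named columns
#'   (`pos_F_<cell>_*`, then `pos_D_<cell>_*`).
#' @export
positional_vector <- function(dataset, cell, chrom, pos) {
  ids <- names(dataset$cells)
  if (!cell %in% ids) stop("unknown cell: ", cell)
  others <- setdiff(ids, cell)       # already lexicographic
  f_order <- c(cell, others)
  fb <- lapply(f_order, function(j) {
    b <- feature_F(dataset, cell, j, chrom, pos)
    colnames(b) <- paste0("pos_F_", j, "_", colnames(b))
    b
  })
  db <- lapply(others, function(j) {
    b <- feature_D(dataset, cell, j, chrom, pos)
    colnames(b) <- paste0("pos_D_", j, "_", colnames(b))
    b
  })
  do.call(cbind, c(fb, db))
}

#' Positional feature matrix for a table of sites
#'
#' @param dataset A [multicell_dataset()].
#' @param cell Target cell id.
#' @param sites data.frame with columns `chrom`, `pos`.
#' @return Numeric matrix, one row per site, `4m + 8(m-1)` columns.
#' @export
positional_feature_matrix <- function(dataset, cell, sites) {
  sites <- as.data.table(sites)
  m <- n_cells(dataset)
  ncol_out <- 4L * m + 8L * (m - 1L)
  out <- NULL
  for (cr in unique(sites$chrom)) {
    idx <- which(sites$chrom == cr)
    block <- positional_vector(dataset, cell, cr, sites$pos[idx])
    if (is.null(out))
      out <- matrix(NA_real_, nrow(sites), ncol_out,
                    dimnames = list(NULL, colnames(block)))
    out[idx, ] <- block
  }
  out
}

#' Skip-k neighbourhood features within one cell
#'
#' Two analyses of how neighbour information decays with distance:
#' `rank_pair` (skip-k1) takes the single k1-th nearest labeled site on each
#' side — 2 states + 2 signed distances; `window` (skip-k2) takes all ranks
#' 1..k2 on each side — 2*k2 states + 2*k2 distances. `window` with k2 = 1
#' equals `rank_pair` with k1 = 1. The target position itself is never its
#' own neighbour.
#'
#' @param profile A [cell_profile()].
#' @param chrom Chromosome.
#' @param pos Query position(s), vectorized.
#' @param k1 Neighbour rank for `rank_pair` mode.
#' @param k2 Window width for `window` mode.
#' @param mode `"rank_pair"` or `"window"`.
#' @return Numeric matrix; 4 columns for `rank_pair`, `4*k2` for `window`.
#' @export
skip_k_features <- function(profile, chrom, pos, k1 = 1L, k2 = 1L,
                            mode = c("rank_pair", "window")) {
  mode <- match.arg(mode)
  ranks <- if (mode == "rank_pair") k1 else seq_len(k2)
  blocks <- lapply(ranks, function(k) {
    nb <- neighbors(profile, chrom, pos, k = k)
    cbind(nb$left_pos - pos, nb$left_state,
          nb$right_pos - pos, nb$right_state)
  })
  left <- do.call(cbind, lapply(blocks, function(b) b[, 1:2, drop = FALSE]))
  right <- do.call(cbind, lapply(blocks, function(b) b[, 3:4, drop = FALSE]))
  out <- cbind(left, right)
  colnames(out) <- c(paste0("skip_L", rep(ranks, each = 2), c("_P", "_S")),
                     paste0("skip_R", rep(ranks, each = 2), c("_P", "_S")))
  out
}
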