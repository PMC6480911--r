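two_cell <- function(pos_a, st_a, pos_b, st_b) {
  multicell_dataset(list(mk_profile("a", pos_a, st_a),
                         mk_profile("b", pos_b, st_b)))
}

test_that("neighbors excludes the query site and encodes missing sides", {
  p <- mk_profile("a", c(10, 30), c(1, 0))
  nb <- neighbors(p, "chr1", 20, k = 1)
  expect_equal(unlist(nb), c(left_pos = 10, left_state = 1,
                             right_pos = 30, right_state = 0))
  # a site exactly at the query position is never its own neighbour
  p2 <- mk_profile("a", c(10, 20, 30), c(1, 1, 0))
  nb2 <- neighbors(p2, "chr1", 20, k = 1)
  expect_equal(unlist(nb2), c(left_pos = 10, left_state = 1,
                              right_pos = 30, right_state = 0))
  nb3 <- neighbors(p2, "chr1", 5, k = 1)
  expect_true(is.na(nb3$left_pos) && is.na(nb3$left_state))
  expect_equal(nb3$right_pos, 10)
})

test_that("neighbors matches a linear-scan oracle for all ranks up to 5", {
  set.seed(31)
  pos <- sort(sample.int(5e4, 1000))
  st <- rbinom(1000, 1, 0.5)
  p <- mk_profile("a", pos, st)
  q <- sample.int(5e4, 300)
  for (k in 1:5) {
    got <- neighbors(p, "chr1", q, k = k)
    want <- t(vapply(q, function(x) oracle_neighbors(pos, st, x, k),
                     numeric(4)))
    expect_equal(unname(as.matrix(got)), unname(want), info = paste("k =", k))
  }
})

test_that("flanking block handles present and absent target positions", {
  # absent in the other cell: nearest flanks with signed distances
  ds <- two_cell(20, 1, c(10, 30), c(1, 0))
  f <- feature_F(ds, "a", "b", "chr1", 20)
  expect_equal(unname(f[1, ]), c(-10, 1, 10, 0))

  # present at index l: flanks are l-1 and l+1, own state at l unused
  ds2 <- two_cell(20, 1, c(5, 20, 40), c(1, 0, 1))
  f2 <- feature_F(ds2, "a", "b", "chr1", 20)
  expect_equal(unname(f2[1, ]), c(-15, 1, 20, 1))

  # same-cell block also excludes the target's own state
  f3 <- feature_F(ds2, "b", "b", "chr1", 20)
  expect_equal(unname(f3[1, ]), c(-15, 1, 20, 1))

  # chromosome boundary: missing side encoded as NA
  f4 <- feature_F(ds, "a", "b", "chr1", 5)
  expect_true(all(is.na(f4[1, 1:2])))
  expect_equal(unname(f4[1, 3:4]), c(5, 1))
})

test_that("consecutive-gap block matches the defining arithmetic", {
  # target position present in the other cell
  ds <- two_cell(20, 1, c(5, 10, 20, 40, 50), c(1, 0, 0, 1, 0))
  d <- feature_D(ds, "a", "b", "chr1", 20)
  expect_equal(unname(d[1, ]), c(5, 1, 10, 0, 20, 0, 10, 0))

  # target position absent: duplicated middle gap kept verbatim
  ds2 <- two_cell(20, 1, c(5, 10, 40, 50), c(1, 0, 1, 0))
  d2 <- feature_D(ds2, "a", "b", "chr1", 20)
  expect_equal(unname(d2[1, ]), c(5, 1, 30, 1, 30, 0, 10, 0))

  # out-of-range indices give NA
  d3 <- feature_D(ds2, "a", "b", "chr1", 7)
  expect_true(is.na(d3[1, "P1"]) && is.na(d3[1, "S1"]))

  # the same-cell block would leak the target's own state
  expect_error(feature_D(ds, "a", "a", "chr1", 20), "leak")
})

test_that("positional vector length is 4m + 8(m-1) for m in 1..30", {
  for (m in c(1, 2, 3, 6, 25, 30)) {
    ds <- multicell_dataset(lapply(seq_len(m), function(i)
      mk_profile(sprintf("c%02d", i), c(10, 50, 90), c(1, 0, 1))))
    v <- positional_vector(ds, "c01", "chr1", 50)
    expect_equal(ncol(v), 4 * m + 8 * (m - 1), info = paste("m =", m))
    expect_equal(anyDuplicated(colnames(v)), 0L)
  }
})

test_that("single-cell dataset yields only the four same-cell flank features", {
  ds <- multicell_dataset(list(mk_profile("solo", c(10, 50, 90), c(1, 0, 1))))
  v <- positional_vector(ds, "solo", "chr1", 50)
  expect_equal(ncol(v), 4L)
  expect_equal(unname(v[1, ]), c(-40, 1, 40, 1))
})

test_that("batch positional matrix equals per-site extraction on simulated data", {
  study <- small_study()
  ds <- study$dataset
  cell <- names(ds$cells)[2]
  sites <- ds$cells[[cell]]$sites[!is.na(state)][seq_len(200)]
  batch <- positional_feature_matrix(ds, cell, sites)
  one_by_one <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i)
    positional_vector(ds, cell, sites$chrom[i], sites$pos[i])))
  expect_equal(batch, one_by_one)
})

test_that("no feature of a site encodes its own label", {
  set.seed(33)
  ds <- random_dataset(m = 3, n = 300, span = 3e4)
  cell <- names(ds$cells)[1]
  lab <- which(!is.na(ds$cells[[cell]]$sites$state))
  pick <- sample(lab, min(50, length(lab)))
  sites <- ds$cells[[cell]]$sites[pick]
  before <- positional_feature_matrix(ds, cell, sites)
  flipped <- ds
  flipped$cells[[cell]]$sites <- copy(ds$cells[[cell]]$sites)
  flipped$cells[[cell]]$sites[pick, state := 1L - state]
  after <- positional_feature_matrix(flipped, cell, sites)
  # each row's features are computed with its own (flipped) label invisible;
  # rows must match when only that row's label changed — flip one at a time
  for (i in seq_len(10)) {
    one <- ds
    one$cells[[cell]]$sites <- copy(ds$cells[[cell]]$sites)
    one$cells[[cell]]$sites[pick[i], state := 1L - state]
    row_i <- positional_feature_matrix(one, cell, sites[i])
    expect_equal(row_i[1, ], before[i, ], info = paste("site", i))
  }
  # sanity: flipping *other* sites does change features (signal is real)
  expect_false(identical(before, after))
})

test_that("translating all positions leaves distance components unchanged", {
  set.seed(34)
  ds <- random_dataset(m = 3, n = 100, span = 2e4)
  cell <- names(ds$cells)[1]
  sites <- ds$cells[[cell]]$sites[!is.na(state)][1:30]
  v1 <- positional_feature_matrix(ds, cell, sites)
  shift <- 7919L
  ds2 <- ds
  for (id in names(ds2$cells)) {
    ds2$cells[[id]]$sites <- copy(ds$cells[[id]]$sites)
    ds2$cells[[id]]$sites[, pos := pos + shift]
  }
  sites2 <- copy(sites)[, pos := pos + shift]
  v2 <- positional_feature_matrix(ds2, cell, sites2)
  expect_equal(v1, v2)
})

test_that("skip-k features follow rank and window contracts", {
  p <- mk_profile("a", c(10, 20, 40, 80), c(1, 0, 0, 1))
  # window k2=1 is definitionally rank_pair k1=1
  w1 <- skip_k_features(p, "chr1", 40, k2 = 1, mode = "window")
  r1 <- skip_k_features(p, "chr1", 40, k1 = 1, mode = "rank_pair")
  expect_equal(unname(w1), unname(r1))

  w2 <- skip_k_features(p, "chr1", 40, k2 = 2, mode = "window")
  expect_equal(ncol(w2), 8L)
  expect_equal(unname(w2[1, c("skip_L1_P", "skip_L1_S")]), c(-20, 0))
  expect_equal(unname(w2[1, c("skip_L2_P", "skip_L2_S")]), c(-30, 1))
  expect_equal(unname(w2[1, c("skip_R1_P", "skip_R1_S")]), c(40, 1))
  expect_true(all(is.na(w2[1, c("skip_R2_P", "skip_R2_S")])))
})

test_that("skip-k features match the neighbour oracle on a simulated chromosome", {
  set.seed(35)
  pos <- sort(sample.int(3e4, 400))
  st <- rbinom(400, 1, 0.5)
  p <- mk_profile("a", pos, st)
  q <- sample.int(3e4, 100)
  for (k in c(1, 3)) {
    got <- skip_k_features(p, "chr1", q, k1 = k, mode = "rank_pair")
    want <- t(vapply(q, function(x) {
      o <- oracle_neighbors(pos, st, x, k)
      c(o["left_pos"] - x, o["left_state"], o["right_pos"] - x,
        o["right_state"])
    }, numeric(4)))
    expect_equal(unname(got), unname(want))
  }
})
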