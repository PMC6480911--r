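#' Simulation configuration for sparse multi-cell methylomes
#'
#' The generator emulates the statistical regime of single-cell bisulfite
#' data: a shared latent methylation landscape that is spatially correlated
#' along the chromosome, per-cell deviations from it (partial cross-cell
#' concordance), sparse per-cell observation (1-40% of sites covered in real
#' scRRBS/scBS-seq; default 30%), and read counts whose depth filter leaves
#' a genuinely excluded fraction.
#'
#' @param m Number of cells (default 5).
#' @param n_chrom Number of chromosomes (default 2, named chr1, chr2, ...).
#' @param chrom_len Chromosome length in bp (default 1e6).
#' @param mean_gap Mean spacing between planted CpG sites in bp (geometric;
#'   default 100, roughly the genome-wide CpG density).
#' @param switch_per_bp Per-bp switching rate of the latent two-state
#'   methylation chain; the state flip probability over a gap of g bp is
#'   `(1 - (1 - 2q)^g) / 2`, so correlation decays on a `1/(2q)` bp scale
#'   (default 1e-3, ~500 bp).
#' @param concordance Probability that a cell copies the latent state at a
#'   site (otherwise it flips); in \[0.5, 1\], default 0.9.
#' @param coverage Per-cell per-site observation probability (default 0.3).
#' @param depth_mean Mean total read depth; depths are `1 + Poisson(mean-1)`
#'   so the >= 4 read filter excludes a real fraction of sites (default 10).
#' @param read_error Per-read probability of reporting the wrong state
#'   (default 0.05).
#' @param seed Integer master seed; every component derives its own stream.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(m = 5L, n_chrom = 2L, chrom_len = 1e6, mean_gap = 100,
                       switch_per_bp = 1e-3, concordance = 0.9,
                       coverage = 0.3, depth_mean = 10, read_error = 0.05,
                       seed = 1L) {
  stopifnot(m >= 1L, n_chrom >= 1L, chrom_len >= 100, mean_gap >= 2,
            switch_per_bp >= 0, switch_per_bp <= 0.5,
            concordance >= 0.5, concordance <= 1,
            coverage > 0, coverage <= 1, depth_mean >= 1,
            read_error >= 0, read_error < 0.5)
  structure(list(m = as.integer(m), n_chrom = as.integer(n_chrom),
                 chrom_len = as.integer(chrom_len), mean_gap = mean_gap,
                 switch_per_bp = switch_per_bp, concordance = concordance,
                 coverage = coverage, depth_mean = depth_mean,
                 read_error = read_error, seed = as.integer(seed)),
            class = "sim_config")
}

# destroy accidental CG dinucleotides in a background sequence
scrub_cg <- function(chars) {
  is_cg <- which(chars[-length(chars)] == "C" & chars[-1L] == "G")
  while (length(is_cg)) {
    chars[is_cg + 1L] <- "A"
    is_cg <- which(chars[-length(chars)] == "C" & chars[-1L] == "G")
  }
  chars
}

#' Simulate a genome with planted CpG sites
#'
#' Random A/C/G/T background with CG dinucleotides planted at
#' geometric-spaced positions; accidental background CGs are removed so the
#' returned positions are exactly the genome's CpG sites.
#'
#' @param cfg A [sim_config()].
#' @return List with `genome` (named character vector, one element per
#'   chromosome) and `positions` (named list of integer vectors, the 1-based
#'   C positions).
#' @export
simulate_genome <- function(cfg) {
  set.seed(cfg$seed)
  genome <- character(cfg$n_chrom)
  positions <- vector("list", cfg$n_chrom)
  names(genome) <- names(positions) <- paste0("chr", seq_len(cfg$n_chrom))
  p_gap <- 1 / (cfg$mean_gap - 1)          # gap = 2 + Geom(p): mean = mean_gap
  for (k in seq_len(cfg$n_chrom)) {
    chars <- sample(c("A", "C", "G", "T"), cfg$chrom_len, replace = TRUE)
    chars <- scrub_cg(chars)
    n_max <- ceiling(cfg$chrom_len / cfg$mean_gap * 1.5) + 100L
    gaps <- 2L + rgeom(n_max, p_gap)
    pos <- 1L + cumsum(gaps)
    pos <- pos[pos + 1L <= cfg$chrom_len]
    chars[pos] <- "C"
    chars[pos + 1L] <- "G"
    genome[k] <- paste(chars, collapse = "")
    positions[[k]] <- pos
  }
  list(genome = genome, positions = positions)
}

# latent two-state path over ordered positions; flip prob over gap g is
# (1 - (1-2q)^g)/2, the g-step transition of a symmetric chain with per-bp
# switch rate q
latent_path <- function(pos, q) {
  n <- length(pos)
  s <- integer(n)
  s[1L] <- rbinom(1L, 1L, 0.5)
  if (n > 1L) {
    pflip <- (1 - (1 - 2 * q)^diff(pos)) / 2
    flips <- rbinom(n - 1L, 1L, pflip)
    s <- c(s[1L], (s[1L] + cumsum(flips)) %% 2L)
  }
  s
}

#' Simulate sparse multi-cell CpG profiles
#'
#' A latent binary state path is drawn over the CpG positions of each
#' chromosome (symmetric two-state Markov chain in genomic distance); each
#' cell copies the latent state with probability `concordance` and flips it
#' otherwise; each (cell, site) pair is observed with probability
#' `coverage`; observed sites receive `1 + Poisson(depth_mean - 1)` total
#' reads and binomial methylated-read counts with error rate `read_error`.
#'
#' @param cfg A [sim_config()].
#' @param positions Named list of per-chromosome CpG position vectors, from
#'   [simulate_genome()].
#' @return A [multicell_dataset()] with read counts and binarized states;
#'   the latent paths are attached as `attr(, "latent")` (a named list).
#' @export
simulate_profiles <- function(cfg, positions) {
  set.seed(cfg$seed + 1L)
  latent <- lapply(positions, latent_path, q = cfg$switch_per_bp)
  cells <- lapply(seq_len(cfg$m), function(i) {
    recs <- lapply(names(positions), function(cr) {
      pos <- positions[[cr]]
      lat <- latent[[cr]]
      true <- ifelse(runif(length(pos)) < cfg$concordance, lat, 1L - lat)
      obs <- runif(length(pos)) < cfg$coverage
      pos <- pos[obs]; true <- true[obs]
      total <- 1L + rpois(length(pos), cfg$depth_mean - 1)
      p_meth <- ifelse(true == 1L, 1 - cfg$read_error, cfg$read_error)
      meth <- rbinom(length(pos), total, p_meth)
      data.table(chrom = cr, pos = pos, meth_reads = meth, total_reads = total)
    })
    cell_profile(sprintf("cell%02d", i), rbindlist(recs))
  })
  ds <- multicell_dataset(cells)
  attr(ds, "latent") <- latent
  ds
}

random_intervals <- function(chroms, chrom_len, n_per_chrom, mean_width) {
  start <- unlist(lapply(chroms, function(cr)
    sort(sample.int(chrom_len - mean_width * 2L, n_per_chrom))))
  width <- pmax(50L, as.integer(rpois(length(start), mean_width)))
  GenomicRanges::reduce(GenomicRanges::GRanges(
    rep(chroms, each = n_per_chrom),
    IRanges::IRanges(start, pmin(start + width, chrom_len))))
}

#' Simulate the full annotation track manifest
#'
#' Emits the conventional 175-track set: CGI/shore/shelf, `n_tfbs` TFBS
#' tracks, `n_chromstate` chromatin-state tracks, `n_histone` histone-mark
#' tracks and DHS as binary interval tracks, plus iHS and constraint as
#' score tracks. When latent states are supplied and `enrichment > 0`, CGI
#' intervals are preferentially placed over runs of unmethylated latent
#' state (CpG islands are hypomethylated in real genomes), so the CGI
#' feature carries signal; `enrichment = 0` places all tracks independently
#' of the states.
#'
#' @param cfg A [sim_config()].
#' @param positions Named per-chromosome CpG position list.
#' @param latent Named per-chromosome latent state list (from
#'   [simulate_profiles()]), or `NULL`.
#' @param enrichment Probability of converting an unmethylated run into a
#'   CGI interval (default 0.8).
#' @param n_tfbs,n_chromstate,n_histone Track counts per class (defaults
#'   144, 15, 10).
#' @return A [track_set()] of length `6 + n_tfbs + n_chromstate + n_histone`
#'   (175 with defaults).
#' @export
simulate_tracks <- function(cfg, positions, latent = NULL, enrichment = 0.8,
                            n_tfbs = 144L, n_chromstate = 15L,
                            n_histone = 10L) {
  set.seed(cfg$seed + 2L)
  chroms <- names(positions)
  cgi <- if (!is.null(latent) && enrichment > 0) {
    parts <- lapply(chroms, function(cr) {
      r <- rle(latent[[cr]])
      ends_i <- cumsum(r$lengths)
      starts_i <- ends_i - r$lengths + 1L
      keep <- r$values == 0L & r$lengths >= 5L
      keep <- keep & runif(length(keep)) < enrichment
      data.frame(chrom = rep(cr, sum(keep)),
                 start = pmax(1L, positions[[cr]][starts_i[keep]] - 100L),
                 end = pmin(cfg$chrom_len, positions[[cr]][ends_i[keep]] + 100L))
    })
    df <- do.call(rbind, parts)
    GenomicRanges::reduce(GenomicRanges::GRanges(
      df$chrom, IRanges::IRanges(df$start, df$end)))
  } else {
    random_intervals(chroms, cfg$chrom_len,
                     max(2L, cfg$chrom_len %/% 50000L), 1000L)
  }
  ss <- derive_shores_shelves(cgi)
  tracks <- list(annotation_track("cgi", "binary_intervals", cgi),
                 annotation_track("cgi_shore", "binary_intervals", ss$shore),
                 annotation_track("cgi_shelf", "binary_intervals", ss$shelf))
  rand_binary <- function(name) {
    gr <- random_intervals(chroms, cfg$chrom_len,
                           max(2L, cfg$chrom_len %/% 100000L), 500L)
    annotation_track(name, "binary_intervals", gr)
  }
  tracks <- c(tracks,
              lapply(sprintf("tfbs_%03d", seq_len(n_tfbs)), rand_binary),
              lapply(sprintf("chromstate_%02d", seq_len(n_chromstate)),
                     rand_binary),
              lapply(sprintf("histone_%02d", seq_len(n_histone)), rand_binary),
              list(rand_binary("dhs")))
  rand_scores <- function(name) {
    gr <- random_intervals(chroms, cfg$chrom_len,
                           max(2L, cfg$chrom_len %/% 20000L), 2000L)
    S4Vectors::mcols(gr)$score <- round(stats::rnorm(length(gr)), 4)
    annotation_track(name, "position_scores", gr)
  }
  tracks <- c(tracks, list(rand_scores("ihs"), rand_scores("constraint")))
  track_set(tracks)
}

#' Simulate a complete study fixture
#'
#' Genome, profiles and tracks from one config and seed.
#'
#' @param cfg A [sim_config()].
#' @param enrichment CGI/state association knob for [simulate_tracks()].
#' @return List with `genome`, `positions`, `dataset`, `tracks`, `latent`.
#' @export
simulate_study <- function(cfg = sim_config(), enrichment = 0.8) {
  g <- simulate_genome(cfg)
  ds <- simulate_profiles(cfg, g$positions)
  tr <- simulate_tracks(cfg, g$positions, latent = attr(ds, "latent"),
                        enrichment = enrichment)
  list(genome = g$genome, positions = g$positions, dataset = ds,
       tracks = tr, latent = attr(ds, "latent"))
}

#' Write a simulated study to disk
#'
#' Emits `genome.fa`, one `profiles/<cell>.tsv` per cell (counts dialect),
#' `tracks/<name>.bed`/`.bedgraph` and a `tracks/manifest.tsv`, the formats
#' every loader in the package consumes.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(file.path(dir, "profiles"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "tracks"), recursive = TRUE, showWarnings = FALSE)
  write_genome(study$genome, file.path(dir, "genome.fa"))
  for (p in study$dataset$cells)
    write_profile(p, file.path(dir, "profiles", paste0(p$cell_id, ".tsv")))
  man <- data.frame(name = names(study$tracks),
                    kind = vapply(study$tracks, `[[`, character(1), "kind"),
                    path = NA_character_)
  for (i in seq_along(study$tracks)) {
    tr <- study$tracks[[i]]
    ext <- if (tr$kind == "binary_intervals") ".bed" else ".bedgraph"
    man$path[i] <- paste0(tr$name, ext)
    write_track(tr, file.path(dir, "tracks", man$path[i]))
  }
  write.table(man, file.path(dir, "tracks", "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
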