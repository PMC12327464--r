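# Pseudobulk tracks and the aggregation statistics: fixed-width binned
# coverage per (group, target), IgG ratio normalization, genome-wide binned
# Pearson correlation, subsampling saturation curves, per-target median
# depth normalization, and Poisson-threshold binarization.

#' Fixed-width binned coverage track
#'
#' A per-contig vector of values at a fixed bin size (last bin truncated at
#' the contig end). 50-bp bins are the convention for browser-style tracks,
#' 5-kb bins for genome-wide correlations, 200-bp bins for chromatin-state
#' binarization.
#'
#' @param values Named list of numeric vectors, one per contig.
#' @param bin_size Bin width (bp).
#' @param genome_lengths Named contig lengths.
#' @return A `binned_track` object.
#' @export
binned_track <- function(values, bin_size, genome_lengths) {
  stopifnot(is.list(values), all(names(values) == names(genome_lengths)))
  expect <- as.integer(ceiling(genome_lengths / bin_size))
  got <- vapply(values, length, integer(1))
  if (!all(got == expect))
    stop("bin vector lengths do not match ceiling(contig length / bin size)")
  structure(list(values = values, bin_size = as.integer(bin_size),
                 genome_lengths = genome_lengths),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat("binned_track:", length(x$values), "contigs @", x$bin_size, "bp,",
      "total signal", format(track_total(x)), "\n")
  invisible(x)
}

#' @rdname binned_track
#' @param track A `binned_track`.
#' @return `track_total()`: the summed signal; `track_values()`: one
#'   concatenated numeric vector over all contigs.
#' @export
track_total <- function(track) sum(vapply(track$values, sum, numeric(1)))

#' @rdname binned_track
#' @export
track_values <- function(track) unlist(track$values, use.names = FALSE)

# count fragment-bin overlaps into a binned_track
.bin_fragments <- function(fragments, genome_lengths, bin_size) {
  vals <- lapply(names(genome_lengths), function(ct) {
    nb <- as.integer(ceiling(genome_lengths[[ct]] / bin_size))
    fr <- fragments[contig == ct]
    if (!nrow(fr)) return(numeric(nb))
    b0 <- fr$start %/% bin_size
    b1 <- pmin((fr$end - 1L) %/% bin_size, nb - 1L)
    span <- b1 - b0 + 1L
    bins <- sequence(span, from = b0 + 1L)  # 1-based bin index
    as.numeric(tabulate(bins, nbins = nb))
  })
  binned_track(stats::setNames(vals, names(genome_lengths)), bin_size,
               genome_lengths)
}

#' Aggregate single-cell fragments into pseudobulk tracks
#'
#' Sums fragment-bin overlap counts per (group, target). With a single
#' group this is the computational aggregate of all single cells for each
#' target. Optional counts-per-million scaling divides each track by its
#' total fragment-bin count x 1e6 (correlations are scale-invariant, so
#' CPM only matters for ratio displays).
#'
#' @param fragments Fragment table (`contig`, `start`, `end`, `cell_id`,
#'   `target`).
#' @param genome_lengths Named contig lengths.
#' @param bin_size Bin width (default 50 bp).
#' @param groups Optional named vector `cell_id -> group label`; cells
#'   without a group are dropped. Default: one group `"all"`.
#' @param scale `"none"` or `"cpm"`.
#' @return Named list of [binned_track()]s, keys `group.target` (or just
#'   the target when there is a single unnamed group).
#' @export
pseudobulk <- function(fragments, genome_lengths, bin_size = 50L,
                       groups = NULL, scale = c("none", "cpm")) {
  scale <- match.arg(scale)
  fragments <- data.table::as.data.table(fragments)
  if (is.null(groups)) {
    fragments[, group := "all"]
  } else {
    fragments[, group := groups[cell_id]]
    fragments <- fragments[!is.na(group)]
  }
  single <- data.table::uniqueN(fragments$group) <= 1L && is.null(groups)
  out <- list()
  for (key in split(seq_len(nrow(fragments)),
                    paste(fragments$group, fragments$target, sep = "."))) {
    fr <- fragments[key]
    tr <- .bin_fragments(fr, genome_lengths, bin_size)
    if (scale == "cpm") {
      tot <- track_total(tr)
      if (tot > 0)
        tr$values <- lapply(tr$values, function(v) v / tot * 1e6)
    }
    nm <- paste(fr$group[1], fr$target[1], sep = ".")
    if (single) nm <- fr$target[1]
    out[[nm]] <- tr
  }
  out[order(names(out))]
}

#' IgG ratio normalization of a signal track
#'
#' Per-bin linear ratio `(signal + pseudocount) / (control + pseudocount)`,
#' the binned equivalent of a ratio comparison between depth-scaled signal
#' and IgG control tracks with pseudocount 1. Both tracks should be
#' depth-scaled (e.g. CPM) first.
#'
#' @param signal,control [binned_track()]s with identical binning.
#' @param pseudocount Added to both numerator and denominator (default 1);
#'   with `pseudocount = 0` any zero control bin is an error.
#' @return A [binned_track()] of ratios.
#' @export
igg_normalize <- function(signal, control, pseudocount = 1) {
  stopifnot(inherits(signal, "binned_track"), inherits(control, "binned_track"))
  if (signal$bin_size != control$bin_size ||
      !identical(names(signal$values), names(control$values)))
    stop("signal and control tracks must share binning")
  if (pseudocount == 0 &&
      any(vapply(control$values, function(v) any(v == 0), logical(1))))
    stop("zero control bins with pseudocount 0")
  vals <- mapply(function(s, c) (s + pseudocount) / (c + pseudocount),
                 signal$values, control$values, SIMPLIFY = FALSE)
  binned_track(vals, signal$bin_size, signal$genome_lengths)
}

#' Re-bin a track to a coarser resolution by summation
#' @param track A [binned_track()].
#' @param bin_size New bin width; must be a multiple of the current one.
#' @return A [binned_track()] at the new resolution.
#' @export
rebin_track <- function(track, bin_size) {
  if (bin_size == track$bin_size) return(track)
  if (bin_size %% track$bin_size != 0)
    stop("new bin size must be a multiple of the current bin size")
  k <- bin_size %/% track$bin_size
  vals <- lapply(names(track$values), function(ct) {
    v <- track$values[[ct]]
    nb <- as.integer(ceiling(track$genome_lengths[[ct]] / bin_size))
    grp <- rep(seq_len(nb), each = k)[seq_along(v)]
    as.numeric(tapply(v, grp, sum))
  })
  binned_track(stats::setNames(vals, names(track$values)), bin_size,
               track$genome_lengths)
}

#' Genome-wide Pearson correlation between two tracks
#'
#' Both tracks are re-binned to `bin_size` (default 5 kb, the conventional
#' resolution for dataset-level comparisons) by summation, concatenated
#' across contigs, and correlated. Invariant under affine scaling of either
#' track.
#'
#' @param a,b [binned_track()]s on the same genome.
#' @param bin_size Comparison resolution.
#' @return Pearson r.
#' @export
track_correlation <- function(a, b, bin_size = 5000L) {
  a <- rebin_track(a, bin_size)
  b <- rebin_track(b, bin_size)
  stopifnot(identical(names(a$values), names(b$values)))
  stats::cor(track_values(a), track_values(b))
}

#' Aggregation saturation curve
#'
#' How many single cells must be aggregated before the pseudobulk
#' recapitulates a reference track? For each cell count, samples cells
#' without replacement, aggregates their fragments, and correlates the
#' aggregate with the reference at 5-kb resolution; repeated `reps` times.
#'
#' @param fragments Fragment table for one target.
#' @param reference A [binned_track()] to correlate against.
#' @param cell_counts Integer vector of subsample sizes (each <= number of
#'   available cells).
#' @param reps Subsampling replicates per size.
#' @param seed Integer seed (fixed seed gives an identical table).
#' @param bin_size Correlation resolution.
#' @return `data.table` with `n_cells`, `mean_r`, `sd_r`.
#' @export
saturation_curve <- function(fragments, reference, cell_counts, reps = 3L,
                             seed = 1L, bin_size = 5000L) {
  fragments <- data.table::as.data.table(fragments)
  cells <- unique(fragments$cell_id)
  if (any(cell_counts > length(cells)))
    stop("cell_counts exceed available cells")
  gl <- reference$genome_lengths
  rows <- list()
  .with_seed(seed, {
    for (n in cell_counts) {
      r <- vapply(seq_len(reps), function(rep_i) {
        pick <- sample(cells, n)
        tr <- .bin_fragments(fragments[cell_id %in% pick], gl, bin_size)
        track_correlation(tr, reference, bin_size)
      }, numeric(1))
      rows[[as.character(n)]] <- data.table::data.table(
        n_cells = n, mean_r = mean(r), sd_r = stats::sd(r))
    }
  })
  data.table::rbindlist(rows)
}

#' Median depth normalization of a bin matrix
#'
#' Scales each cell's bin vector by `median(per-cell total) / (cell total)`
#' so that all per-cell totals equal the per-target median — the standard
#' depth normalization applied per histone modification before dimensional
#' reduction.
#'
#' @param mat bins x cells matrix (sparse or dense) for one target; all
#'   included cells must have positive totals.
#' @return Matrix of the same shape.
#' @export
median_normalize <- function(mat) {
  totals <- Matrix::colSums(mat)
  if (any(totals <= 0)) stop("all cells must have positive totals")
  med <- stats::median(totals)
  out <- mat %*% Matrix::Diagonal(x = med / totals)
  dimnames(out) <- dimnames(mat)
  out
}

#' Upper-tail Poisson threshold
#'
#' Smallest integer `t` with `P(Poisson(lambda) >= t) <= p`.
#'
#' @param lambda Poisson mean(s).
#' @param p Tail probability (default 5e-7, the conventional stringency for
#'   chromatin-state binarization).
#' @return Integer threshold(s).
#' @export
poisson_threshold <- function(lambda, p = 5e-7) {
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  as.integer(stats::qpois(1 - p, lambda) + 1L)
}

#' Poisson binarization of a binned signal track
#'
#' Marks bin `b` as 1 when its count reaches the upper-tail threshold
#' `t(lambda_b)` at probability `p`. Without a control, `lambda_b` is the
#' genome-wide mean signal per bin. With an IgG control, the local
#' expectation is the depth-matched control
#' (`control_b * total_signal / total_control`) floored at the genome-wide
#' mean, mirroring how binarization tools treat sparse controls; the floor
#' can be disabled.
#'
#' @param signal [binned_track()] of non-negative integer counts (re-binned
#'   to `bin_size` if needed).
#' @param control Optional [binned_track()] (IgG) on the same genome.
#' @param p Tail probability.
#' @param bin_size Binarization resolution (default 200 bp).
#' @param floor_global_mean Keep the genome-wide mean as a lower bound on
#'   the local expectation (default TRUE).
#' @return A [binned_track()] of 0/1 values.
#' @export
poisson_binarize <- function(signal, control = NULL, p = 5e-7,
                             bin_size = 200L, floor_global_mean = TRUE) {
  signal <- rebin_track(signal, bin_size)
  nb <- sum(vapply(signal$values, length, integer(1)))
  gmean <- track_total(signal) / nb
  if (!is.null(control)) {
    control <- rebin_track(control, bin_size)
    if (!identical(names(control$values), names(signal$values)))
      stop("signal and control tracks must share contigs")
    tot_c <- track_total(control)
    if (tot_c == 0) stop("control track has zero total signal")
    sf <- track_total(signal) / tot_c
  }
  vals <- lapply(names(signal$values), function(ct) {
    s <- signal$values[[ct]]
    lam <- if (is.null(control)) {
      rep(if (floor_global_mean) gmean else 0, length(s))
    } else {
      l <- control$values[[ct]] * sf
      if (floor_global_mean) pmax(l, gmean) else l
    }
    as.numeric(s >= poisson_threshold(lam, p))
  })
  binned_track(stats::setNames(vals, names(signal$values)), bin_size,
               signal$genome_lengths)
}

#' Write / read bedGraph tracks
#'
#' Plain four-column bedGraph (contig, start, end, value), 0-based
#' half-open, bins at contig ends truncated; zero bins are written so the
#' file round-trips exactly.
#'
#' @param track A [binned_track()].
#' @param path Output path (gz supported).
#' @export
write_bedgraph <- function(track, path) {
  rows <- lapply(names(track$values), function(ct) {
    v <- track$values[[ct]]
    s <- (seq_along(v) - 1L) * track$bin_size
    data.table::data.table(contig = ct, start = s,
                           end = pmin(s + track$bin_size,
                                      track$genome_lengths[[ct]]),
                           value = v)
  })
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph
#' @param genome_lengths,bin_size Geometry of the stored track.
#' @export
read_bedgraph <- function(path, genome_lengths, bin_size) {
  dt <- .fread_auto(path, sep = "\t", header = FALSE,
                          col.names = c("contig", "start", "end", "value"))
  vals <- lapply(names(genome_lengths), function(ct) {
    nb <- as.integer(ceiling(genome_lengths[[ct]] / bin_size))
    v <- numeric(nb)
    d <- dt[contig == ct]
    v[d$start %/% bin_size + 1L] <- d$value
    v
  })
  binned_track(stats::setNames(vals, names(genome_lengths)), bin_size,
               genome_lengths)
}

#' Write a binarized track as per-mark TSV plus a BED of 1-bins
#'
#' One TSV per mark (`<mark>_binary.tsv`: contig, bin index, 0/1) and a BED
#' of the bins marked 1.
#'
#' @param binary A 0/1 [binned_track()] from [poisson_binarize()].
#' @param mark Mark name used in file names.
#' @param dir Output directory.
#' @export
write_binarized <- function(binary, mark, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(names(binary$values), function(ct)
    data.table::data.table(contig = ct,
                           bin = seq_along(binary$values[[ct]]) - 1L,
                           value = as.integer(binary$values[[ct]])))
  tab <- data.table::rbindlist(rows)
  data.table::fwrite(tab, file.path(dir, paste0(mark, "_binary.tsv")),
                     sep = "\t")
  ones <- tab[value == 1L]
  data.table::fwrite(
    ones[, .(contig, start = bin * binary$bin_size,
             end = pmin((bin + 1L) * binary$bin_size,
                        binary$genome_lengths[contig]))],
    file.path(dir, paste0(mark, "_binary.bed")), sep = "\t",
    col.names = FALSE)
  invisible(dir)
}
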