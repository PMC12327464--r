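# Cell- and dataset-level quality metrics: FRiP, duplication rates, the
# standard unique-read cell filters with recovery rate, Cramer's V between
# binarized modalities, and k-nearest-neighbour label agreement.

# peaks (data.table contig/start/end, 0-based) -> merged GRanges
.peaks_granges <- function(peaks) {
  peaks <- data.table::as.data.table(peaks)
  GenomicRanges::reduce(GenomicRanges::GRanges(
    peaks$contig, IRanges::IRanges(peaks$start + 1L, peaks$end)))
}

#' Fraction of fragments in peaks (FRiP)
#'
#' For each (cell, target), the fraction of unique fragments overlapping at
#' least one peak by >= 1 bp; peaks are merged first, so the statistic is
#' invariant to peak order and to splitting peaks into touching pieces.
#' Cells with no fragments for a target are reported as missing, not zero.
#'
#' @param fragments Fragment table (`contig`, `start`, `end`, `cell_id`,
#'   `target`), 0-based half-open.
#' @param peaks Peak intervals: `data.table` with `contig`, `start`, `end`
#'   (0-based) or a BED path.
#' @return List with `per_cell` (`cell_id`, `target`, `n_fragments`,
#'   `n_in_peak`, `frip`) and `per_target` aggregate (all cells pooled).
#' @examples
#' fr <- data.table::data.table(contig = "chr1", start = c(0, 100, 200, 900),
#'                              end = c(50, 150, 250, 950),
#'                              cell_id = "c1", target = "H3K4me3")
#' pk <- data.table::data.table(contig = "chr1", start = 0, end = 260)
#' frip(fr, pk)$per_target$frip   # 0.75
#' @export
frip <- function(fragments, peaks) {
  if (is.character(peaks) && length(peaks) == 1L) peaks <- read_bed(peaks)
  fragments <- data.table::as.data.table(fragments)
  pk <- .peaks_granges(peaks)
  fg <- GenomicRanges::GRanges(fragments$contig,
                               IRanges::IRanges(fragments$start + 1L,
                                                fragments$end))
  # suppress the benign seqlevel-merge notice when fragments and peaks
  # live on disjoint contigs (legitimately FRiP 0)
  hit <- suppressWarnings(IRanges::overlapsAny(fg, pk))
  per_cell <- fragments[, .(n_fragments = .N, n_in_peak = sum(hit[.I])),
                        by = .(cell_id, target)]
  per_cell[, frip := n_in_peak / n_fragments]
  per_target <- per_cell[, .(n_fragments = sum(n_fragments),
                             n_in_peak = sum(n_in_peak)), by = target]
  per_target[, frip := n_in_peak / n_fragments]
  list(per_cell = per_cell[], per_target = per_target[])
}

#' Apply the unique-read cell filters
#'
#' A cell passes when its total unique DNA reads (summed over all targets,
#' IgG included) strictly exceed `dna_min` and its unique RNA molecules
#' strictly exceed `rna_min` — the standard thresholds are > 2500 for DNA
#' and > 2000 for RNA. Recovery is the passing fraction of the number of
#' cells loaded into the experiment, when supplied.
#'
#' @param cell_stats `data.table` with `cell_id`, `dna_unique`,
#'   `rna_unique` (one row per cell; `NA` treated as 0).
#' @param dna_min,rna_min Strict lower bounds on unique counts.
#' @param n_input Number of cells loaded (optional, for the recovery rate).
#' @return List with `cells` (input plus logical `pass`), `pass_ids`,
#'   `n_pass` and `recovery` (`NA` when `n_input` missing).
#' @export
filter_cells <- function(cell_stats, dna_min = 2500L, rna_min = 2000L,
                         n_input = NULL) {
  if (dna_min < 0 || rna_min < 0) stop("thresholds must be non-negative")
  cs <- data.table::copy(data.table::as.data.table(cell_stats))
  cs[is.na(dna_unique), dna_unique := 0L]
  cs[is.na(rna_unique), rna_unique := 0L]
  cs[, pass := dna_unique > dna_min & rna_unique > rna_min]
  list(cells = cs[],
       pass_ids = cs[pass == TRUE, cell_id],
       n_pass = sum(cs$pass),
       recovery = if (is.null(n_input)) NA_real_ else sum(cs$pass) / n_input)
}

#' Cramer's V between two binarized single-cell matrices
#'
#' Both matrices (cells x features, shared indices) are binarized at
#' `count > 0`; the 2x2 contingency table over all (cell, feature) entries
#' gives `V = sqrt(chi^2 / N)` with the Pearson statistic (no continuity
#' correction), so for 2x2 tables V equals the absolute phi coefficient and
#' is symmetric in its arguments. A degenerate margin (one variable
#' constant) yields 0 with a warning.
#'
#' @param a,b Matrices (dense or sparse) of identical dimensions, cells x
#'   features (orientation is irrelevant as long as it matches).
#' @return V in `[0, 1]`.
#' @export
cramers_v <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("matrices must share dimensions")
  av <- as.vector(a > 0)
  bv <- as.vector(b > 0)
  tab <- table(factor(av, c(FALSE, TRUE)), factor(bv, c(FALSE, TRUE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate margin: one variable is constant; V set to 0")
    return(0)
  }
  chi2 <- suppressWarnings(
    unname(stats::chisq.test(tab, correct = FALSE)$statistic))
  sqrt(chi2 / sum(tab))
}

#' Fraction of k-nearest neighbours sharing a cell's label
#'
#' For each cell, its `k` nearest neighbours (Euclidean distance on the
#' supplied representation, self excluded, distance ties broken by cell
#' index) are examined for the same class label; the per-cell fractions are
#' averaged. Used to quantify how well a feature space separates
#' RNA-defined lineages (conventionally `k = 50`).
#'
#' @param features Numeric matrix, cells x dimensions.
#' @param labels Vector of class labels, one per cell.
#' @param k Neighbourhood size (`0 < k < n_cells`).
#' @return Mean same-label fraction in `[0, 1]`.
#' @export
knn_label_agreement <- function(features, labels, k = 50L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (length(labels) != n) stop("one label per cell required")
  if (k <= 0L) stop("k must be positive")
  if (k >= n) stop("k must be smaller than the number of cells")
  d <- as.matrix(stats::dist(features))
  agree <- vapply(seq_len(n), function(i) {
    ord <- order(d[i, ], seq_len(n))      # ties broken by cell index
    nb <- setdiff(ord, i)[seq_len(k)]
    mean(labels[nb] == labels[i])
  }, numeric(1))
  mean(agree)
}

#' Assemble the dataset-level QC report
#'
#' Joins demultiplexing statistics, per-cell unique DNA/RNA counts,
#' per-target duplication rates and FRiP, the filter outcome, and the
#' barcode-space collision estimate into one deterministic report.
#'
#' @param demux_stats `stats` element from [demux_reads()].
#' @param fragments DNA fragment table (with `dup_count`).
#' @param molecules RNA molecule table (with `dup_count`).
#' @param peaks Peak table or BED path (for FRiP), or `NULL` to skip.
#' @param design A [barcode_design()] (for the collision estimate).
#' @param dna_min,rna_min Filter thresholds, see [filter_cells()].
#' @param n_input_cells Cells loaded, for recovery and collision estimates
#'   (default: number of cells observed).
#' @return A `qc_report` list: `per_cell` table, `per_target` table,
#'   `filter` outcome, `dataset` summary.
#' @export
qc_summary <- function(demux_stats, fragments, molecules, peaks, design,
                       dna_min = 2500L, rna_min = 2000L,
                       n_input_cells = NULL) {
  fragments <- data.table::as.data.table(fragments)
  molecules <- data.table::as.data.table(molecules)
  dna_cell <- fragments[, .(dna_unique = .N, dna_total = sum(dup_count)),
                        by = cell_id]
  rna_cell <- molecules[, .(rna_unique = .N, rna_total = sum(dup_count)),
                        by = cell_id]
  per_cell <- merge(dna_cell, rna_cell, by = "cell_id", all = TRUE)
  gene_per_cell <- NULL
  per_target <- fragments[, .(unique_reads = .N, total_reads = sum(dup_count)),
                          by = target]
  per_target[, duplication_rate := 1 - unique_reads / total_reads]
  if (!is.null(peaks)) {
    fp <- frip(fragments, peaks)$per_target
    per_target <- merge(per_target, fp[, .(target, frip)], by = "target",
                        all.x = TRUE)
  }
  rna_row <- molecules[, .(target = "RNA", unique_reads = .N,
                           total_reads = sum(dup_count))]
  rna_row[, duplication_rate := 1 - unique_reads / total_reads]
  filt <- filter_cells(per_cell[, .(cell_id, dna_unique, rna_unique)],
                       dna_min = dna_min, rna_min = rna_min,
                       n_input = n_input_cells)
  n_obs <- nrow(per_cell)
  n_for_collision <- n_input_cells %||% n_obs
  structure(list(
    per_cell = merge(per_cell, filt$cells[, .(cell_id, pass)],
                     by = "cell_id"),
    per_target = data.table::rbindlist(list(per_target, rna_row),
                                       fill = TRUE),
    filter = list(dna_min = dna_min, rna_min = rna_min,
                  n_pass = filt$n_pass, recovery = filt$recovery),
    dataset = list(
      n_cells_observed = n_obs,
      demux = demux_stats,
      collision_estimate_linear =
        collision_rate(n_for_collision, barcode_combinations(design),
                       "linear"),
      collision_estimate_birthday =
        collision_rate(n_for_collision, barcode_combinations(design),
                       "birthday"))),
    class = "qc_report")
}

#' Write a QC report as JSON plus a per-cell TSV
#' @param report A `qc_report` from [qc_summary()].
#' @param dir Output directory.
#' @export
write_qc_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(report$per_cell, file.path(dir, "qc_per_cell.tsv"),
                     sep = "\t")
  jsonlite::write_json(
    list(per_target = report$per_target, filter = report$filter,
         dataset = report$dataset),
    file.path(dir, "qc_report.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(dir)
}
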