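# Modality-specific deduplication and quantification: DNA duplicates share a
# mapping position within a cell (UMI ignored); RNA duplicates share mapping
# position *and* UMI within a cell. Deduplicated DNA becomes per-target
# fragment files; deduplicated RNA becomes a gene x cell UMI count matrix.

# split "BC1:BC2:BC3:target:umi:serial" read names into components
.parse_read_names <- function(name) {
  parts <- data.table::tstrsplit(name, ":", fill = NA_character_)
  if (length(parts) != 6L)
    stop("read names must have 6 colon-separated fields ",
         "(BC1:BC2:BC3:target:umi:serial)")
  data.table::data.table(
    cell_id = paste(parts[[1]], parts[[2]], parts[[3]], sep = ":"),
    target = parts[[4]], umi = parts[[5]])
}

#' Deduplicate DNA records by mapping position per cell
#'
#' DNA fragments carry no usable UMI signal in this assay, so duplicates are
#' defined purely by identical mapping coordinates within one cell and
#' target; the UMI is ignored. One fragment is emitted per distinct
#' `(cell, target, contig, start, end)` with its multiplicity.
#'
#' @param records Aligned records (`data.table` with `name`, `contig`,
#'   `start`, `end`), names formatted `BC1:BC2:BC3:target:umi:serial`.
#' @return List with `fragments` (`contig`, `start`, `end`, `cell_id`,
#'   `target`, `dup_count`) and `stats` (`n_input`, `n_unique`,
#'   `n_rejected`, `duplication_rate`).
#' @export
dedup_dna <- function(records) {
  records <- data.table::as.data.table(records)
  meta <- .parse_read_names(records$name)
  bad <- is.na(meta$umi)
  dt <- cbind(records[, .(contig, start, end)], meta)[!bad]
  frags <- dt[, .(dup_count = .N), by = .(cell_id, target, contig, start, end)]
  data.table::setorder(frags, contig, start, end, cell_id)
  list(fragments = frags[, .(contig, start, end, cell_id, target, dup_count)],
       stats = list(n_input = nrow(records), n_unique = nrow(frags),
                    n_rejected = sum(bad),
                    duplication_rate = if (nrow(dt)) 1 - nrow(frags) / nrow(dt)
                                       else NA_real_))
}

#' Deduplicate RNA records by mapping position and UMI per cell
#'
#' One molecule is kept per distinct `(cell, contig, 5' position, strand,
#' UMI)`; UMIs are compared exactly (no correction or graph collapsing). The
#' 5' position is the strand-aware first transcribed base of the alignment.
#'
#' @param records Aligned records with `name` (`BC1:BC2:BC3:rt:umi:serial`),
#'   `contig`, `start`, `end`, `strand`.
#' @return List with `molecules` (`contig`, `pos`, `strand`, `cell_id`,
#'   `rt`, `umi`, `dup_count`) and `stats`.
#' @export
dedup_rna <- function(records) {
  records <- data.table::as.data.table(records)
  meta <- .parse_read_names(records$name)
  bad <- is.na(meta$umi)
  dt <- cbind(records[, .(contig, start, end, strand)], meta)[!bad]
  dt[, pos := data.table::fifelse(strand == "-", end - 1L, start)]
  mols <- dt[, .(dup_count = .N),
             by = .(cell_id, rt = target, contig, pos, strand, umi)]
  data.table::setorder(mols, contig, pos, cell_id, umi)
  list(molecules = mols[, .(contig, pos, strand, cell_id, rt, umi, dup_count)],
       stats = list(n_input = nrow(records), n_unique = nrow(mols),
                    n_rejected = sum(bad),
                    duplication_rate = if (nrow(dt)) 1 - nrow(mols) / nrow(dt)
                                       else NA_real_))
}

# gene table (data.table contig/start/end 0-based, gene_id) -> GRanges
.genes_granges <- function(genes) {
  GenomicRanges::GRanges(
    genes$contig,
    IRanges::IRanges(genes$start + 1L, genes$end),
    gene_id = genes$gene_id)
}

#' Count deduplicated RNA molecules per gene and cell
#'
#' Each molecule is assigned to the single gene whose interval contains its
#' 5' position; molecules overlapping no gene or several genes are dropped
#' and counted. The result is a sparse genes x cells UMI matrix.
#'
#' @param molecules Output of [dedup_rna()] (`$molecules`).
#' @param genes Gene annotation: `data.table`/data.frame with `contig`,
#'   `start`, `end` (0-based half-open), `gene_id` (BED-like), or a path to
#'   a 6-column BED file.
#' @param cells Optional character vector fixing the column set/order.
#' @return List with `matrix` (sparse `dgCMatrix`, genes x cells) and
#'   `stats` (`n_molecules`, `n_assigned`, `n_unassigned`, `n_ambiguous`).
#' @export
count_genes <- function(molecules, genes, cells = NULL) {
  if (is.character(genes) && length(genes) == 1L) genes <- read_bed(genes)
  genes <- data.table::as.data.table(genes)
  molecules <- data.table::as.data.table(molecules)
  gr <- .genes_granges(genes)
  mq <- GenomicRanges::GRanges(molecules$contig,
                               IRanges::IRanges(molecules$pos + 1L,
                                                molecules$pos + 1L))
  ov <- GenomicRanges::findOverlaps(mq, gr)
  nh <- tabulate(S4Vectors::queryHits(ov), nbins = length(mq))
  uniq <- which(nh == 1L)
  keep <- ov[S4Vectors::queryHits(ov) %in% uniq]
  gene_of <- genes$gene_id[S4Vectors::subjectHits(keep)]
  cell_of <- molecules$cell_id[S4Vectors::queryHits(keep)]
  if (is.null(cells)) cells <- sort(unique(molecules$cell_id))
  gi <- match(gene_of, genes$gene_id)
  ci <- match(cell_of, cells)
  ok <- !is.na(ci)
  mat <- Matrix::sparseMatrix(
    i = gi[ok], j = ci[ok], x = 1,
    dims = c(nrow(genes), length(cells)),
    dimnames = list(genes$gene_id, cells))
  list(matrix = methods::as(mat, "CsparseMatrix"),
       stats = list(n_molecules = nrow(molecules),
                    n_assigned = sum(ok),
                    n_unassigned = sum(nh == 0L),
                    n_ambiguous = sum(nh > 1L)))
}

#' Write/read a fragments file
#'
#' Five-column fragment dialect: contig, start, end (0-based half-open),
#' cell barcode, duplicate count; sorted by (contig, start). One file per
#' target is the convention (`<target>.fragments.tsv.gz`).
#'
#' @param fragments Fragment table from [dedup_dna()].
#' @param path Output path (gzipped when ending in `.gz`).
#' @return The path, invisibly; `read_fragments()` returns a `data.table`.
#' @export
write_fragments <- function(fragments, path) {
  out <- data.table::as.data.table(fragments)[
    order(contig, start, end), .(contig, start, end, cell_id, dup_count)]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_fragments
#' @param target Target label to attach to the read table (the file itself
#'   does not carry one).
#' @export
read_fragments <- function(path, target = NA_character_) {
  dt <- .fread_auto(path, sep = "\t", header = FALSE,
                          col.names = c("contig", "start", "end", "cell_id",
                                        "dup_count"))
  dt[, target := target]
  dt[]
}

#' Read a BED file (3+ columns) into a 0-based table
#' @param path BED path.
#' @return `data.table` with `contig`, `start`, `end` and, when present,
#'   `gene_id`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  dt <- .fread_auto(path, sep = "\t", header = FALSE)
  nms <- c("contig", "start", "end", "gene_id", "score", "strand")
  data.table::setnames(dt, nms[seq_len(min(ncol(dt), 6L))])
  dt[]
}

#' Genome-wide bin matrix from fragments
#'
#' Fixed-width non-overlapping bins across the genome (default 5 kb, the
#' standard resolution for single-cell chromatin clustering); a fragment
#' increments every bin it overlaps by one.
#'
#' @param fragments Fragment table (`contig`, `start`, `end`, `cell_id`).
#' @param genome_lengths Named integer vector of contig lengths.
#' @param bin_size Bin width in bp (> 0).
#' @param cells Optional fixed cell (column) ordering.
#' @return Sparse `dgCMatrix`, bins x cells; bin names `contig:start-end`.
#' @export
make_bin_matrix <- function(fragments, genome_lengths, bin_size = 5000L,
                            cells = NULL) {
  if (bin_size <= 0) stop("bin_size must be positive")
  fragments <- data.table::as.data.table(fragments)
  nbins <- stats::setNames(as.integer(ceiling(genome_lengths / bin_size)),
                           names(genome_lengths))
  offs <- stats::setNames(cumsum(c(0L, nbins))[seq_along(nbins)],
                          names(genome_lengths))
  bin_names <- unlist(lapply(names(genome_lengths), function(ct) {
    s <- (seq_len(nbins[[ct]]) - 1L) * bin_size
    sprintf("%s:%d-%d", ct, s, pmin(s + bin_size, genome_lengths[[ct]]))
  }), use.names = FALSE)
  if (is.null(cells)) cells <- sort(unique(fragments$cell_id))
  if (!nrow(fragments))
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(sum(nbins), length(cells)),
                                dimnames = list(bin_names, cells)))
  b0 <- fragments$start %/% bin_size
  b1 <- (fragments$end - 1L) %/% bin_size
  span <- b1 - b0 + 1L
  rows <- rep(seq_len(nrow(fragments)), span)
  bins <- sequence(span, from = b0 + 1L) - 1L  # every bin the fragment touches
  gbin <- offs[fragments$contig[rows]] + bins + 1L
  ci <- match(fragments$cell_id[rows], cells)
  ok <- !is.na(ci) & bins >= 0L & bins < nbins[fragments$contig[rows]]
  Matrix::sparseMatrix(i = gbin[ok], j = ci[ok], x = 1,
                       dims = c(sum(nbins), length(cells)),
                       dimnames = list(bin_names, cells))
}

#' Write a sparse count matrix as MatrixMarket with sidecars
#'
#' `matrix.mtx` plus `features.tsv` (row ids) and `barcodes.tsv` (column
#' ids), the conventional sparse-matrix exchange layout.
#'
#' @param mat Sparse matrix with dimnames.
#' @param dir Output directory.
#' @export
write_mtx <- function(mat, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(mat, file.path(dir, "matrix.mtx"))
  writeLines(rownames(mat), file.path(dir, "features.tsv"))
  writeLines(colnames(mat), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' @rdname write_mtx
#' @export
read_mtx <- function(dir) {
  mat <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  dimnames(mat) <- list(readLines(file.path(dir, "features.tsv")),
                        readLines(file.path(dir, "barcodes.tsv")))
  methods::as(mat, "CsparseMatrix")
}
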