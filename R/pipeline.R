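# End-to-end pipeline over the synthetic scenario: simulate -> demultiplex
# -> align -> deduplicate/quantify -> QC -> aggregate. Each stage asserts
# its conservation counters (inputs = outputs + rejects).

#' Pipeline configuration
#'
#' Collects thresholds, bin sizes, file paths and the root seed. All
#' randomness flows from `seed`, split per stage. The configuration
#' round-trips through YAML unchanged.
#'
#' @param scenario A [scenario()], or a YAML path understood by
#'   [read_scenario_yaml()]; `NULL` uses the default scenario.
#' @param design A [barcode_design()], or a whitelist TSV path; `NULL` uses
#'   [default_barcode_design()].
#' @param max_mismatch Demultiplexer mismatch allowance (0 or 1).
#' @param dna_min,rna_min Cell filter thresholds (strict lower bounds).
#' @param mapq_dna,mapq_rna Mapping-quality cutoffs for external
#'   alignments.
#' @param bin_size_track,bin_size_matrix,bin_size_binarize Bin widths (bp)
#'   for pseudobulk tracks, the cell-level bin matrix, and Poisson
#'   binarization.
#' @param seed Root seed.
#' @param out_dir Output directory, or `NULL` for in-memory results only.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(scenario = NULL, design = NULL,
                            max_mismatch = 0L, dna_min = 2500L,
                            rna_min = 2000L, mapq_dna = 10L, mapq_rna = 50L,
                            bin_size_track = 50L, bin_size_matrix = 5000L,
                            bin_size_binarize = 200L, seed = 1L,
                            out_dir = NULL) {
  if (is.character(scenario)) scenario <- read_scenario_yaml(scenario)
  if (is.character(design)) design <- read_design_whitelists(design)
  cfg <- structure(list(
    scenario = scenario, design = design,
    max_mismatch = as.integer(max_mismatch),
    dna_min = as.integer(dna_min), rna_min = as.integer(rna_min),
    mapq_dna = as.integer(mapq_dna), mapq_rna = as.integer(mapq_rna),
    bin_size_track = as.integer(bin_size_track),
    bin_size_matrix = as.integer(bin_size_matrix),
    bin_size_binarize = as.integer(bin_size_binarize),
    seed = as.integer(seed), out_dir = out_dir), class = "pipeline_config")
  validate_pipeline_config(cfg)
}

#' @rdname pipeline_config
#' @param cfg A `pipeline_config`.
#' @export
validate_pipeline_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  for (f in c("dna_min", "rna_min", "mapq_dna", "mapq_rna"))
    if (cfg[[f]] < 0) stop(f, " must be non-negative")
  for (f in c("bin_size_track", "bin_size_matrix", "bin_size_binarize"))
    if (cfg[[f]] <= 0) stop(f, " must be positive")
  if (!cfg$max_mismatch %in% c(0L, 1L)) stop("max_mismatch must be 0 or 1")
  if (!is.null(cfg$scenario)) validate_scenario(cfg$scenario)
  cfg
}

#' Serialize a pipeline configuration to YAML (and back)
#'
#' Scalar settings are stored directly; the scenario and design, when
#' present, are embedded under their own keys so one file captures the whole
#' run. The configuration round-trips unchanged.
#'
#' @param cfg A [pipeline_config()].
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns a [pipeline_config()].
#' @export
write_pipeline_config <- function(cfg, path) {
  cfg <- validate_pipeline_config(cfg)
  obj <- unclass(cfg)
  if (!is.null(obj$scenario)) {
    tmp <- tempfile(); write_scenario_yaml(obj$scenario, tmp)
    obj$scenario <- yaml::read_yaml(tmp); unlink(tmp)
  }
  if (!is.null(obj$design)) {
    tmp <- tempfile(); write_design_yaml(obj$design, tmp)
    obj$design <- yaml::read_yaml(tmp); unlink(tmp)
  }
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  sc <- NULL
  if (!is.null(obj$scenario)) {
    tmp <- tempfile(); yaml::write_yaml(obj$scenario, tmp)
    sc <- read_scenario_yaml(tmp); unlink(tmp)
  }
  dsn <- NULL
  if (!is.null(obj$design)) {
    tmp <- tempfile(); yaml::write_yaml(obj$design, tmp)
    dsn <- read_design_yaml(tmp); unlink(tmp)
  }
  pipeline_config(scenario = sc, design = dsn,
                  max_mismatch = obj$max_mismatch, dna_min = obj$dna_min,
                  rna_min = obj$rna_min, mapq_dna = obj$mapq_dna,
                  mapq_rna = obj$mapq_rna,
                  bin_size_track = obj$bin_size_track,
                  bin_size_matrix = obj$bin_size_matrix,
                  bin_size_binarize = obj$bin_size_binarize,
                  seed = obj$seed, out_dir = obj$out_dir)
}

.assert_conserved <- function(stage, total, parts) {
  if (total != sum(unlist(parts)))
    stop("conservation violated in ", stage, ": ", total, " inputs vs ",
         sum(unlist(parts)), " accounted for")
}

#' Run the end-to-end pipeline on a synthetic scenario
#'
#' Chains simulation, demultiplexing, exact alignment, modality-specific
#' deduplication, gene counting, QC summary and pseudobulk aggregation
#' (CPM-scaled tracks, IgG ratio tracks, pairwise 5-kb track correlations,
#' per-target bin matrices, gene-level Cramer's V between the active marks
#' and with RNA). Conservation counters are asserted at every stage. With
#' `out_dir` set, fragments, matrices, tracks and the QC report are written
#' to disk.
#'
#' @param config A [pipeline_config()].
#' @return A list with every stage's outputs (`sim`, `demux`, `align`,
#'   `fragments`, `molecules`, `gene_counts`, `bin_matrices`, `qc`,
#'   `tracks`, `correlations`, `cramers_v`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  config <- validate_pipeline_config(config)
  sc <- config$scenario %||% scenario(seed = config$seed)
  design <- config$design %||% default_barcode_design()

  ## simulate -------------------------------------------------------------
  sim <- simulate_experiment(sc, design)
  n_reads <- nrow(sim$reads)

  ## demultiplex ----------------------------------------------------------
  dmx <- demux_reads(sim$reads$read2, design,
                     modality = "auto", max_mismatch = config$max_mismatch)
  ann <- dmx$annotations
  .assert_conserved("demux", n_reads,
                    list(valid = dmx$stats$n_valid,
                         rejected = n_reads - dmx$stats$n_valid))

  ## align valid reads ----------------------------------------------------
  ok <- which(ann$status == "valid")
  read_names <- paste(ann$cell_id[ok], ann$target_or_rt[ok], ann$umi[ok],
                      ok, sep = ":")
  aln <- align_exact(stats::setNames(sim$reads$read1[ok], read_names),
                     sim$genome)
  .assert_conserved("align", length(ok),
                    list(aln$stats$n_unique, aln$stats$n_multi,
                         aln$stats$n_unmapped))
  rec <- aln$records
  is_dna <- ann$modality[ok][match(rec$name, read_names)] == "DNA"

  ## deduplicate ----------------------------------------------------------
  dna <- dedup_dna(rec[is_dna])
  rna <- dedup_rna(rec[!is_dna])
  .assert_conserved("dedup_dna", nrow(rec[is_dna]),
                    list(sum(dna$fragments$dup_count), dna$stats$n_rejected))
  .assert_conserved("dedup_rna", nrow(rec[!is_dna]),
                    list(sum(rna$molecules$dup_count), rna$stats$n_rejected))

  ## quantify -------------------------------------------------------------
  cells <- sort(unique(c(dna$fragments$cell_id, rna$molecules$cell_id)))
  gene_counts <- count_genes(rna$molecules, sim$genes, cells = cells)
  gl <- .genome_lengths(sim$genome)
  bin_matrices <- stats::setNames(
    lapply(sort(unique(dna$fragments$target)), function(tg)
      make_bin_matrix(dna$fragments[target == tg], gl,
                      bin_size = config$bin_size_matrix, cells = cells)),
    sort(unique(dna$fragments$target)))

  ## QC -------------------------------------------------------------------
  peaks_all <- unique(sim$peaks[, .(target, contig, start, end)])
  qc <- qc_summary(dmx$stats, dna$fragments, rna$molecules,
                   peaks = NULL, design = design,
                   dna_min = config$dna_min, rna_min = config$rna_min,
                   n_input_cells = sc$n_cells)
  # per-target FRiP against that target's own peak set
  frips <- data.table::rbindlist(lapply(
    intersect(unique(dna$fragments$target), unique(peaks_all$target)),
    function(tg) {
      f <- frip(dna$fragments[target == tg],
                peaks_all[target == tg, .(contig, start, end)])$per_target
      f
    }))
  qc$per_target <- merge(qc$per_target, frips[, .(target, frip)],
                         by = "target", all.x = TRUE)

  ## aggregate ------------------------------------------------------------
  tracks <- pseudobulk(dna$fragments, gl, bin_size = config$bin_size_track,
                       scale = "cpm")
  igg <- sc$igg
  ratio_tracks <- list()
  if (igg %in% names(tracks)) {
    for (tg in setdiff(names(tracks), igg))
      ratio_tracks[[tg]] <- igg_normalize(tracks[[tg]], tracks[[igg]])
  }
  tgs <- names(tracks)
  correlations <- matrix(NA_real_, length(tgs), length(tgs),
                         dimnames = list(tgs, tgs))
  for (i in seq_along(tgs)) for (j in seq_len(i))
    correlations[i, j] <- correlations[j, i] <-
      track_correlation(tracks[[tgs[i]]], tracks[[tgs[j]]],
                        bin_size = config$bin_size_matrix)

  ## gene-level Cramer's V between modalities ------------------------------
  activity <- lapply(stats::setNames(nm = setdiff(tgs, igg)), function(tg)
    .gene_activity(dna$fragments[target == tg], sim$genes, cells))
  activity$RNA <- gene_counts$matrix
  pairs_ <- utils::combn(names(activity), 2)
  cv <- apply(pairs_, 2, function(p)
    suppressWarnings(cramers_v(activity[[p[1]]], activity[[p[2]]])))
  cramers <- data.table::data.table(a = pairs_[1, ], b = pairs_[2, ],
                                    v = cv)

  res <- list(sim = sim, demux = dmx, align = aln$stats,
              fragments = dna$fragments, dna_stats = dna$stats,
              molecules = rna$molecules, rna_stats = rna$stats,
              gene_counts = gene_counts, bin_matrices = bin_matrices,
              qc = qc, tracks = tracks, ratio_tracks = ratio_tracks,
              correlations = correlations, cramers_v = cramers,
              config = config)
  if (!is.null(config$out_dir)) .write_pipeline_outputs(res, config$out_dir)
  res
}

# fragments-over-gene-body counts, genes x cells (for Cramer's V features)
.gene_activity <- function(fragments, genes, cells) {
  gr <- .genes_granges(genes)
  fg <- GenomicRanges::GRanges(fragments$contig,
                               IRanges::IRanges(fragments$start + 1L,
                                                fragments$end))
  ov <- GenomicRanges::findOverlaps(fg, gr)
  gi <- S4Vectors::subjectHits(ov)
  ci <- match(fragments$cell_id[S4Vectors::queryHits(ov)], cells)
  ok <- !is.na(ci)
  Matrix::sparseMatrix(i = gi[ok], j = ci[ok], x = 1,
                       dims = c(length(gr), length(cells)),
                       dimnames = list(genes$gene_id, cells))
}

.write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tg in unique(res$fragments$target))
    write_fragments(res$fragments[target == tg],
                    file.path(dir, paste0(tg, ".fragments.tsv.gz")))
  write_mtx(res$gene_counts$matrix, file.path(dir, "rna_counts"))
  write_qc_report(res$qc, dir)
  for (nm in names(res$tracks))
    write_bedgraph(res$tracks[[nm]],
                   file.path(dir, paste0(nm, ".cpm.bedgraph.gz")))
  for (nm in names(res$ratio_tracks))
    write_bedgraph(res$ratio_tracks[[nm]],
                   file.path(dir, paste0(nm, ".igg_ratio.bedgraph.gz")))
  data.table::fwrite(data.table::as.data.table(res$correlations,
                                               keep.rownames = "target"),
                     file.path(dir, "track_correlations.tsv"), sep = "\t")
  data.table::fwrite(res$cramers_v, file.path(dir, "cramers_v.tsv"),
                     sep = "\t")
  invisible(dir)
}
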