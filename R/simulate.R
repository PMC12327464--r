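# Ground-truthed simulation of a multi-target single-cell CUT&Tag + RNA
# experiment: a random genome, cell types with type-specific peak sets per
# chromatin target, an IgG background-only target, negative-binomial
# per-cell molecule counts, PCR duplication, and Read2 assembled with the
# assay's fixed barcode layout (optionally with substitution errors).

#' Describe a simulated experiment
#'
#' A scenario fixes everything the simulator needs: genome size, cell types
#' and mixing proportions, chromatin targets (active marks with peak sets,
#' plus an IgG-like background target with none), the per-target in-peak
#' probability (the scenario-level FRiP), negative-binomial molecule counts
#' per cell, gene models and per-type expression, barcode substitution error
#' rate, PCR duplication factor and seed. Defaults describe a 500-cell,
#' two-mark + IgG experiment with per-cell depths in the range reported for
#' multi-target CUT&Tag assays, so that the standard cell filters
#' (DNA > 2500, RNA > 2000 unique) are genuinely exercised.
#'
#' @param n_cells Number of cells.
#' @param cell_types Named numeric vector of mixing proportions (sums to 1).
#' @param targets Character vector of active chromatin targets; must be
#'   present in the design's antibody index.
#' @param igg Name of the background-only target (no peaks, FRiP 0).
#' @param frip Named (per active target) or scalar probability that a DNA
#'   fragment falls inside a peak of its cell's type.
#' @param genome_lengths Named integer vector of contig lengths; the genome
#'   sequence is drawn uniformly at random.
#' @param n_peaks Peaks per (target, cell type); `peak_shared_frac` of them
#'   are shared between types, the rest are type-specific.
#' @param peak_width Peak width in bp (>= max fragment length so fragments
#'   fit inside).
#' @param peak_shared_frac Fraction of each type's peaks shared by all types.
#' @param fragments_per_cell Named list `target -> c(mu, size)` of
#'   negative-binomial parameters for DNA molecules per cell (include the
#'   IgG target).
#' @param n_genes,gene_width Gene models: count and width (bp), placed
#'   non-overlapping, random strand.
#' @param umis_per_cell `c(mu, size)` negative-binomial parameters for RNA
#'   molecules per cell.
#' @param expression_shape Gamma shape for per-type gene expression rates;
#'   smaller values give more type-distinct expression profiles.
#' @param barcode_error_rate Per-base substitution probability applied to
#'   Read2.
#' @param duplication_factor Mean PCR copies per molecule (copies are
#'   `1 + Poisson(factor - 1)`).
#' @param collision_rate Fraction of cells given another cell's barcode
#'   combination (see [inject_collisions()]).
#' @param fragment_length Integer range of DNA fragment lengths (uniform).
#' @param read1_length Length of the genomic/cDNA read (Read1).
#' @param rt_sample Name of the RT index used for this sample (default:
#'   first entry of the design's RT table).
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return A `scmtr_scenario` object (list).
#' @seealso [simulate_experiment()]
#' @export
scenario <- function(n_cells = 500L,
                     cell_types = c(TypeA = 0.5, TypeB = 0.5),
                     targets = c("H3K4me3", "H3K27me3"),
                     igg = "IgG",
                     frip = 0.8,
                     genome_lengths = c(chr1 = 800000L, chr2 = 200000L),
                     n_peaks = 150L,
                     peak_width = 1000L,
                     peak_shared_frac = 0.5,
                     fragments_per_cell = NULL,
                     n_genes = 200L,
                     gene_width = 2000L,
                     umis_per_cell = c(mu = 2400, size = 5),
                     expression_shape = 0.5,
                     barcode_error_rate = 0,
                     duplication_factor = 2,
                     collision_rate = 0,
                     fragment_length = c(150L, 500L),
                     read1_length = 50L,
                     rt_sample = NULL,
                     seed = 1L) {
  if (is.null(fragments_per_cell)) {
    fragments_per_cell <- c(
      stats::setNames(rep(list(c(mu = 1300, size = 5)), length(targets)), targets),
      stats::setNames(list(c(mu = 200, size = 5)), igg))
  }
  if (length(frip) == 1L && is.null(names(frip)))
    frip <- stats::setNames(rep(frip, length(targets)), targets)
  sc <- structure(list(
    n_cells = as.integer(n_cells), cell_types = cell_types,
    targets = targets, igg = igg, frip = frip,
    genome_lengths = genome_lengths, n_peaks = as.integer(n_peaks),
    peak_width = as.integer(peak_width), peak_shared_frac = peak_shared_frac,
    fragments_per_cell = fragments_per_cell,
    n_genes = as.integer(n_genes), gene_width = as.integer(gene_width),
    umis_per_cell = umis_per_cell, expression_shape = expression_shape,
    barcode_error_rate = barcode_error_rate,
    duplication_factor = duplication_factor,
    collision_rate = collision_rate,
    fragment_length = as.integer(fragment_length),
    read1_length = as.integer(read1_length),
    rt_sample = rt_sample, seed = as.integer(seed)), class = "scmtr_scenario")
  validate_scenario(sc)
}

#' @rdname scenario
#' @param sc A `scmtr_scenario`.
#' @export
validate_scenario <- function(sc) {
  stopifnot(inherits(sc, "scmtr_scenario"))
  if (sc$n_cells < 1L) stop("n_cells must be positive")
  if (abs(sum(sc$cell_types) - 1) > 1e-8)
    stop("cell type proportions must sum to 1")
  if (any(sc$frip < 0 | sc$frip > 1)) stop("frip must be in [0, 1]")
  if (!all(sc$targets %in% names(sc$frip)))
    stop("frip must name every active target")
  all_targets <- c(sc$targets, sc$igg)
  if (!all(all_targets %in% names(sc$fragments_per_cell)))
    stop("fragments_per_cell must name every target incl. IgG")
  if (sc$collision_rate < 0 || sc$collision_rate >= 1)
    stop("collision_rate must be in [0, 1)")
  if (sc$barcode_error_rate < 0 || sc$barcode_error_rate > 1)
    stop("barcode_error_rate must be in [0, 1]")
  if (sc$duplication_factor < 1) stop("duplication_factor must be >= 1")
  if (sc$peak_width < sc$fragment_length[2])
    stop("peak_width must be >= max fragment length")
  if (sc$gene_width < sc$read1_length) stop("gene_width too small for reads")
  if (any(sc$genome_lengths < sc$peak_width))
    stop("contigs shorter than peak_width")
  sc
}

#' Read/write a scenario as YAML
#' @param sc A `scmtr_scenario`; `path` a YAML file path.
#' @rdname scenario
#' @export
write_scenario_yaml <- function(sc, path) {
  obj <- unclass(sc)
  obj$fragments_per_cell <- lapply(obj$fragments_per_cell, as.list)
  obj$cell_types <- as.list(obj$cell_types)
  obj$frip <- as.list(obj$frip)
  obj$umis_per_cell <- as.list(obj$umis_per_cell)
  obj$genome_lengths <- as.list(obj$genome_lengths)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname scenario
#' @export
read_scenario_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  listify <- function(x) stats::setNames(unlist(x), names(x))
  sc <- scenario(
    n_cells = obj$n_cells, cell_types = listify(obj$cell_types),
    targets = unlist(obj$targets), igg = obj$igg, frip = listify(obj$frip),
    genome_lengths = listify(obj$genome_lengths), n_peaks = obj$n_peaks,
    peak_width = obj$peak_width, peak_shared_frac = obj$peak_shared_frac,
    fragments_per_cell = lapply(obj$fragments_per_cell, listify),
    n_genes = obj$n_genes, gene_width = obj$gene_width,
    umis_per_cell = listify(obj$umis_per_cell),
    expression_shape = obj$expression_shape,
    barcode_error_rate = obj$barcode_error_rate,
    duplication_factor = obj$duplication_factor,
    collision_rate = obj$collision_rate,
    fragment_length = unlist(obj$fragment_length),
    read1_length = obj$read1_length, rt_sample = obj$rt_sample,
    seed = obj$seed)
  sc
}

# decode mixed-radix combination index into per-round barcode indices
.decode_combo <- function(idx0, sizes) {
  out <- matrix(0L, length(idx0), length(sizes))
  x <- idx0
  for (j in seq_along(sizes)) {
    out[, j] <- as.integer(x %% sizes[j])
    x <- x %/% sizes[j]
  }
  out
}

# sample peak slots: non-overlapping width-`pw` windows on a slot grid
.sample_slots <- function(n, genome_lengths, pw) {
  nslots <- pmax(0L, as.integer(genome_lengths %/% pw))
  tot <- sum(nslots)
  if (n > tot) stop("not enough room for ", n, " peaks")
  pick <- sort(sample.int(tot, n))
  contig_idx <- findInterval(pick - 1L, cumsum(c(0L, nslots)), left.open = FALSE)
  local_slot <- pick - cumsum(c(0L, nslots))[contig_idx] - 1L
  data.table::data.table(
    contig = names(genome_lengths)[contig_idx],
    slot = local_slot,
    start = local_slot * pw,
    end = (local_slot + 1L) * pw)
}

#' Reassign a fraction of cells to another cell's barcode combination
#'
#' Models barcode collisions: each selected cell takes the full BC1:BC2:BC3
#' combination of a randomly chosen other cell, so the pair becomes
#' indistinguishable downstream. Both members of a colliding pair are
#' flagged.
#'
#' @param cells Cell truth table (`data.table` with columns `cell`,
#'   `barcode`, `bc1`, `bc2`, `bc3`, ...), as produced by
#'   [simulate_experiment()].
#' @param rate Fraction of cells to reassign, in `[0, 1)`.
#' @param seed Integer seed.
#' @return The cell table with updated barcodes plus logical `collided` and
#'   character `collision_partner` columns.
#' @export
inject_collisions <- function(cells, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("collision rate must be in [0, 1)")
  cells <- data.table::copy(data.table::as.data.table(cells))
  cells[, `:=`(collided = FALSE, collision_partner = NA_character_)]
  n <- nrow(cells)
  m <- as.integer(round(rate * n))
  if (m == 0L) return(cells[])
  if (m >= n) stop("collision rate leaves no unaffected partner cells")
  .with_seed(seed, {
    victims <- sample.int(n, m)
    # partners drawn from non-victims so each colliding pair ends up with
    # one well-defined shared combination
    pool <- setdiff(seq_len(n), victims)
    partners <- pool[sample.int(length(pool), m, replace = TRUE)]
  })
  for (col in c("barcode", "bc1", "bc2", "bc3"))
    data.table::set(cells, victims, col, cells[[col]][partners])
  cells[victims, `:=`(collided = TRUE, collision_partner = cells$cell[partners])]
  cells[partners, collided := TRUE]
  cells[]
}

#' Simulate a full scMTR-seq experiment with ground truth
#'
#' Draws a random genome, peak and gene models, cells with distinct barcode
#' combinations (collisions only when requested), per-cell DNA molecules per
#' target (in-peak with the scenario FRiP, fully inside a peak of the cell's
#' type; background placed outside that target's peaks) and RNA molecules
#' (gene chosen from type-specific expression rates, random 8-nt UMI), PCR
#' duplicates, and finally the reads: Read1 is the fragment's 5' end (DNA)
#' or a gene-strand cDNA substring (RNA); Read2 is
#' `BC3 + linker + BC2 + linker + BC1 + linker + ID + UMI` (127 nt) with
#' per-base substitution errors at the scenario rate.
#'
#' @param sc A [scenario()].
#' @param design A [barcode_design()]; defaults to the packaged design.
#' @param out_dir Optional directory: when given, FASTQ, truth tables, peak
#'   and gene BEDs, genome FASTA and the design/scenario are written there.
#' @return A `scmtr_sim` list: `reads` (data.table `read_id`, `read1`,
#'   `read2`), `truth` (`cells`, `cell_counts`, `reads` tables), `genome`
#'   (named character), `peaks`, `genes`, `scenario`, `design`, `rt_sample`.
#' @examples
#' sc <- scenario(n_cells = 20, genome_lengths = c(chr1 = 50000L),
#'                n_peaks = 10, n_genes = 20,
#'                fragments_per_cell = list(H3K4me3 = c(mu = 40, size = 10),
#'                                          H3K27me3 = c(mu = 40, size = 10),
#'                                          IgG = c(mu = 10, size = 10)),
#'                umis_per_cell = c(mu = 50, size = 10), seed = 7)
#' sim <- simulate_experiment(sc)
#' sim$truth$cells[1:3]
#' @export
simulate_experiment <- function(sc, design = default_barcode_design(),
                                out_dir = NULL) {
  validate_scenario(sc)
  layout <- design$layout
  if (attr(layout, "min_read_length") !=
      sum(nchar(c(design$rounds$BC1[1], design$rounds$BC2[1],
                  design$rounds$BC3[1], design$antibody_index[1], "NNNNNNNN"))) +
      sum(nchar(design$linkers)))
    stop("design layout does not match barcode + linker lengths")
  missing_ab <- setdiff(sc$targets, names(design$antibody_index))
  if (length(missing_ab))
    stop("targets missing from antibody index: ", paste(missing_ab, collapse = ", "))
  if (!sc$igg %in% names(design$antibody_index))
    stop("IgG target missing from antibody index")
  rt_sample <- sc$rt_sample %||% names(design$rt_index)[1]

  .with_seed(sc$seed, {
    ## genome ---------------------------------------------------------------
    genome <- vapply(sc$genome_lengths, .random_sequence, character(1))
    names(genome) <- names(sc$genome_lengths)

    ## peaks: shared + type-specific slots per target -----------------------
    types <- names(sc$cell_types)
    pw <- sc$peak_width
    n_shared <- as.integer(round(sc$peak_shared_frac * sc$n_peaks))
    n_spec <- sc$n_peaks - n_shared
    peaks <- list()
    for (tg in sc$targets) {
      slots <- .sample_slots(n_shared + n_spec * length(types),
                             sc$genome_lengths, pw)
      shared <- slots[seq_len(n_shared)]
      rest <- slots[-seq_len(n_shared)]
      for (i in seq_along(types)) {
        own <- rest[seq_len(n_spec) + (i - 1L) * n_spec]
        peaks[[paste(tg, types[i])]] <- data.table::data.table(
          target = tg, cell_type = types[i],
          rbind(shared, own))
      }
    }
    peaks <- if (length(peaks)) data.table::rbindlist(peaks) else
      data.table::data.table(target = character(), cell_type = character(),
                             contig = character(), slot = integer(),
                             start = integer(), end = integer())

    ## genes ----------------------------------------------------------------
    gene_slots <- .sample_slots(sc$n_genes, sc$genome_lengths, sc$gene_width)
    genes <- data.table::data.table(
      gene_id = sprintf("gene%04d", seq_len(sc$n_genes)),
      contig = gene_slots$contig, start = gene_slots$start,
      end = gene_slots$end,
      strand = sample(c("+", "-"), sc$n_genes, replace = TRUE))

    ## per-type expression rates
    expr <- vapply(types, function(t) {
      r <- stats::rgamma(sc$n_genes, shape = sc$expression_shape)
      r / sum(r)
    }, numeric(sc$n_genes))

    ## cells ----------------------------------------------------------------
    sizes <- vapply(design$rounds, length, integer(1))  # BC1, BC2, BC3
    B <- prod(sizes)
    if (sc$n_cells > B) stop("more cells than barcode combinations")
    combo <- .decode_combo(sample.int(B, sc$n_cells) - 1L, sizes)
    cells <- data.table::data.table(
      cell = sprintf("cell%05d", seq_len(sc$n_cells)),
      bc1 = design$rounds$BC1[combo[, 1] + 1L],
      bc2 = design$rounds$BC2[combo[, 2] + 1L],
      bc3 = design$rounds$BC3[combo[, 3] + 1L],
      cell_type = sample(types, sc$n_cells, replace = TRUE,
                         prob = sc$cell_types))
    cells[, barcode := paste(bc1, bc2, bc3, sep = ":")]
    cells <- inject_collisions(cells, sc$collision_rate,
                               seed = .stage_seed(sc$seed, 17L))

    ## DNA molecules --------------------------------------------------------
    all_targets <- c(sc$targets, sc$igg)
    dna <- list()
    for (tg in all_targets) {
      par <- sc$fragments_per_cell[[tg]]
      n_mol <- stats::rnbinom(sc$n_cells, size = par[["size"]], mu = par[["mu"]])
      ci <- rep(seq_len(sc$n_cells), n_mol)
      ntot <- length(ci)
      if (ntot == 0L) next
      fr <- if (tg %in% names(sc$frip)) sc$frip[[tg]] else 0
      inp <- stats::rbinom(ntot, 1L, fr) == 1L
      len <- sample(seq(sc$fragment_length[1], sc$fragment_length[2]),
                    ntot, replace = TRUE)
      mol <- data.table::data.table(
        cell_idx = ci, target = tg, in_peak = inp, len = len,
        contig = NA_character_, start = NA_integer_)
      tpk <- peaks[target == tg]
      pk_slots <- unique(tpk[, paste(contig, slot)])
      clen <- sc$genome_lengths
      cprob <- clen / sum(clen)
      place <- function(rows) {
        # in-peak: uniform over the cell-type's peaks for this target,
        # fragment fully inside the peak
        for (ty in types) {
          rws <- rows[inp[rows] & cells$cell_type[ci[rows]] == ty]
          if (!length(rws)) next
          pk <- tpk[cell_type == ty]
          j <- sample.int(nrow(pk), length(rws), replace = TRUE)
          off <- floor(stats::runif(length(rws)) * (pw - mol$len[rws] + 1L))
          data.table::set(mol, rws, "contig", pk$contig[j])
          data.table::set(mol, rws, "start", as.integer(pk$start[j] + off))
        }
        # background: uniform, rejected out of this target's peak slots
        todo <- rows[!inp[rows]]
        while (length(todo)) {
          cidx <- sample.int(length(clen), length(todo), replace = TRUE,
                             prob = cprob)
          st <- floor(stats::runif(length(todo)) *
                        (clen[cidx] - mol$len[todo] + 1L))
          data.table::set(mol, todo, "contig", names(clen)[cidx])
          data.table::set(mol, todo, "start", as.integer(st))
          if (length(pk_slots)) {
            s1 <- paste(mol$contig[todo], mol$start[todo] %/% pw)
            s2 <- paste(mol$contig[todo],
                        (mol$start[todo] + mol$len[todo] - 1L) %/% pw)
            todo <- todo[s1 %in% pk_slots | s2 %in% pk_slots]
          } else todo <- integer(0)
        }
      }
      place(seq_len(ntot))
      # distinct molecules within a cell are distinct insertion events:
      # redraw any two molecules of one cell sharing a read start, so that
      # position-only deduplication recovers molecules exactly
      repeat {
        key <- paste(mol$cell_idx, mol$contig, mol$start)
        clash <- which(duplicated(key))
        if (!length(clash)) break
        place(clash)
      }
      dna[[tg]] <- mol
    }
    dna <- data.table::rbindlist(dna)
    dna[, `:=`(end = start + len, len = NULL)]
    dna[, modality := "DNA"]
    dna[, strand := "+"]
    dna[, umi := .kmer_table(8L)[sample.int(65536L, .N, replace = TRUE)]]

    ## RNA molecules --------------------------------------------------------
    n_umi <- stats::rnbinom(sc$n_cells, size = sc$umis_per_cell[["size"]],
                            mu = sc$umis_per_cell[["mu"]])
    ci <- rep(seq_len(sc$n_cells), n_umi)
    rna <- data.table::data.table(cell_idx = ci)
    rna[, gene_idx := 0L]
    for (i in seq_along(types)) {
      rows <- which(cells$cell_type[ci] == types[i])
      if (length(rows))
        data.table::set(rna, rows, "gene_idx",
                        sample.int(sc$n_genes, length(rows), replace = TRUE,
                                   prob = expr[, i]))
    }
    off <- floor(stats::runif(nrow(rna)) * (sc$gene_width - sc$read1_length + 1L))
    rna[, `:=`(
      target = rt_sample, in_peak = NA,
      contig = genes$contig[gene_idx],
      start = as.integer(genes$start[gene_idx] + off),
      strand = genes$strand[gene_idx],
      modality = "RNA")]
    rna[, end := start + sc$read1_length]
    rna[, umi := .kmer_table(8L)[sample.int(65536L, .N, replace = TRUE)]]
    rna[, gene_idx := NULL]

    mol <- data.table::rbindlist(list(dna, rna), use.names = TRUE)
    mol[, molecule_id := seq_len(.N)]

    ## truth per-cell counts (molecules and unique after dedup rules) -------
    dna_counts <- mol[modality == "DNA",
      .(n_molecules = .N,
        n_unique = data.table::uniqueN(paste(contig, start, end))),
      by = .(cell_idx, modality, target)]
    rna_counts <- mol[modality == "RNA",
      .(n_molecules = .N,
        n_unique = data.table::uniqueN(paste(contig, start, strand, umi))),
      by = .(cell_idx, modality, target)]
    cell_counts <- data.table::rbindlist(list(dna_counts, rna_counts))
    cell_counts[, `:=`(cell = cells$cell[cell_idx],
                       barcode = cells$barcode[cell_idx],
                       cell_type = cells$cell_type[cell_idx])]

    ## PCR duplication and read emission ------------------------------------
    copies <- 1L + stats::rpois(nrow(mol), sc$duplication_factor - 1)
    ridx <- rep(seq_len(nrow(mol)), copies)
    truth_reads <- mol[ridx]
    truth_reads[, read_id := seq_len(.N)]
    truth_reads[, `:=`(cell = cells$cell[cell_idx],
                       barcode = cells$barcode[cell_idx],
                       cell_type = cells$cell_type[cell_idx])]

    ## Read1: DNA fragment 5' end / RNA gene-strand cDNA
    r1len <- sc$read1_length
    read1 <- substring(genome[truth_reads$contig],
                       truth_reads$start + 1L,
                       truth_reads$start + r1len)
    neg <- which(truth_reads$modality == "RNA" & truth_reads$strand == "-")
    if (length(neg)) read1[neg] <- .revcomp(read1[neg])

    ## Read2: BC3 + L + BC2 + L + BC1 + L + ID + UMI
    id_seq <- character(nrow(truth_reads))
    is_dna <- truth_reads$modality == "DNA"
    id_seq[is_dna] <- design$antibody_index[truth_reads$target[is_dna]]
    id_seq[!is_dna] <- design$rt_index[[rt_sample]]
    read2 <- paste0(cells$bc3[truth_reads$cell_idx], design$linkers[1],
                    cells$bc2[truth_reads$cell_idx], design$linkers[2],
                    cells$bc1[truth_reads$cell_idx], design$linkers[3],
                    id_seq, truth_reads$umi)

    ## substitution errors on Read2
    if (sc$barcode_error_rate > 0) {
      L <- nchar(read2[1])
      ncell_bases <- length(read2) * L
      n_err <- stats::rbinom(1L, ncell_bases, sc$barcode_error_rate)
      if (n_err > 0L) {
        hit <- sample(ncell_bases, n_err)
        erow <- (hit - 1L) %/% L + 1L
        epos <- (hit - 1L) %% L + 1L
        cur <- substring(read2[erow], epos, epos)
        sub <- .bases[(match(cur, .bases) - 1L + sample.int(3L, n_err, TRUE)) %% 4L + 1L]
        # apply sequentially within a read (multiple hits per read possible)
        ed <- data.table::data.table(erow, epos, sub)
        ed[, pass := seq_len(.N), by = erow]
        for (p in seq_len(max(ed$pass))) {
          ep <- ed[pass == p]
          substr(read2[ep$erow], ep$epos, ep$epos) <- ep$sub
        }
      }
    }

    reads <- data.table::data.table(read_id = truth_reads$read_id,
                                    read1 = read1, read2 = read2)
    truth_reads[, cell_idx := NULL]

    sim <- structure(list(
      reads = reads,
      truth = list(cells = cells, cell_counts = cell_counts,
                   reads = truth_reads),
      genome = genome,
      peaks = peaks[, .(target, cell_type, contig, start, end)],
      genes = genes,
      scenario = sc, design = design, rt_sample = rt_sample),
      class = "scmtr_sim")
  })
  if (!is.null(out_dir)) write_simulation(sim, out_dir)
  sim
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.scmtr_sim <- function(x, ...) {
  cat("scmtr_sim:", nrow(x$truth$cells), "cells,",
      nrow(x$reads), "reads (",
      sum(x$truth$reads$modality == "DNA"), "DNA /",
      sum(x$truth$reads$modality == "RNA"), "RNA )\n")
  invisible(x)
}

#' Write simulation artifacts to disk
#'
#' Writes paired gzipped FASTQ (`R1.fastq.gz`, `R2.fastq.gz`), truth tables
#' (TSV), per-target peak BED (0-based half-open, union over cell types),
#' gene BED, genome FASTA, the design whitelist TSV/YAML and the scenario
#' YAML.
#'
#' @param sim A `scmtr_sim` from [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nm <- sprintf("r%08d", sim$reads$read_id)
  write_fastq(nm, sim$reads$read1, file.path(dir, "R1.fastq.gz"))
  write_fastq(nm, sim$reads$read2, file.path(dir, "R2.fastq.gz"))
  data.table::fwrite(sim$truth$cells, file.path(dir, "truth_cells.tsv"),
                     sep = "\t")
  data.table::fwrite(sim$truth$cell_counts,
                     file.path(dir, "truth_cell_counts.tsv"), sep = "\t")
  data.table::fwrite(sim$truth$reads, file.path(dir, "truth_reads.tsv.gz"),
                     sep = "\t")
  for (tg in unique(sim$peaks$target)) {
    un <- unique(sim$peaks[target == tg, .(contig, start, end)])
    data.table::fwrite(un[order(contig, start)],
                       file.path(dir, paste0("peaks_", tg, ".bed")),
                       sep = "\t", col.names = FALSE)
  }
  data.table::fwrite(
    sim$genes[, .(contig, start, end, gene_id, score = 0L, strand)],
    file.path(dir, "genes.bed"), sep = "\t", col.names = FALSE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$genome),
                              file.path(dir, "genome.fa"))
  write_design_whitelists(sim$design, file.path(dir, "whitelists.tsv"))
  write_design_yaml(sim$design, file.path(dir, "design.yaml"))
  write_scenario_yaml(sim$scenario, file.path(dir, "scenario.yaml"))
  invisible(dir)
}
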