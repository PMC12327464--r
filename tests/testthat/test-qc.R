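test_that("FRiP handles boundary cases exactly and respects peak splitting", {
  cell <- "c1"
  frags <- data.table(contig = "chr1", start = c(0L, 100L, 200L, 900L),
                      end = c(50L, 150L, 250L, 950L),
                      cell_id = cell, target = "H3K4me3")
  # 3 of 4 fragments overlap the peak region
  pk <- data.table(contig = "chr1", start = 0L, end = 260L)
  expect_equal(frip(frags, pk)$per_target$frip, 0.75)
  # all inside peaks -> 1; whole-genome peak -> 1
  expect_equal(frip(frags, data.table(contig = "chr1", start = 0L,
                                      end = 1000L))$per_target$frip, 1)
  # invariance to splitting a peak into touching pieces and to order
  pk_split <- data.table(contig = "chr1", start = c(130L, 0L),
                         end = c(260L, 130L))
  expect_equal(frip(frags, pk_split)$per_cell$frip,
               frip(frags, pk)$per_cell$frip)
  # a single base of overlap counts
  edge <- data.table(contig = "chr1", start = c(49L), end = c(60L))
  expect_equal(frip(frags[1], edge)$per_target$frip, 1)
  # missing cells are absent, not zero
  res <- frip(frags, pk)
  expect_false("c2" %in% res$per_cell$cell_id)
})

test_that("cell filters are strict and monotone with exact hand enumeration", {
  cs <- data.table(
    cell_id = c("c1", "c2", "c3", "c4", "c5"),
    dna_unique = c(2500L, 2501L, 9000L, 2400L, 5000L),
    rna_unique = c(3000L, 2001L, 2000L, 5000L, NA))
  res <- filter_cells(cs)
  # hand enumeration: c1 fails DNA (strict), c2 passes both boundaries,
  # c3 fails RNA (strict), c4 fails DNA, c5 has no RNA
  expect_identical(res$pass_ids, "c2")
  expect_equal(res$n_pass, 1)
  expect_equal(filter_cells(cs, n_input = 10)$recovery, 0.1)

  # monotone: raising thresholds never adds cells
  lo <- filter_cells(cs, dna_min = 1000L, rna_min = 1000L)
  hi <- filter_cells(cs, dna_min = 3000L, rna_min = 2500L)
  expect_true(all(hi$pass_ids %in% lo$pass_ids))
  expect_error(filter_cells(cs, dna_min = -1), "non-negative")
})

test_that("Cramer's V equals the brute-force chi-square value on 2x2 tables", {
  # enumerate tables, reconstruct matrices with those margins
  tabs <- list(matrix(c(8, 3, 2, 7), 2),
               matrix(c(20, 5, 1, 30), 2),
               matrix(c(4, 4, 4, 4), 2),
               matrix(c(50, 1, 2, 60), 2))
  for (tab in tabs) {
    a <- rep(c(0, 0, 1, 1), times = as.vector(tab))
    b <- rep(c(0, 1, 0, 1), times = as.vector(tab))
    v <- cramers_v(matrix(a, ncol = 1), matrix(b, ncol = 1))
    t2 <- table(factor(a > 0, c(FALSE, TRUE)), factor(b > 0, c(FALSE, TRUE)))
    expect_equal(v, sqrt(brute_chisq_2x2(t2) / sum(t2)))
  }
  # worked 2x2 example [[8,2],[3,7]] against the closed form
  tab <- matrix(c(8, 3, 2, 7), 2)
  a <- rep(c(0, 0, 1, 1), times = as.vector(tab))
  b <- rep(c(0, 1, 0, 1), times = as.vector(tab))
  expect_equal(cramers_v(cbind(a), cbind(b)),
               sqrt(20 * (8 * 7 - 2 * 3)^2 / (10 * 10 * 11 * 9) / 20))
})

test_that("Cramer's V is 1 on identical matrices, ~0 on independent ones, symmetric", {
  set.seed(3)
  m <- matrix(rbinom(400, 1, 0.5), 20)
  expect_equal(cramers_v(m, m), 1)
  a <- matrix(rbinom(1e4, 1, 0.5), 100)
  b <- matrix(rbinom(1e4, 1, 0.5), 100)
  expect_lte(cramers_v(a, b), 0.05)
  expect_equal(cramers_v(a, b), cramers_v(b, a))
  # degenerate margin warns and returns 0
  expect_warning(v0 <- cramers_v(matrix(1, 3, 3), m[1:3, 1:3]), "degenerate")
  expect_equal(v0, 0)
})

test_that("kNN label agreement behaves on separable, permuted and forced cases", {
  set.seed(4)
  n <- 120
  x <- rbind(matrix(rnorm(n / 2 * 2, 0), ncol = 2),
             matrix(rnorm(n / 2 * 2, 50), ncol = 2))
  lab <- rep(c("a", "b"), each = n / 2)
  expect_equal(knn_label_agreement(x, lab, k = 20), 1)
  # k = n - 1 forces every other cell into the neighbourhood:
  # agreement equals (class size - 1) / (n - 1) averaged = class proportion
  # adjusted for self-exclusion
  exp_forced <- mean(c(rep((n / 2 - 1) / (n - 1), n)))
  expect_equal(knn_label_agreement(x, lab, k = n - 1), exp_forced)
  # random labels on one cloud: agreement near 1/2
  y <- matrix(rnorm(n * 2), ncol = 2)
  perm <- sample(lab)
  ag <- knn_label_agreement(y, perm, k = 20)
  se <- sqrt(0.25 / (n * 20))  # conservative scale for the mean fraction
  expect_lt(abs(ag - 0.5), 10 * se)
  expect_error(knn_label_agreement(x, lab, k = 0), "positive")
  expect_error(knn_label_agreement(x, lab, k = n), "smaller")
})

test_that("qc summary is deterministic and consistent with its inputs", {
  sim <- simulate_experiment(tiny_scenario(seed = 71))
  ann <- demux_reads(sim$reads$read2, sim$design)$annotations
  ok <- which(ann$status == "valid")
  nm <- make_read_names(ann$cell_id[ok], ann$target_or_rt[ok], ann$umi[ok], ok)
  aln <- align_exact(setNames(sim$reads$read1[ok], nm), sim$genome)
  is_dna <- ann$modality[ok][match(aln$records$name, nm)] == "DNA"
  dna <- dedup_dna(aln$records[is_dna])
  rna <- dedup_rna(aln$records[!is_dna])
  peaks <- unique(sim$peaks[, .(contig, start, end)])
  rep1 <- qc_summary(NULL, dna$fragments, rna$molecules, peaks, sim$design,
                     dna_min = 100L, rna_min = 40L,
                     n_input_cells = sim$scenario$n_cells)
  rep2 <- qc_summary(NULL, dna$fragments, rna$molecules, peaks, sim$design,
                     dna_min = 100L, rna_min = 40L,
                     n_input_cells = sim$scenario$n_cells)
  expect_identical(rep1$per_cell, rep2$per_cell)
  expect_identical(rep1$per_target, rep2$per_target)

  # duplication factor 2 -> per-target duplication rate near 0.5
  per <- rep1$per_target[target != "RNA"]
  for (i in seq_len(nrow(per))) {
    n_mol <- per$unique_reads[i]
    expect_lt(abs(per$duplication_rate[i] - 0.5), 3 / sqrt(n_mol))
  }
  # rates bounded, collision estimates present
  expect_true(all(per$duplication_rate >= 0 & per$duplication_rate <= 1))
  expect_equal(rep1$dataset$collision_estimate_linear,
               collision_rate(30, 110592))

  # no duplicates injected -> duplication rate exactly 0
  sc0 <- tiny_scenario(seed = 72, duplication_factor = 1)
  sim0 <- simulate_experiment(sc0)
  tr0 <- sim0$truth$reads[modality == "DNA"]
  rec0 <- data.table(name = make_read_names(tr0$barcode, tr0$target, tr0$umi,
                                            tr0$read_id),
                     contig = tr0$contig, start = tr0$start, end = tr0$end)
  d0 <- dedup_dna(rec0)
  # position-only dedup can merge distinct molecules at the same spot, so
  # assert against the truth table's unique-position count
  expect_equal(nrow(d0$fragments),
               sum(sim0$truth$cell_counts[modality == "DNA", n_unique]))
})

test_that("qc report writes JSON and per-cell TSV", {
  sim <- simulate_experiment(tiny_scenario(seed = 73, n_cells = 10L))
  tr <- sim$truth$reads
  dna_t <- tr[modality == "DNA"]
  rna_t <- tr[modality == "RNA"]
  dna <- dedup_dna(data.table(name = make_read_names(dna_t$barcode, dna_t$target,
                                                     dna_t$umi, dna_t$read_id),
                              contig = dna_t$contig, start = dna_t$start,
                              end = dna_t$end))
  rna <- dedup_rna(data.table(name = make_read_names(rna_t$barcode, "RT01",
                                                     rna_t$umi, rna_t$read_id),
                              contig = rna_t$contig, start = rna_t$start,
                              end = rna_t$end, strand = rna_t$strand))
  rep <- qc_summary(NULL, dna$fragments, rna$molecules, NULL, sim$design)
  dir <- tempfile()
  write_qc_report(rep, dir)
  js <- jsonlite::read_json(file.path(dir, "qc_report.json"))
  expect_true(all(c("per_target", "filter", "dataset") %in% names(js)))
  tsv <- fread(file.path(dir, "qc_per_cell.tsv"))
  expect_equal(nrow(tsv), nrow(rep$per_cell))
  unlink(dir, recursive = TRUE)
})
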