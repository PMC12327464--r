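test_that("DNA dedup collapses by position only and conserves read counts", {
  cell <- "AAAAAAAA:CCCCCCCC:GGGGGGGG"
  rec <- data.table(
    name = make_read_names(rep(cell, 4), "H3K4me3",
                           c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG", "AAAAAAAA")),
    contig = "chr1", start = c(100L, 100L, 100L, 500L),
    end = c(250L, 250L, 250L, 700L))
  res <- dedup_dna(rec)
  expect_equal(nrow(res$fragments), 2)
  # three same-position reads with different UMIs collapse to one fragment
  expect_equal(res$fragments[start == 100L, dup_count], 3L)
  expect_equal(sum(res$fragments$dup_count), nrow(rec))

  # identical positions in different cells stay separate
  cell2 <- "TTTTTTTT:CCCCCCCC:GGGGGGGG"
  rec2 <- rbind(rec[1], rec[1])
  rec2$name[2] <- make_read_names(cell2, "H3K4me3", "AAAAAAAA", 9)
  expect_equal(nrow(dedup_dna(rec2)$fragments), 2)
})

test_that("RNA dedup keys on position plus UMI and is idempotent", {
  cell <- "AAAAAAAA:CCCCCCCC:GGGGGGGG"
  rec <- data.table(
    name = make_read_names(rep(cell, 7), "RT01",
                           c("AAAAAAAA", "TTTTTTTT", rep("GGGGGGGG", 5))),
    contig = "chr1", start = 100L, end = 150L, strand = "+")
  res <- dedup_rna(rec)
  # same position, two UMIs -> two molecules; five identical copies -> one
  expect_equal(nrow(res$molecules), 3)
  expect_equal(res$molecules[umi == "GGGGGGGG", dup_count], 5L)
  expect_equal(sum(res$molecules$dup_count), nrow(rec))

  # idempotence: dedup of the deduplicated stream changes nothing
  rec2 <- data.table(
    name = make_read_names(rep(cell, nrow(res$molecules)), "RT01",
                           res$molecules$umi),
    contig = res$molecules$contig, start = res$molecules$pos,
    end = res$molecules$pos + 50L, strand = res$molecules$strand)
  res2 <- dedup_rna(rec2)
  expect_equal(res2$molecules[, .(contig, pos, strand, umi)],
               res$molecules[, .(contig, pos, strand, umi)])

  # 5' anchor is strand-aware: a minus-strand record keys on end - 1
  neg <- data.table(name = make_read_names(cell, "RT01", "AAAAAAAA"),
                    contig = "chr1", start = 100L, end = 150L, strand = "-")
  expect_equal(dedup_rna(neg)$molecules$pos, 149L)
})

test_that("both dedup rules equal brute-force grouping on random records", {
  set.seed(8)
  n <- 10000
  cells <- sprintf("AAAAAAA%d:CCCCCCCC:GGGGGGGG", sample(1:9, n, TRUE))
  umis <- sprintf("ACGTACG%d", sample(1:4, n, TRUE))
  start <- sample(1:300, n, TRUE)
  rec <- data.table(
    name = make_read_names(cells, "H3K4me3", umis),
    contig = sample(c("chr1", "chr2"), n, TRUE),
    start = start, end = start + sample(150:200, n, TRUE), strand = "+")

  res_d <- dedup_dna(rec)
  brute_d <- rec[, .(n = .N),
                 by = .(cell = sub(":H3K4me3:.*", "", name), contig, start, end)]
  expect_equal(nrow(res_d$fragments), nrow(brute_d))
  expect_equal(sort(res_d$fragments$dup_count), sort(brute_d$n))
  expect_equal(sum(res_d$fragments$dup_count), n)

  res_r <- dedup_rna(rec)
  brute_r <- rec[, .(n = .N),
                 by = .(cell = sub(":H3K4me3:.*", "", name), contig, start,
                        umi = sub(".*H3K4me3:(........):.*", "\\1", name))]
  expect_equal(nrow(res_r$molecules), nrow(brute_r))
  expect_equal(sort(res_r$molecules$dup_count), sort(brute_r$n))
  expect_equal(sum(res_r$molecules$dup_count), n)
})

test_that("gene counting assigns unique overlaps and drops the rest", {
  genes <- data.table(contig = "chr1", start = c(0L, 1000L, 1900L),
                      end = c(500L, 2000L, 2500L),
                      gene_id = c("g1", "g2", "g3"), score = 0L, strand = "+")
  cell <- "AAAAAAAA:CCCCCCCC:GGGGGGGG"
  mols <- data.table(
    contig = "chr1",
    pos = c(100L, 1100L, 700L, 1950L),  # g1, g2, intergenic, ambiguous g2/g3
    strand = "+", cell_id = cell, rt = "RT01",
    umi = sprintf("ACGTACG%d", 1:4), dup_count = 1L)
  res <- count_genes(mols, genes)
  expect_equal(sum(res$matrix), 2)
  expect_equal(as.numeric(res$matrix["g1", cell]), 1)
  expect_equal(as.numeric(res$matrix["g2", cell]), 1)
  expect_equal(res$stats$n_unassigned, 1)
  expect_equal(res$stats$n_ambiguous, 1)

  # matrix total equals assigned molecules on simulated data, and per-gene
  # totals track the scenario's expression expectation
  sim <- simulate_experiment(tiny_scenario(seed = 61, n_cells = 100L))
  tr <- unique(sim$truth$reads[modality == "RNA"], by = "molecule_id")
  mols2 <- unique(tr[, .(contig, pos = fifelse(strand == "-", end - 1L, start),
                         strand, cell_id = barcode, rt = "RT01", umi)])
  mols2[, dup_count := 1L]
  res2 <- count_genes(mols2, sim$genes)
  expect_equal(sum(res2$matrix), res2$stats$n_assigned)
  expect_equal(res2$stats$n_unassigned + res2$stats$n_ambiguous +
                 res2$stats$n_assigned, nrow(mols2))
  # genes are non-overlapping and molecules start inside a gene: all assigned
  expect_equal(res2$stats$n_assigned, nrow(mols2))
})

test_that("fragment files round-trip and bin matrices count overlaps", {
  frags <- data.table(contig = c("chr1", "chr1", "chr2"),
                      start = c(0L, 4900L, 100L),
                      end = c(100L, 5100L, 200L),
                      cell_id = c("c1", "c1", "c2"),
                      target = "H3K4me3", dup_count = c(2L, 1L, 3L))
  path <- tempfile(fileext = ".fragments.tsv.gz")
  write_fragments(frags, path)
  back <- read_fragments(path, target = "H3K4me3")
  expect_equal(back[, .(contig, start, end, cell_id, dup_count)],
               frags[order(contig, start), .(contig, start, end, cell_id,
                                             dup_count)])

  gl <- c(chr1 = 10000L, chr2 = 1000L)
  m <- make_bin_matrix(frags, gl, bin_size = 5000L)
  expect_equal(dim(m), c(3L, 2L))  # 2 bins chr1 + 1 truncated bin chr2
  expect_equal(as.numeric(m["chr1:0-5000", "c1"]), 2)    # (0,100) + (4900,5100)
  expect_equal(as.numeric(m["chr1:5000-10000", "c1"]), 1)  # spans the boundary
  expect_equal(as.numeric(m["chr2:0-1000", "c2"]), 1)

  empty <- make_bin_matrix(frags[0], gl, bin_size = 5000L, cells = c("c1"))
  expect_equal(dim(empty), c(3L, 1L))
  expect_equal(sum(empty), 0)

  d <- tempfile()
  write_mtx(m, d)
  m2 <- read_mtx(d)
  expect_equal(as.matrix(m2), as.matrix(m))
  unlink(d, recursive = TRUE)
})
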