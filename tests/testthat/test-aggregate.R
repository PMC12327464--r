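gl <- c(chr1 = 10000L, chr2 = 3000L)

simple_frags <- function() {
  data.table(contig = c("chr1", "chr1", "chr2", "chr1"),
             start = c(10L, 5100L, 100L, 60L),
             end = c(60L, 5200L, 200L, 120L),
             cell_id = c("c1", "c1", "c2", "c2"),
             target = "H3K4me3")
}

test_that("pseudobulk counts fragment-bin overlaps and conserves partitions", {
  fr <- simple_frags()
  tr <- pseudobulk(fr, gl, bin_size = 50L)[["H3K4me3"]]
  expect_equal(tr$values$chr1[1], 1)        # (10,60) touches bin 0
  expect_equal(tr$values$chr1[2], 2)        # (10,60) and (60,120) touch bin 1
  expect_equal(tr$values$chr1[103], 1)      # (5100,5200) bin 102 (0-based)
  expect_equal(length(tr$values$chr2), 60)

  # group tracks sum to the all-cell track for any partition, and cell
  # order does not matter
  groups <- c(c1 = "g1", c2 = "g2")
  by_grp <- pseudobulk(fr, gl, bin_size = 50L, groups = groups)
  total <- track_values(tr)
  summed <- track_values(by_grp[["g1.H3K4me3"]]) +
    track_values(by_grp[["g2.H3K4me3"]])
  expect_equal(summed, total)
  tr_perm <- pseudobulk(fr[c(3, 1, 4, 2)], gl, bin_size = 50L)[["H3K4me3"]]
  expect_equal(tr_perm$values, tr$values)

  # conservation of total fragment-bin overlap counts: each of the four
  # fragments spans a bin boundary, so 8 overlaps in total
  expect_equal(track_total(tr), 8)
})

test_that("IgG ratio normalization follows (s + pc) / (c + pc)", {
  sig <- binned_track(list(chr1 = c(3, 1, 0), chr2 = c(1)), 5000L,
                      c(chr1 = 15000L, chr2 = 4000L))
  ctl <- binned_track(list(chr1 = c(1, 1, 0), chr2 = c(1)), 5000L,
                      c(chr1 = 15000L, chr2 = 4000L))
  r <- igg_normalize(sig, ctl, pseudocount = 1)
  expect_equal(r$values$chr1, c(2, 1, 1))
  expect_equal(r$values$chr2, 1)
  # signal == control -> ratio 1 everywhere
  same <- igg_normalize(ctl, ctl)
  expect_true(all(track_values(same) == 1))
  # pseudocount 0 with a zero control bin is a division guard error
  expect_error(igg_normalize(sig, ctl, pseudocount = 0), "zero control")
  mis <- binned_track(list(chr1 = c(3, 1, 0)), 5000L, c(chr1 = 15000L))
  expect_error(igg_normalize(sig, mis), "share binning")
})

test_that("track correlation is scale-invariant, 1 on identity, ~0 on noise", {
  set.seed(12)
  n <- 10000
  a <- binned_track(list(chr1 = rpois(n, 5)), 5000L, c(chr1 = 5000L * n))
  b <- binned_track(list(chr1 = rpois(n, 5)), 5000L, c(chr1 = 5000L * n))
  expect_equal(track_correlation(a, a), 1)
  a2 <- binned_track(list(chr1 = 2 * a$values$chr1 + 7), 5000L,
                     c(chr1 = 5000L * n))
  expect_equal(track_correlation(a, a2), 1)
  expect_lte(abs(track_correlation(a, b)), 0.05)

  # re-binning sums: a 50-bp track correlated at 5 kb equals manual rebin
  v <- rpois(200, 3)
  t50 <- binned_track(list(chr1 = v), 50L, c(chr1 = 10000L))
  t5k <- rebin_track(t50, 5000L)
  expect_equal(t5k$values$chr1, c(sum(v[1:100]), sum(v[101:200])))
  expect_error(rebin_track(t50, 75L), "multiple")
})

test_that("saturation curves are deterministic, exact at full depth, rising", {
  sim <- simulate_experiment(tiny_scenario(seed = 81, n_cells = 60L))
  tr <- sim$truth$reads[modality == "DNA" & target == "H3K4me3"]
  frags <- unique(tr[, .(contig, start, end, cell_id = barcode)])
  frags[, target := "H3K4me3"]
  glx <- sim$scenario$genome_lengths
  reference <- pseudobulk(frags, glx, bin_size = 5000L)[["H3K4me3"]]

  n_all <- uniqueN(frags$cell_id)
  curve <- saturation_curve(frags, reference, c(5, 20, n_all), reps = 3,
                            seed = 9)
  curve2 <- saturation_curve(frags, reference, c(5, 20, n_all), reps = 3,
                             seed = 9)
  expect_identical(curve, curve2)
  # full-depth aggregate equals the reference exactly
  expect_equal(curve[n_cells == n_all, mean_r], 1)
  expect_equal(curve[n_cells == n_all, sd_r], 0)
  # mean correlation non-decreasing within one replicate sd
  expect_true(all(diff(curve$mean_r) > -pmax(curve$sd_r[-1], 1e-6)))
})

test_that("median normalization equalizes per-cell totals at the median", {
  set.seed(13)
  m <- Matrix::Matrix(matrix(rpois(200, 4) + 1, 20, 10), sparse = TRUE)
  colnames(m) <- sprintf("c%02d", 1:10)
  norm <- median_normalize(m)
  med <- median(Matrix::colSums(m))
  expect_equal(unname(Matrix::colSums(norm)), rep(med, 10))
  # equal-depth input is unchanged
  eq <- Matrix::Matrix(matrix(2, 5, 4), sparse = TRUE)
  expect_equal(as.matrix(median_normalize(eq)), as.matrix(eq))
  # a cell at twice the median depth is halved
  m2 <- cbind(eq, 2 * eq[, 1, drop = FALSE])
  expect_equal(as.numeric(median_normalize(m2)[, 5]), rep(2, 5))
  expect_error(median_normalize(cbind(eq, 0 * eq[, 1, drop = FALSE])),
               "positive totals")
})

test_that("Poisson thresholds equal brute-force tail summation", {
  for (lam in c(0.1, 1, 5, 20)) {
    expect_equal(poisson_threshold(lam, 5e-7),
                 brute_poisson_threshold(lam, 5e-7))
  }
  expect_equal(poisson_threshold(0, 5e-7), 1L)  # any count is extreme
  expect_error(poisson_threshold(1, 0), "p must be")
})

test_that("Poisson binarization marks enriched bins and is monotone", {
  glb <- c(chr1 = 40000L)
  counts <- rep(2, 200); counts[c(10, 50)] <- 30
  sig <- binned_track(list(chr1 = counts), 200L, glb)
  bin <- poisson_binarize(sig, p = 5e-7, bin_size = 200L)
  expect_equal(which(bin$values$chr1 == 1), c(10, 50))

  # uniform signal at its own expectation stays all-zero
  flat <- binned_track(list(chr1 = rep(3, 200)), 200L, glb)
  expect_true(all(poisson_binarize(flat)$values$chr1 == 0))

  # lambda = 0 with the floor disabled marks any nonzero bin
  sparse <- binned_track(list(chr1 = c(rep(0, 199), 1)), 200L, glb)
  b0 <- poisson_binarize(sparse, floor_global_mean = FALSE)
  # note: global mean floor disabled and no control -> lambda 0
  expect_equal(which(b0$values$chr1 == 1), 200)

  # control scaling: hot control bins raise the local expectation
  ctl <- binned_track(list(chr1 = c(rep(1, 100), rep(20, 100))), 200L, glb)
  sig2 <- binned_track(list(chr1 = rep(15, 200)), 200L, glb)
  bc <- poisson_binarize(sig2, control = ctl, p = 1e-3)
  first_half <- bc$values$chr1[1:100]
  second_half <- bc$values$chr1[101:200]
  expect_true(mean(first_half) >= mean(second_half))
  zero_ctl <- binned_track(list(chr1 = rep(0, 200)), 200L, glb)
  expect_error(poisson_binarize(sig2, control = zero_ctl), "zero total")

  # monotone: adding counts to enriched bins never flips 1 -> 0
  counts2 <- counts; counts2[c(10, 50)] <- counts2[c(10, 50)] + 5
  b_more <- poisson_binarize(binned_track(list(chr1 = counts2), 200L, glb),
                             p = 5e-7)
  expect_true(all(b_more$values$chr1 >= bin$values$chr1))
})

test_that("bedGraph and binarized outputs round-trip", {
  set.seed(14)
  tr <- binned_track(list(chr1 = rpois(200, 2), chr2 = rpois(60, 2)), 50L, gl)
  path <- tempfile(fileext = ".bedgraph.gz")
  write_bedgraph(tr, path)
  back <- read_bedgraph(path, gl, 50L)
  expect_equal(back$values, tr$values)
  # final bin is truncated at the contig end (readLines decompresses gz)
  lines <- fread(text = readLines(path), header = FALSE)
  expect_equal(max(lines$V3), 10000)

  bdir <- tempfile()
  bin <- poisson_binarize(tr, p = 1e-4, bin_size = 50L)
  write_binarized(bin, "H3K4me3", bdir)
  tsv <- fread(file.path(bdir, "H3K4me3_binary.tsv"))
  expect_equal(nrow(tsv), 260)
  expect_true(all(tsv$value %in% c(0, 1)))
  unlink(bdir, recursive = TRUE)
})
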