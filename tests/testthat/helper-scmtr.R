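library(data.table)

# small, fast scenario used across unit tests
tiny_scenario <- function(seed = 7, ...) {
  args <- list(
    n_cells = 30L,
    genome_lengths = c(chr1 = 60000L, chr2 = 20000L),
    n_peaks = 10L, peak_width = 600L,
    fragments_per_cell = list(H3K4me3 = c(mu = 60, size = 10),
                              H3K27me3 = c(mu = 60, size = 10),
                              IgG = c(mu = 15, size = 10)),
    umis_per_cell = c(mu = 80, size = 10),
    n_genes = 20L,
    seed = seed)
  do.call(scenario, modifyList(args, list(...)))
}

# brute-force Hamming distance between two equal-length strings
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# exhaustive all-pairs minimum distance (independent of the package's
# matrix-based implementation)
brute_min_distance <- function(wl) {
  min(apply(combn(length(wl), 2), 2, function(p) hamming(wl[p[1]], wl[p[2]])))
}

# chi-square for a 2x2 table from the closed-form N(ad-bc)^2/(r1 r2 c1 c2)
brute_chisq_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- sum(tab)
  n * (a * d - b * c)^2 /
    (sum(tab[1, ]) * sum(tab[2, ]) * sum(tab[, 1]) * sum(tab[, 2]))
}

# brute-force Poisson upper-tail threshold by pmf summation
brute_poisson_threshold <- function(lambda, p) {
  t <- 0L
  repeat {
    tail <- 1 - sum(dpois(0:(t - 1), lambda))
    if (t == 0L) tail <- 1
    if (tail <= p) return(t)
    t <- t + 1L
  }
}

# read names in the pipeline's BC1:BC2:BC3:target:umi:serial convention
make_read_names <- function(cell, target, umi, serial = seq_along(cell)) {
  paste(cell, target, umi, serial, sep = ":")
}
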