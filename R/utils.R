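.pkg_cache <- new.env(parent = emptyenv())

.bases <- c("A", "C", "G", "T")

# all 4^k k-mers in fixed order, cached (used to draw UMIs)
.kmer_table <- function(k) {
  key <- paste0("kmers", k)
  if (is.null(.pkg_cache[[key]])) {
    m <- as.matrix(expand.grid(rep(list(.bases), k), stringsAsFactors = FALSE))
    .pkg_cache[[key]] <- apply(m[, rev(seq_len(k)), drop = FALSE], 1, paste, collapse = "")
  }
  .pkg_cache[[key]]
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.random_sequence <- function(n) {
  paste(sample(.bases, n, replace = TRUE), collapse = "")
}

# run code under a seed without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# derive a stage seed from a root seed, kept below 2^31
.stage_seed <- function(seed, stage) {
  (as.numeric(seed) * 1000003 + stage) %% 2147483647
}

#' Write / read gzipped FASTQ
#'
#' Four-line records with a constant quality string; sequence identity and
#' read names are what matter at desk scale.
#'
#' @param names,seqs Character vectors of read names and sequences.
#' @param path Output path (gzipped when it ends in `.gz`).
#' @return `read_fastq()` returns a named character vector of sequences.
#' @keywords internal
#' @export
write_fastq <- function(names, seqs, path) {
  stopifnot(length(names) == length(seqs))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  qual <- strrep("I", nchar(seqs))
  writeLines(paste0("@", names, "\n", seqs, "\n+\n", qual), con, sep = "\n")
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), names(x))
}

# named integer vector of contig lengths from a genome character vector
.genome_lengths <- function(genome) {
  stats::setNames(nchar(genome), names(genome))
}

# fread that handles .gz via a connection (no optional helper packages)
.fread_auto <- function(path, ...) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    txt <- readLines(con)
    if (!length(txt)) txt <- ""
    data.table::fread(text = txt, ...)
  } else {
    data.table::fread(path, ...)
  }
}
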