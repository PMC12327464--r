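# Desk-scale alignment: exact full-length substring lookup against a small
# genome (both strands), plus a minimal SAM reader with the modality-specific
# mapping-quality and proper-pair filters applied to externally aligned data.

# index of every w-mer in the genome, both strands, with occurrence counts
.genome_index <- function(genome, w) {
  idx <- list()
  for (ct in names(genome)) {
    L <- nchar(genome[[ct]])
    if (L < w) next
    starts <- seq_len(L - w + 1L)
    fwd <- substring(genome[[ct]], starts, starts + w - 1L)
    rev <- .revcomp(fwd)
    idx[[ct]] <- data.table::data.table(
      kmer = c(fwd, rev),
      contig = ct,
      start = c(starts - 1L, starts - 1L),  # 0-based fragment start
      strand = rep(c("+", "-"), each = length(starts)))
  }
  idx <- data.table::rbindlist(idx)
  # hits per sequence; a sequence occurring once maps uniquely
  idx[, n_hits := .N, by = kmer]
  idx[!duplicated(kmer)]
}

#' Exact alignment of annotated reads to a small genome
#'
#' Looks every read up in an index of all genome substrings of the read
#' length (forward and reverse-complement). Reads with exactly one genomic
#' occurrence are reported at mapping quality 60; reads hitting several loci
#' or none are dropped and counted. Only exact full-length matches are
#' considered: the simulator places no errors on the genomic read, so a
#' mismatch-tolerant search would never fire at desk scale.
#'
#' @param reads Character vector of read sequences; names (e.g.
#'   `cell:target:umi:serial`) are carried into the records.
#' @param genome Named character vector of contig sequences (as in
#'   `scmtr_sim$genome`) or a `Biostrings::DNAStringSet`.
#' @return List with `records` (`data.table`: `name`, `contig`, `start`,
#'   `end` 0-based half-open, `strand`, `mapq`) and `stats`
#'   (`n_input`, `n_unique`, `n_multi`, `n_unmapped`).
#' @export
align_exact <- function(reads, genome) {
  if (methods::is(genome, "DNAStringSet"))
    genome <- stats::setNames(as.character(genome), names(genome))
  if (!length(genome)) stop("empty genome")
  widths <- unique(nchar(reads))
  if (length(widths) != 1L)
    stop("align_exact expects fixed-length reads; got widths ",
         paste(widths, collapse = ", "))
  idx <- .genome_index(genome, widths)
  hit <- idx[match(reads, idx$kmer)]
  unique_hit <- !is.na(hit$n_hits) & hit$n_hits == 1L
  records <- data.table::data.table(
    name = if (!is.null(names(reads))) names(reads)[unique_hit] else
      which(unique_hit),
    contig = hit$contig[unique_hit],
    start = hit$start[unique_hit],
    end = hit$start[unique_hit] + widths,
    strand = hit$strand[unique_hit],
    mapq = 60L)
  list(records = records,
       stats = list(n_input = length(reads),
                    n_unique = sum(unique_hit),
                    n_multi = sum(!is.na(hit$n_hits) & hit$n_hits > 1L),
                    n_unmapped = sum(is.na(hit$n_hits))))
}

# reference-consumed length from a CIGAR string
.cigar_reflen <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(0L)
    toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", toks))
    op <- sub("^[0-9]+", "", toks)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Read a minimal SAM file into aligned records
#'
#' Parses the eleven mandatory SAM fields (optional tags ignored), drops
#' unmapped and secondary/supplementary records, applies the strict
#' mapping-quality filter (`mapq > 10` for DNA, `mapq > 50` for RNA, as used
#' for this assay's data), and for paired input keeps only proper pairs in
#' FR orientation, merging the two mates into one fragment-spanning record
#' `(min start, max end)`. Coordinates are converted from SAM 1-based to
#' 0-based half-open.
#'
#' @param path SAM file path (plain text).
#' @param modality `"DNA"` or `"RNA"` (selects the default mapq cutoff).
#' @param mapq_min Override the strict lower bound (record kept when
#'   `mapq > mapq_min`).
#' @return List with `records` (`name`, `contig`, `start`, `end`, `strand`,
#'   `mapq`, `proper_pair`) and `stats` (input, kept, mapq-filtered,
#'   orientation-filtered, malformed counts).
#' @export
read_alignments <- function(path, modality = c("DNA", "RNA"),
                            mapq_min = NULL) {
  modality <- match.arg(modality)
  if (is.null(mapq_min)) mapq_min <- if (modality == "DNA") 10L else 50L
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  n_malformed <- 0L
  if (!length(lines))
    return(list(records = data.table::data.table(
      name = character(), contig = character(), start = integer(),
      end = integer(), strand = character(), mapq = integer(),
      proper_pair = logical()),
      stats = list(n_input = 0L, n_kept = 0L, n_mapq = 0L,
                   n_orientation = 0L, n_malformed = 0L)))
  fields <- data.table::tstrsplit(lines, "\t", fill = NA_character_)
  if (length(fields) < 11L)
    stop("not a SAM file: fewer than 11 mandatory fields")
  rec <- data.table::data.table(
    qname = fields[[1]], flag = suppressWarnings(as.integer(fields[[2]])),
    rname = fields[[3]], pos = suppressWarnings(as.integer(fields[[4]])),
    mapq = suppressWarnings(as.integer(fields[[5]])), cigar = fields[[6]])
  bad <- is.na(rec$flag) | is.na(rec$pos) | is.na(rec$mapq) |
    is.na(fields[[11]])
  if (any(bad)) {
    n_malformed <- sum(bad)
    warning(n_malformed, " malformed SAM records skipped")
    rec <- rec[!bad]
  }
  n_input <- nrow(rec)
  rec <- rec[bitwAnd(flag, 4L) == 0L & bitwAnd(flag, 256L) == 0L &
               bitwAnd(flag, 2048L) == 0L & rname != "*"]
  n_mapq <- sum(rec$mapq <= mapq_min)
  rec <- rec[mapq > mapq_min]
  rec[, `:=`(start = pos - 1L, end = pos - 1L + .cigar_reflen(cigar),
             strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
             paired = bitwAnd(flag, 1L) > 0L,
             proper = bitwAnd(flag, 2L) > 0L,
             mate_rev = bitwAnd(flag, 32L) > 0L)]
  n_orientation <- 0L
  singles <- rec[paired == FALSE]
  out <- list()
  if (nrow(singles))
    out$single <- singles[, .(name = qname, contig = rname, start, end,
                              strand, mapq, proper_pair = FALSE)]
  paired <- rec[paired == TRUE]
  if (nrow(paired)) {
    # proper FR pairs only: flags proper, mates on same contig, one mate
    # reversed and the other not
    ok <- paired[proper & ((strand == "-") != mate_rev)]
    n_orientation <- nrow(paired) - nrow(ok)
    if (nrow(ok)) {
      merged <- ok[, .(contig = rname[1], start = min(start), end = max(end),
                       strand = strand[which.min(start)], mapq = min(mapq),
                       n_mates = .N, same_contig = data.table::uniqueN(rname) == 1L),
                   by = qname]
      dropped <- sum(!merged$same_contig)
      n_orientation <- n_orientation + dropped
      merged <- merged[same_contig == TRUE]
      out$paired <- merged[, .(name = qname, contig, start, end, strand,
                               mapq, proper_pair = TRUE)]
    }
  }
  records <- if (length(out)) data.table::rbindlist(out) else
    data.table::data.table(name = character(), contig = character(),
                           start = integer(), end = integer(),
                           strand = character(), mapq = integer(),
                           proper_pair = logical())
  list(records = records[],
       stats = list(n_input = n_input, n_kept = nrow(records),
                    n_mapq = n_mapq, n_orientation = n_orientation,
                    n_malformed = n_malformed))
}

#' Write aligned records as a debugging TSV
#' @param records `data.table` of aligned records.
#' @param path Output path.
#' @export
write_alignments_tsv <- function(records, path) {
  data.table::fwrite(records, path, sep = "\t")
  invisible(path)
}
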