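# Decoding Read2 into (cell, modality, target/RT, UMI): fixed-position
# segment extraction followed by whitelist matching, exact by default or
# with unambiguous one-mismatch correction.

#' Extract the raw barcode segments from Read2
#'
#' Pulls the five fixed-position substrings (BC3, BC2, BC1, ID, UMI) from
#' each barcode read. Reads shorter than the layout's minimum length are
#' flagged rather than dropped.
#'
#' @param sequences Character vector of Read2 sequences.
#' @param layout A [read_layout()].
#' @return `data.table` with columns `bc3`, `bc2`, `bc1`, `id`, `umi`
#'   (`NA` for short reads) and logical `too_short`.
#' @examples
#' parse_read2(strrep("A", 127))
#' @export
parse_read2 <- function(sequences, layout = read_layout()) {
  seg <- as.data.frame(layout)
  min_len <- attr(layout, "min_read_length")
  short <- nchar(sequences) < min_len
  pull <- function(nm) {
    i <- match(nm, seg$segment)
    out <- substring(sequences, seg$start[i], seg$end[i])
    out[short] <- NA_character_
    out
  }
  data.table::data.table(
    bc3 = pull("BC3"), bc2 = pull("BC2"), bc1 = pull("BC1"),
    id = pull("ID"), umi = pull("UMI"), too_short = short)
}

# one-mismatch neighbourhood dictionary: maps every sequence at Hamming
# distance <= 1 of a whitelist entry to that entry; sequences claimed by two
# entries map to the sentinel "" (ambiguous)
.mm1_dict <- function(whitelist) {
  w <- nchar(whitelist[1])
  neigh <- character(0)
  owner <- character(0)
  for (p in seq_len(w)) {
    for (b in .bases) {
      v <- whitelist
      substr(v, p, p) <- b
      neigh <- c(neigh, v)
      owner <- c(owner, whitelist)
    }
  }
  keep <- !duplicated(paste(neigh, owner))  # same owner via several routes
  neigh <- neigh[keep]; owner <- owner[keep]
  amb <- neigh[duplicated(neigh)]
  dict <- stats::setNames(owner, neigh)
  dict[unique(amb)] <- ""
  dict
}

#' Match raw segments against a whitelist
#'
#' Exact set membership (`max_mismatch = 0`, mirroring exact forward-strand
#' unique matching) or unambiguous Hamming-1 correction (`max_mismatch = 1`:
#' a segment is corrected only when exactly one whitelist entry lies within
#' distance 1; zero or two-plus candidates fail). Safe correction requires a
#' whitelist minimum pairwise distance of at least 3
#' ([min_pairwise_distance()]).
#'
#' @param raw Character vector of raw segment sequences.
#' @param whitelist Character vector of allowed barcodes (equal length).
#' @param max_mismatch 0 or 1.
#' @return List with `match` (corrected whitelist entry or `NA`) and
#'   `ambiguous` (logical: failed because two entries were equally close).
#' @examples
#' wl <- c("AAAA", "TTTT")
#' match_segment("AAAT", wl, max_mismatch = 1)$match
#' @export
match_segment <- function(raw, whitelist, max_mismatch = 0L) {
  if (!max_mismatch %in% c(0L, 1L)) stop("max_mismatch must be 0 or 1")
  w <- nchar(whitelist[1])
  bad_len <- !is.na(raw) & nchar(raw) != w
  if (max_mismatch == 0L) {
    m <- whitelist[match(raw, whitelist)]
    m[bad_len] <- NA_character_
    return(list(match = m, ambiguous = rep(FALSE, length(raw))))
  }
  dict <- .mm1_dict(whitelist)
  m <- unname(dict[raw])
  m[bad_len] <- NA_character_
  amb <- !is.na(m) & m == ""
  m[amb] <- NA_character_
  list(match = m, ambiguous = amb)
}

#' Demultiplex barcode reads into read annotations
#'
#' Applies [parse_read2()] then per-segment whitelist matching. A read is
#' `valid` only when BC3, BC2, BC1 and the ID all match; the first failing
#' segment (in read order BC3, BC2, BC1, ID) determines the failure status,
#' with `ambiguous` reported when that segment had two equally close
#' whitelist entries under one-mismatch matching. The cell id is the
#' corrected `BC1:BC2:BC3` combination; UMIs are taken verbatim and never
#' corrected. Modality is resolved per read from which ID table matched
#' (`auto`), or forced.
#'
#' `max_mismatch` governs the three cell-barcode segments only. The 5-nt
#' antibody/RT index is matched exactly by default even when barcode
#' correction is on: a wrongly "corrected" index silently moves a read to a
#' different target or modality, and with ten codewords in a 5-nt space the
#' distance budget (at most 4) cannot make that failure mode negligible the
#' way the distance-5 8-mer whitelists can. Enable `id_max_mismatch = 1`
#' only if that risk is acceptable.
#'
#' @param read2 Character vector of barcode-read sequences (named or not).
#' @param design A [barcode_design()].
#' @param modality `"auto"` (default), `"DNA"` (antibody IDs only) or
#'   `"RNA"` (RT IDs only).
#' @param max_mismatch Mismatch allowance for BC1/BC2/BC3, 0 or 1.
#' @param id_max_mismatch Mismatch allowance for the antibody/RT index
#'   (default 0, see above).
#' @return List with `annotations` (`data.table`: `read_id`, `cell_id`,
#'   `modality`, `target_or_rt`, `umi`, `status`) and `stats` (input/valid
#'   counts, per-status and per-target tallies).
#' @seealso [demux_fastq()] for the file-level interface.
#' @export
demux_reads <- function(read2, design, modality = c("auto", "DNA", "RNA"),
                        max_mismatch = 0L, id_max_mismatch = 0L) {
  modality <- match.arg(modality)
  stopifnot(inherits(design, "barcode_design"))
  seg <- parse_read2(read2, design$layout)

  m3 <- match_segment(seg$bc3, design$rounds$BC3, max_mismatch)
  m2 <- match_segment(seg$bc2, design$rounds$BC2, max_mismatch)
  m1 <- match_segment(seg$bc1, design$rounds$BC1, max_mismatch)
  ab <- design$antibody_index
  rt <- design$rt_index
  id_wl <- switch(modality, auto = c(ab, rt), DNA = ab, RNA = rt)
  mid <- match_segment(seg$id, unname(id_wl), id_max_mismatch)
  id_label <- names(id_wl)[match(mid$match, unname(id_wl))]
  read_modality <- ifelse(is.na(mid$match), NA_character_,
                          ifelse(mid$match %in% unname(ab), "DNA", "RNA"))
  if (modality != "auto") read_modality[!is.na(mid$match)] <- modality

  status <- rep("valid", length(read2))
  fail <- function(cur, miss, amb, code) {
    pick <- cur == "valid" & miss
    status[pick & !amb] <<- code
    status[pick & amb] <<- "ambiguous"
  }
  status[seg$too_short] <- "too_short"
  fail(status, is.na(m3$match) & !seg$too_short, m3$ambiguous, "bad_BC3")
  fail(status, is.na(m2$match), m2$ambiguous, "bad_BC2")
  fail(status, is.na(m1$match), m1$ambiguous, "bad_BC1")
  fail(status, is.na(mid$match), mid$ambiguous, "bad_ID")

  valid <- status == "valid"
  ann <- data.table::data.table(
    read_id = if (!is.null(names(read2))) names(read2) else seq_along(read2),
    cell_id = ifelse(valid, paste(m1$match, m2$match, m3$match, sep = ":"),
                     NA_character_),
    modality = ifelse(valid, read_modality, NA_character_),
    target_or_rt = ifelse(valid, id_label, NA_character_),
    umi = seg$umi,
    status = status)

  per_target <- ann[status == "valid", .N, by = target_or_rt]
  stats <- list(
    n_input = length(read2),
    n_valid = sum(valid),
    valid_fraction = mean(valid),
    by_status = as.list(table(status)),
    per_target = stats::setNames(per_target$N, per_target$target_or_rt),
    max_mismatch = max_mismatch)
  list(annotations = ann, stats = stats)
}

#' File-level demultiplexer
#'
#' Reads a FASTQ pair, annotates every read via [demux_reads()], and
#' re-emits valid reads as a Read1 FASTQ named
#' `BC1:BC2:BC3:target:UMI:serial`; rejected reads go to a separate FASTQ
#' whose names carry the failure status. Demultiplexing statistics are
#' written as JSON.
#'
#' @param r1_path,r2_path Input FASTQ (gz) paths: genomic/cDNA read and
#'   barcode read.
#' @param out_dir Output directory.
#' @param design,modality,max_mismatch,id_max_mismatch Passed to
#'   [demux_reads()].
#' @return Invisibly, the [demux_reads()] result.
#' @export
demux_fastq <- function(r1_path, r2_path, out_dir, design,
                        modality = "auto", max_mismatch = 0L,
                        id_max_mismatch = 0L) {
  r1 <- read_fastq(r1_path)
  r2 <- read_fastq(r2_path)
  if (length(r1) != length(r2)) stop("R1/R2 read counts differ")
  res <- demux_reads(stats::setNames(as.character(r2), names(r2)), design,
                     modality = modality, max_mismatch = max_mismatch,
                     id_max_mismatch = id_max_mismatch)
  ann <- res$annotations
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- ann$status == "valid"
  if (any(ok)) {
    nm <- paste(ann$cell_id[ok], ann$target_or_rt[ok], ann$umi[ok],
                seq_len(sum(ok)), sep = ":")
    dna <- ann$modality[ok] == "DNA"
    write_fastq(nm[dna], unname(r1)[ok][dna],
                file.path(out_dir, "valid_DNA.fastq.gz"))
    write_fastq(nm[!dna], unname(r1)[ok][!dna],
                file.path(out_dir, "valid_RNA.fastq.gz"))
  }
  if (any(!ok)) {
    write_fastq(paste0(ann$read_id[!ok], " ", ann$status[!ok]),
                unname(r1)[!ok], file.path(out_dir, "rejects.fastq.gz"))
  }
  jsonlite::write_json(res$stats, file.path(out_dir, "demux_stats.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
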