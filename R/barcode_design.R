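# Barcode architecture: three split-pool rounds of cell barcodes ligated onto
# every molecule, plus a 5-nt index distinguishing the antibody-Tn5 complex
# (DNA fragments) or the RT primer (RNA molecules), and an 8-nt UMI.

#' Fixed-position layout of the barcode read (Read2)
#'
#' Coordinates are 1-based inclusive, as conventionally printed for this
#' assay: BC3 at 1-8, BC2 at 39-46, BC1 at 77-84, the antibody/RT index (ID)
#' at 115-119 and the UMI at 120-127, with 30-nt ligation linkers between
#' barcode blocks. Reads shorter than the largest segment end cannot be
#' decoded.
#'
#' @param bc3,bc2,bc1,id,umi Integer vectors of length 2: first and last base
#'   (1-based, inclusive) of each segment in Read2.
#' @return A `read_layout` object: a data.frame with columns `segment`,
#'   `start`, `end`, plus attribute `min_read_length`.
#' @examples
#' read_layout()
#' @export
read_layout <- function(bc3 = c(1L, 8L), bc2 = c(39L, 46L), bc1 = c(77L, 84L),
                        id = c(115L, 119L), umi = c(120L, 127L)) {
  segs <- list(BC3 = bc3, BC2 = bc2, BC1 = bc1, ID = id, UMI = umi)
  for (nm in names(segs)) {
    s <- segs[[nm]]
    if (length(s) != 2L || any(s < 1L) || s[2] < s[1])
      stop("invalid segment coordinates for ", nm)
  }
  df <- data.frame(
    segment = names(segs),
    start = vapply(segs, `[`, integer(1), 1L),
    end = vapply(segs, `[`, integer(1), 2L),
    stringsAsFactors = FALSE
  )
  # non-overlap check on sorted starts
  o <- order(df$start)
  if (any(df$start[o][-1] <= df$end[o][-nrow(df)]))
    stop("read layout segments overlap")
  attr(df, "min_read_length") <- max(df$end)
  class(df) <- c("read_layout", "data.frame")
  df
}

#' Construct and validate a barcode design
#'
#' A design bundles the per-round cell-barcode whitelists (default three
#' rounds of 48 8-mers), the antibody-index table mapping 5-nt sequences to
#' chromatin targets (including the IgG background control), the RT-index
#' table labelling RNA-derived molecules, and the fixed Read2 layout.
#' Antibody and RT index sequences must be disjoint so that modality can be
#' resolved per read.
#'
#' @param rounds Named list of character vectors (`BC1`, `BC2`, `BC3`), each a
#'   whitelist of equal-length barcodes, unique within the round.
#' @param antibody_index Named character vector: `target name -> 5-nt index`.
#' @param rt_index Named character vector: `sample label -> 5-nt index`.
#' @param layout A [read_layout()] object.
#' @param linkers Character vector of the three fixed linker sequences placed
#'   between barcode blocks in Read2 (never matched during demultiplexing).
#' @return A `barcode_design` object (list).
#' @seealso [default_barcode_design()], [barcode_combinations()]
#' @export
barcode_design <- function(rounds, antibody_index, rt_index,
                           layout = read_layout(),
                           linkers = NULL) {
  if (!is.list(rounds) || length(rounds) < 1L)
    stop("design must have at least one barcoding round")
  if (is.null(names(rounds)) || any(!nzchar(names(rounds))))
    stop("rounds must be named (BC1, BC2, BC3, ...)")
  for (nm in names(rounds)) {
    wl <- rounds[[nm]]
    if (length(wl) < 1L) stop("round ", nm, " is empty")
    if (length(unique(nchar(wl))) != 1L)
      stop("round ", nm, ": barcodes have unequal lengths")
    if (anyDuplicated(wl)) stop("round ", nm, ": duplicate barcodes")
  }
  for (tab in list(antibody_index, rt_index)) {
    if (length(tab) && length(unique(nchar(tab))) != 1L)
      stop("index sequences must have equal length")
  }
  if (anyDuplicated(c(antibody_index, rt_index)))
    stop("antibody and RT index sequences must be disjoint and unique")
  if (is.null(linkers)) {
    # fixed arbitrary sequences filling the gaps between consecutive Read2
    # segments; never matched during demultiplexing
    seg <- as.data.frame(layout)
    seg <- seg[order(seg$start), ]
    gaps <- seg$start[-1] - seg$end[-nrow(seg)] - 1L
    linkers <- vapply(gaps[gaps > 0L], function(g)
      paste(rep(c("A", "C", "T", "G"), length.out = g), collapse = ""),
      character(1))
  }
  structure(list(rounds = rounds, antibody_index = antibody_index,
                 rt_index = rt_index, layout = layout, linkers = linkers),
            class = "barcode_design")
}

#' @export
print.barcode_design <- function(x, ...) {
  cat("barcode_design:", length(x$rounds), "rounds (",
      paste(vapply(x$rounds, length, integer(1)), collapse = " x "), "barcodes ),",
      length(x$antibody_index), "antibody indexes,",
      length(x$rt_index), "RT indexes\n")
  cat("  cell barcode space:", format(barcode_combinations(x), big.mark = ","),
      "combinations\n")
  invisible(x)
}

#' Size of the combinatorial cell-barcode space
#'
#' The product of the whitelist sizes over the split-pool rounds: with the
#' default three rounds of 48 barcodes this is 48^3 = 110,592 combinations.
#' The antibody/RT index does not contribute to cell identity by default
#' (every cell carries all antibody indexes); set `include_rt = TRUE` when
#' multiple RT indexes are used to partition cells into sublibraries and
#' should be counted as an extra round.
#'
#' @param design A [barcode_design()].
#' @param include_rt Multiply in the RT-index count as an additional round.
#' @return Number of distinct cell barcode combinations.
#' @examples
#' barcode_combinations(default_barcode_design())  # 110592
#' @export
barcode_combinations <- function(design, include_rt = FALSE) {
  stopifnot(inherits(design, "barcode_design"))
  if (length(design$rounds) == 0L) stop("design has no barcoding rounds")
  n <- prod(vapply(design$rounds, length, integer(1)))
  if (include_rt) n <- n * max(1L, length(design$rt_index))
  n
}

#' Barcode collision rate for a given cell load
#'
#' Probability that a cell shares its combinatorial barcode with another cell
#' when `n_cells` cells draw uniformly from `n_combinations` barcode
#' combinations. The `linear` estimator is the occupancy ratio
#' `n_cells / n_combinations` (clipped at 1); at the default 110,592-combination
#' space it gives ~1% for 1,100 cells and ~10% for 11,000 cells. The
#' `birthday` estimator is the exact per-cell collision probability
#' `1 - (1 - 1/B)^(n-1)`, always at or below the linear value.
#'
#' @param n_cells Number of cells loaded (>= 1).
#' @param n_combinations Size of the barcode space (>= 1), e.g. from
#'   [barcode_combinations()].
#' @param method `"linear"` (default) or `"birthday"`.
#' @return Collision probability in `[0, 1]`.
#' @examples
#' collision_rate(1100, 110592)            # ~0.01
#' collision_rate(11000, 110592)           # ~0.10
#' collision_rate(11000, 110592, "birthday")
#' @export
collision_rate <- function(n_cells, n_combinations,
                           method = c("linear", "birthday")) {
  method <- match.arg(method)
  if (length(n_cells) != 1L || length(n_combinations) != 1L ||
      !is.finite(n_cells) || !is.finite(n_combinations) ||
      n_cells < 1 || n_combinations < 1)
    stop("n_cells and n_combinations must be positive")
  switch(method,
    linear = min(1, n_cells / n_combinations),
    birthday = 1 - (1 - 1 / n_combinations)^(n_cells - 1)
  )
}

# integer matrix of byte codes, one row per barcode
.barcode_matrix <- function(whitelist) {
  n <- nchar(whitelist[1])
  matrix(utf8ToInt(paste(whitelist, collapse = "")), ncol = n, byrow = TRUE)
}

#' Minimum pairwise Hamming distance of a whitelist
#'
#' Guards mismatch-aware demultiplexing: one-mismatch correction is
#' unambiguous only when all pairwise distances are at least 3 (the shipped
#' default whitelists keep distance >= 4, so that two sequencing errors can
#' never be "corrected" into a different barcode).
#'
#' @param whitelist Character vector (>= 2 entries, equal lengths, unique).
#' @return The minimum Hamming distance over all pairs.
#' @examples
#' min_pairwise_distance(c("AAAA", "AATT", "TTTT"))
#' @export
min_pairwise_distance <- function(whitelist) {
  if (length(whitelist) < 2L) stop("need at least two whitelist entries")
  if (length(unique(nchar(whitelist))) != 1L)
    stop("whitelist entries have unequal lengths")
  if (anyDuplicated(whitelist)) stop("whitelist entries must be distinct")
  m <- .barcode_matrix(whitelist)
  best <- ncol(m)
  for (i in seq_len(nrow(m) - 1L)) {
    d <- rowSums(m[(i + 1L):nrow(m), , drop = FALSE] !=
                   matrix(m[i, ], nrow(m) - i, ncol(m), byrow = TRUE))
    best <- min(best, d)
  }
  as.integer(best)
}

#' Greedily build a whitelist with a guaranteed minimum Hamming distance
#'
#' Scans a seeded random permutation of sequences of the requested length and
#' keeps each candidate whose distance to all accepted barcodes is at least
#' `min_dist`. Used once to generate the whitelists shipped with the package.
#'
#' @param n Number of barcodes wanted.
#' @param width Barcode length in nt.
#' @param min_dist Minimum pairwise Hamming distance to enforce.
#' @param seed Integer seed for the candidate permutation.
#' @return Character vector of `n` barcodes.
#' @export
make_hamming_whitelist <- function(n, width, min_dist, seed = 1L) {
  bases <- c("A", "C", "G", "T")
  total <- 4^width
  set.seed(seed)
  ord <- sample.int(total) - 1L
  chosen <- matrix(integer(0), 0L, width)
  out <- character(0)
  for (code in ord) {
    digits <- (code %/% 4^(seq_len(width) - 1L)) %% 4L
    if (nrow(chosen)) {
      d <- rowSums(chosen != matrix(digits, nrow(chosen), width, byrow = TRUE))
      if (min(d) < min_dist) next
    }
    chosen <- rbind(chosen, digits)
    out <- c(out, paste(bases[digits + 1L], collapse = ""))
    if (length(out) == n) return(out)
  }
  stop("could not find ", n, " barcodes of width ", width,
       " at min distance ", min_dist)
}

#' The packaged default barcode design
#'
#' Three rounds of 48 8-nt cell barcodes (minimum pairwise Hamming distance
#' 4 within each round), six antibody indexes (five histone-mark targets
#' plus IgG) and four RT indexes, all 5 nt with minimum pairwise distance 4
#' across the combined index set, and the standard Read2 layout. The tables
#' are shipped as a plain whitelist TSV under `inst/extdata`.
#'
#' @return A [barcode_design()].
#' @examples
#' d <- default_barcode_design()
#' barcode_combinations(d)
#' @export
default_barcode_design <- function() {
  path <- system.file("extdata", "default_whitelists.tsv", package = "scmtr",
                      mustWork = TRUE)
  read_design_whitelists(path)
}

#' Read or write whitelist tables
#'
#' Whitelists travel as a headered TSV with columns `name`, `sequence`,
#' `role` where role is a round (`BC1`/`BC2`/`BC3`) or `antibody`/`rt`.
#'
#' @param path TSV file path.
#' @param layout Read2 layout to attach (default [read_layout()]).
#' @return `read_design_whitelists()`: a [barcode_design()].
#' @export
read_design_whitelists <- function(path, layout = read_layout()) {
  tab <- .fread_auto(path, sep = "\t", colClasses = "character")
  need <- c("name", "sequence", "role")
  if (!all(need %in% names(tab))) stop("whitelist TSV needs columns ",
                                       paste(need, collapse = ", "))
  round_names <- sort(setdiff(unique(tab$role), c("antibody", "rt")))
  rounds <- lapply(round_names, function(r) tab[role == r, sequence])
  names(rounds) <- round_names
  ab <- tab[role == "antibody"]
  rt <- tab[role == "rt"]
  barcode_design(
    rounds = rounds[c("BC1", "BC2", "BC3")[c("BC1", "BC2", "BC3") %in% round_names]],
    antibody_index = stats::setNames(ab$sequence, ab$name),
    rt_index = stats::setNames(rt$sequence, rt$name),
    layout = layout
  )
}

#' @param design A [barcode_design()] to serialize.
#' @rdname read_design_whitelists
#' @export
write_design_whitelists <- function(design, path) {
  stopifnot(inherits(design, "barcode_design"))
  rows <- list()
  for (r in names(design$rounds)) {
    wl <- design$rounds[[r]]
    rows[[r]] <- data.table::data.table(
      name = sprintf("%s_%02d", r, seq_along(wl)), sequence = wl, role = r)
  }
  rows[["antibody"]] <- data.table::data.table(
    name = names(design$antibody_index), sequence = unname(design$antibody_index),
    role = "antibody")
  rows[["rt"]] <- data.table::data.table(
    name = names(design$rt_index), sequence = unname(design$rt_index), role = "rt")
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t")
  invisible(path)
}

#' Serialize a design to YAML (and back)
#'
#' Layout coordinates are stored 1-based inclusive, as printed in assay
#' protocols.
#'
#' @param design A [barcode_design()].
#' @param path YAML file path.
#' @return `read_design_yaml()` returns a [barcode_design()].
#' @export
write_design_yaml <- function(design, path) {
  stopifnot(inherits(design, "barcode_design"))
  seg <- as.data.frame(design$layout)
  obj <- list(
    rounds = lapply(design$rounds, as.list),
    antibody_index = as.list(design$antibody_index),
    rt_index = as.list(design$rt_index),
    linkers = as.list(design$linkers),
    layout = stats::setNames(
      lapply(seq_len(nrow(seg)), function(i) list(start = seg$start[i], end = seg$end[i])),
      seg$segment)
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_design_yaml
#' @export
read_design_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  lay <- obj$layout
  layout <- read_layout(
    bc3 = c(lay$BC3$start, lay$BC3$end), bc2 = c(lay$BC2$start, lay$BC2$end),
    bc1 = c(lay$BC1$start, lay$BC1$end), id = c(lay$ID$start, lay$ID$end),
    umi = c(lay$UMI$start, lay$UMI$end))
  barcode_design(
    rounds = lapply(obj$rounds, unlist),
    antibody_index = unlist(obj$antibody_index),
    rt_index = unlist(obj$rt_index),
    layout = layout,
    linkers = unlist(obj$linkers))
}
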