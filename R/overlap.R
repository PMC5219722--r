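# Geometry between a target gene and the gene overprinted on it: where the
# two coding sequences share nucleotides, on which strand, and in which
# codon phase. All coordinates are 0-based, half-open; codon indices are
# 0-based (the initiation codon is index 0).

#' Construct an overlap geometry
#'
#' Describes the shared region between a target gene and its overlapping
#' gene: `target_span` in target coordinates, `overlap_span` in the
#' overlapping gene's own coordinates, the strand relationship, and the
#' overlapping gene's codon phase at the start of the shared region
#' (`frame_shift`, which always equals `overlap_span[1] %% 3`).
#'
#' Supply a geometry explicitly to [gene_pair()] when automatic detection is
#' ambiguous (e.g. repeated sequence).
#'
#' @param target_span Integer length-2 vector, 0-based half-open interval in
#'   target coordinates.
#' @param overlap_span Same, in the overlapping gene's coordinates.
#' @param strand `"same"` or `"opposite"`.
#' @return An object of class `overlap_geometry`.
#' @export
overlap_geometry <- function(target_span, overlap_span, strand = c("same", "opposite")) {
  strand <- match.arg(strand)
  target_span <- as.integer(target_span)
  overlap_span <- as.integer(overlap_span)
  stopifnot(length(target_span) == 2L, length(overlap_span) == 2L)
  if (target_span[2L] <= target_span[1L] || overlap_span[2L] <= overlap_span[1L] ||
      target_span[1L] < 0L || overlap_span[1L] < 0L) {
    stop("spans must be non-empty 0-based half-open intervals", call. = FALSE)
  }
  if (diff(target_span) != diff(overlap_span)) {
    stop("target_span and overlap_span must have equal length", call. = FALSE)
  }
  structure(
    list(
      target_span = target_span,
      overlap_span = overlap_span,
      strand = strand,
      frame_shift = overlap_span[1L] %% 3L
    ),
    class = "overlap_geometry"
  )
}

#' @export
print.overlap_geometry <- function(x, ...) {
  cat(
    "overlap geometry: target [", x$target_span[1L], ", ", x$target_span[2L],
    ") <-> overlapping [", x$overlap_span[1L], ", ", x$overlap_span[2L],
    "), strand ", x$strand, ", frame shift ", x$frame_shift, "\n",
    sep = ""
  )
  invisible(x)
}

#' Detect the overlap between two genes
#'
#' Finds the longest exact common substring between the target gene and
#' either strand of the overlapping gene. Detection requires exact identity
#' (the two inputs describe the same genomic region; a mismatch indicates
#' user error and must surface) and a unique maximal match; same-strand
#' matches are preferred over opposite-strand matches of equal length.
#'
#' @param target,overlapping Unambiguous nucleotide sequences.
#' @param min_len Minimum acceptable overlap length in nucleotides. Below
#'   roughly 15 nt, chance matches between unrelated genes become likely.
#' @return An [overlap_geometry()].
#' @examples
#' ov <- paste0("T", "ATGGGGGGCTCAAAACCCGAGCACAACTAA", "CC")
#' find_overlap("ATGGGGGGCTCAAAACCCGAGCACAACTAA", ov)
#' @export
find_overlap <- function(target, overlapping, min_len = 15L) {
  target <- nt_sequence(target, allow_ambiguous = FALSE, what = "target")
  overlapping <- nt_sequence(overlapping, allow_ambiguous = FALSE,
                             what = "overlapping")
  fwd <- .lcs_occurrences(target, overlapping)
  rev_ <- .lcs_occurrences(target, reverse_complement(overlapping))
  use_same <- fwd$len >= rev_$len
  best <- if (use_same) fwd else rev_
  if (best$len < min_len) {
    stop("no overlap detected: longest common substring is ", best$len,
         " nt (< min_len = ", min_len, ")", call. = FALSE)
  }
  if (nrow(best$occ) > 1L) {
    stop(
      "ambiguous overlap: ", nrow(best$occ), " distinct maximal matches of ",
      best$len, " nt on the ", if (use_same) "same" else "opposite",
      " strand; pass an explicit geometry to gene_pair()", call. = FALSE
    )
  }
  t0 <- best$occ$target_start[1L]
  o0 <- best$occ$other_start[1L]
  L <- best$len
  if (use_same) {
    overlap_span <- c(o0, o0 + L)
    strand <- "same"
  } else {
    # o0 indexes the reverse complement; convert to forward coordinates.
    n <- nchar(overlapping)
    overlap_span <- c(n - o0 - L, n - o0)
    strand <- "opposite"
  }
  overlap_geometry(c(t0, t0 + L), overlap_span, strand)
}

# All occurrences of the longest common substring between a and b.
# Dynamic programme over match-run lengths, vectorised along b.
# Returns 0-based start positions.
.lcs_occurrences <- function(a, b) {
  ac <- .seq_chars(a)
  bc <- .seq_chars(b)
  n <- length(ac)
  m <- length(bc)
  prev <- integer(m)
  best_len <- 0L
  ends <- list()
  for (i in seq_len(n)) {
    hit <- bc == ac[i]
    cur <- integer(m)
    cur[hit] <- c(0L, prev)[which(hit)] + 1L
    mx <- if (m) max(cur) else 0L
    if (mx > best_len) {
      best_len <- mx
      ends <- list(cbind(i, which(cur == mx)))
    } else if (mx == best_len && best_len > 0L) {
      ends <- c(ends, list(cbind(i, which(cur == mx))))
    }
    prev <- cur
  }
  if (best_len == 0L) {
    return(list(len = 0L, occ = data.frame(target_start = integer(0L),
                                           other_start = integer(0L))))
  }
  e <- do.call(rbind, ends)
  occ <- data.frame(
    target_start = e[, 1L] - best_len,
    other_start = e[, 2L] - best_len
  )
  list(len = best_len, occ = unique(occ))
}

#' Bundle a target gene with its overlapping gene
#'
#' Pairs the gene to be knocked out (`target`) with the gene whose protein
#' must be preserved (`overlapping`), detecting the overlap geometry with
#' [find_overlap()] unless one is supplied. The geometry is checked against
#' the sequences: extracting the shared span from both genes (reverse
#' complemented for opposite-strand overlaps) must give identical
#' nucleotides.
#'
#' @param target Nucleotide sequence of the gene to be knocked out.
#' @param overlapping Nucleotide sequence of the gene to preserve.
#' @param geometry Optional [overlap_geometry()]; bypasses detection.
#' @param min_overlap Passed to [find_overlap()] as `min_len`.
#' @return An object of class `gene_pair`.
#' @examples
#' pair <- sample_gene_pair()
#' pair$geometry
#' @export
gene_pair <- function(target, overlapping, geometry = NULL, min_overlap = 15L) {
  target <- nt_sequence(target, allow_ambiguous = FALSE, what = "target")
  overlapping <- nt_sequence(overlapping, allow_ambiguous = FALSE,
                             what = "overlapping")
  if (nchar(target) < 3L || nchar(overlapping) < 3L) {
    stop("both sequences must be at least 3 nt long", call. = FALSE)
  }
  if (is.null(geometry)) {
    geometry <- find_overlap(target, overlapping, min_len = min_overlap)
  }
  stopifnot(inherits(geometry, "overlap_geometry"))
  if (geometry$target_span[2L] > nchar(target) ||
      geometry$overlap_span[2L] > nchar(overlapping)) {
    stop("geometry spans exceed sequence lengths", call. = FALSE)
  }
  t_sub <- substr(target, geometry$target_span[1L] + 1L, geometry$target_span[2L])
  o_sub <- substr(overlapping, geometry$overlap_span[1L] + 1L,
                  geometry$overlap_span[2L])
  if (geometry$strand == "opposite") o_sub <- reverse_complement(o_sub)
  if (t_sub != o_sub) {
    stop("geometry inconsistent with sequences: shared spans differ",
         call. = FALSE)
  }
  structure(
    list(target = target, overlapping = overlapping, geometry = geometry),
    class = "gene_pair"
  )
}

#' @export
print.gene_pair <- function(x, ...) {
  cat("gene pair: target ", nchar(x$target), " nt, overlapping ",
      nchar(x$overlapping), " nt\n", sep = "")
  print(x$geometry)
  invisible(x)
}

#' Map a target-gene position into the overlapping gene's codons
#'
#' The coordinate bridge used by every preservation check: given a 0-based
#' nucleotide position in the target that lies inside the shared span,
#' returns the 0-based codon index of the overlapping gene whose codon
#' covers the corresponding nucleotide, the 0-based offset within that
#' codon, and the strand. On the opposite strand the mapping accounts for
#' reversal (the first and last shared positions swap ends).
#'
#' @param geometry An [overlap_geometry()].
#' @param target_pos 0-based nucleotide position in the target.
#' @return List with `codon_index`, `offset_in_codon`, `strand`, and
#'   `overlap_pos` (the 0-based nucleotide position in the overlapping
#'   gene's forward coordinates).
#' @export
map_position <- function(geometry, target_pos) {
  stopifnot(inherits(geometry, "overlap_geometry"))
  target_pos <- as.integer(target_pos)
  if (target_pos < geometry$target_span[1L] ||
      target_pos >= geometry$target_span[2L]) {
    stop("target_pos ", target_pos, " lies outside the shared span [",
         geometry$target_span[1L], ", ", geometry$target_span[2L], ")",
         call. = FALSE)
  }
  r <- target_pos - geometry$target_span[1L]
  ov_pos <- if (geometry$strand == "same") {
    geometry$overlap_span[1L] + r
  } else {
    geometry$overlap_span[2L] - 1L - r
  }
  list(
    codon_index = ov_pos %/% 3L,
    offset_in_codon = ov_pos %% 3L,
    strand = geometry$strand,
    overlap_pos = ov_pos
  )
}
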