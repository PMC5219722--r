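# Core nucleic-acid machinery: alphabet validation, complementation,
# translation, degenerate (IUPAC) matching and FASTA I/O. Everything else in
# the package is built on these primitives.

# IUPAC nucleotide codes as bitmasks over {A=1, C=2, G=4, T=8}. Matching and
# complementation are bit operations on these masks.
IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L,  # A/G
  Y = 10L, # C/T
  S = 6L,  # C/G
  W = 9L,  # A/T
  K = 12L, # G/T
  M = 3L,  # A/C
  B = 14L, # C/G/T
  D = 13L, # A/G/T
  H = 11L, # A/C/T
  V = 7L,  # A/C/G
  N = 15L
)

# Complement of each code: swap the A and T bits and the C and G bits.
IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

#' The standard genetic code
#'
#' Returns the standard (translation table 1) codon-to-amino-acid map as a
#' named character vector of 64 entries, with the three stop codons (TAA,
#' TAG, TGA) mapped to `"*"`. [translate()] accepts any table with this
#' shape, so alternative genetic codes can be supplied programmatically;
#' only the standard code is bundled.
#'
#' @return Named character vector: names are the 64 unambiguous codons,
#'   values are one-letter amino acids (`"*"` for stop).
#' @examples
#' standard_genetic_code()[c("ATG", "TCA", "TAA")]
#' @export
standard_genetic_code <- function() {
  bases <- c("T", "C", "A", "G")
  # base1 varies slowest, then base2, then base3 -- the classical TCAG
  # table layout, matching the amino-acid string below.
  codons <- paste0(
    rep(bases, each = 16L),
    rep(rep(bases, each = 4L), times = 4L),
    rep(bases, times = 16L)
  )
  aas <- strsplit(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
    ""
  )[[1L]]
  stats::setNames(aas, codons)
}

.GENETIC_CODE <- standard_genetic_code()

.code_table <- function(table = NULL) {
  if (is.null(table)) .GENETIC_CODE else table
}

#' Validate and normalise a nucleotide sequence
#'
#' Uppercases the input, converts `U` to `T`, and checks every residue
#' against the 15-letter IUPAC nucleotide alphabet. All package functions
#' call this on their sequence arguments, so mixed-case or RNA-style input
#' is accepted anywhere.
#'
#' @param x Single character string.
#' @param allow_ambiguous If `FALSE`, ambiguity codes (anything outside
#'   A/C/G/T) are rejected too.
#' @param what Label used in error messages.
#' @return The normalised sequence string.
#' @examples
#' nt_sequence("augC")  # "ATGC"
#' @export
nt_sequence <- function(x, allow_ambiguous = TRUE, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  s <- chartr("u", "T", toupper(x))
  s <- chartr("U", "T", s)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  alphabet <- if (allow_ambiguous) names(IUPAC_BITS) else c("A", "C", "G", "T")
  bad <- which(!(chars %in% alphabet))
  if (length(bad)) {
    stop(
      what, ": invalid residue '", chars[bad[1L]], "' at position ",
      bad[1L] - 1L, " (0-based)",
      call. = FALSE
    )
  }
  s
}

.seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

.seq_bits <- function(seq) unname(IUPAC_BITS[.seq_chars(seq)])

#' Reverse complement
#'
#' Watson-Crick complement in reverse order. Ambiguity codes map to their
#' complementary degeneracy sets (R to Y, K to M, S/W/N to themselves, ...),
#' so the operation is an involution on any IUPAC sequence.
#'
#' @param seq Nucleotide sequence (string; validated and normalised).
#' @return The reverse-complemented sequence string.
#' @examples
#' reverse_complement("ATGC") # "GCAT"
#' @export
reverse_complement <- function(seq) {
  seq <- nt_sequence(seq)
  if (nchar(seq) == 0L) return(seq)
  paste(rev(unname(IUPAC_COMPLEMENT[.seq_chars(seq)])), collapse = "")
}

.complement_base <- function(base) unname(IUPAC_COMPLEMENT[base])

#' Translate a nucleotide sequence
#'
#' Translates frame 0 codon by codon. Stop codons emit `"*"` and translation
#' continues to the end of the sequence, so every stop in the frame is
#' visible -- knockout verification depends on seeing internal stops. A
#' trailing partial codon (fewer than 3 nt) is ignored.
#'
#' @param seq Nucleotide sequence; must be unambiguous (A/C/G/T) over the
#'   translated span.
#' @param table Codon table as returned by [standard_genetic_code()]
#'   (the default).
#' @return Protein string of length `floor(nchar(seq) / 3)`.
#' @examples
#' translate("ATGGATTAA") # "MD*"
#' @export
translate <- function(seq, table = NULL) {
  seq <- nt_sequence(seq)
  table <- .code_table(table)
  n_codon <- nchar(seq) %/% 3L
  if (n_codon == 0L) return("")
  starts <- seq.int(1L, by = 3L, length.out = n_codon)
  codons <- substring(seq, starts, starts + 2L)
  aa <- table[codons]
  if (anyNA(aa)) {
    bad <- which(is.na(aa))[1L]
    stop(
      "cannot translate ambiguous codon '", codons[bad],
      "' at codon index ", bad - 1L, " (0-based)",
      call. = FALSE
    )
  }
  paste(aa, collapse = "")
}

#' Match a degenerate pattern against a concrete window
#'
#' Tests whether an equal-length window of unambiguous DNA is covered by an
#' IUPAC-degenerate pattern: at every position the window base must lie in
#' the degeneracy set of the pattern base. This is the primitive behind
#' restriction-site scanning, where enzymes such as HinfI (GANTC) carry
#' degenerate recognition sequences.
#'
#' @param pattern IUPAC pattern (may contain ambiguity codes).
#' @param window Unambiguous sequence of the same length.
#' @return `TRUE` or `FALSE`.
#' @examples
#' iupac_match("GANTC", "GATTC") # TRUE
#' iupac_match("GANTC", "GAGGC") # FALSE
#' @export
iupac_match <- function(pattern, window) {
  pattern <- nt_sequence(pattern, what = "pattern")
  window <- nt_sequence(window, allow_ambiguous = FALSE, what = "window")
  if (nchar(pattern) != nchar(window)) {
    stop("pattern and window must have equal length", call. = FALSE)
  }
  all(bitwAnd(.seq_bits(pattern), .seq_bits(window)) > 0L)
}

# Vectorised core of find_sites: positions (1-based) in `bits` where the
# pattern mask vector matches. Shared by the restriction module.
.match_positions <- function(pattern_bits, bits) {
  k <- length(pattern_bits)
  n <- length(bits)
  if (n < k) return(integer(0L))
  ok <- rep(TRUE, n - k + 1L)
  idx <- seq_len(n - k + 1L)
  for (j in seq_len(k)) {
    ok <- ok & bitwAnd(pattern_bits[j], bits[idx + j - 1L]) > 0L
  }
  which(ok)
}

#' Read a FASTA file
#'
#' Parses plain-text FASTA: `>`-headers, wrapped or unwrapped sequence
#' lines, CRLF line endings tolerated. The identifier is the first
#' whitespace-delimited token of the header; the remainder is the
#' description. Gap characters or whitespace *inside* a sequence body are an
#' error, not silently stripped -- coding sequences must be contiguous.
#'
#' @param path File path, connection, or a character vector of lines.
#' @return Data frame with columns `id`, `desc`, `seq`, one row per record.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  lines <- if (is.character(path) && length(path) != 1L) {
    path
  } else if (is.character(path) &&
             (startsWith(path, ">") || grepl("\n", path, fixed = TRUE))) {
    strsplit(path, "\n", fixed = TRUE)[[1L]]
  } else {
    readLines(path)
  }
  lines <- sub("\r$", "", lines)
  hdr <- which(startsWith(lines, ">"))
  if (length(hdr) == 0L) {
    stop("not a FASTA file: no '>' header found", call. = FALSE)
  }
  if (hdr[1L] != 1L && any(nzchar(trimws(lines[seq_len(hdr[1L] - 1L)])))) {
    stop("FASTA parse error at line 1: content before first '>' header",
         call. = FALSE)
  }
  n <- length(hdr)
  ids <- character(n)
  descs <- character(n)
  seqs <- character(n)
  bounds <- c(hdr, length(lines) + 1L)
  for (i in seq_len(n)) {
    header <- sub("^>", "", lines[hdr[i]])
    header <- trimws(header)
    if (!nzchar(header)) {
      stop("FASTA parse error at line ", hdr[i], ": empty identifier",
           call. = FALSE)
    }
    sp <- regexpr("\\s", header)
    if (sp > 0L) {
      ids[i] <- substr(header, 1L, sp - 1L)
      descs[i] <- trimws(substr(header, sp + 1L, nchar(header)))
    } else {
      ids[i] <- header
      descs[i] <- ""
    }
    body_lines <- lines[seq.int(hdr[i] + 1L, length.out = bounds[i + 1L] - hdr[i] - 1L)]
    body_lines <- body_lines[nzchar(body_lines)]
    if (length(body_lines) == 0L) {
      stop("FASTA parse error at line ", hdr[i], ": record '", ids[i],
           "' has no sequence lines", call. = FALSE)
    }
    if (any(grepl("[\\s-]", body_lines, perl = TRUE))) {
      off <- which(grepl("[\\s-]", body_lines, perl = TRUE))[1L]
      stop("FASTA parse error near line ", hdr[i] + off,
           ": whitespace or gap character inside sequence body",
           call. = FALSE)
    }
    seqs[i] <- nt_sequence(paste(body_lines, collapse = ""),
                           what = paste0("record '", ids[i], "'"))
  }
  data.frame(id = ids, desc = descs, seq = seqs, stringsAsFactors = FALSE)
}

#' Write records to FASTA
#'
#' Emits `>`-headers (`id` plus `desc` when non-empty) and sequence lines
#' wrapped at 70 columns. Round-trips with [read_fasta()] exactly.
#'
#' @param records Data frame with columns `id`, `seq` and optionally `desc`.
#' @param path File path or connection; use `stdout()` to print.
#' @param width Line-wrap width in columns.
#' @return Invisibly, the character vector of lines written.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  desc <- if ("desc" %in% names(records)) records$desc else rep("", nrow(records))
  out <- character(0L)
  for (i in seq_len(nrow(records))) {
    header <- if (nzchar(desc[i])) paste(records$id[i], desc[i]) else records$id[i]
    s <- records$seq[i]
    starts <- seq.int(1L, nchar(s), by = width)
    out <- c(out, paste0(">", header), substring(s, starts, starts + width - 1L))
  }
  writeLines(out, path)
  invisible(out)
}
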