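# Independent oracles used across the suite. Deliberately naive: exhaustive
# enumeration and third-party translation (Biostrings), sharing as little
# code as possible with the package's own search paths.

BASES <- c("A", "C", "G", "T")
STOPS <- c("TAA", "TAG", "TGA")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# Third-party translator: full-length, through internal stops.
bs_translate <- function(seq) {
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(seq, 1L, 3L * (nchar(seq) %/% 3L))),
    no.init.codon = TRUE
  ))
}

# Splice the (possibly mutated) target's shared span into the overlapping
# gene as a single block -- a geometry-level reconstruction that never uses
# map_position().
splice_overlapping <- function(pair, mutant_target) {
  g <- pair$geometry
  block <- substr(mutant_target, g$target_span[1L] + 1L, g$target_span[2L])
  if (g$strand == "opposite") block <- reverse_complement(block)
  paste0(
    substr(pair$overlapping, 1L, g$overlap_span[1L]),
    block,
    substr(pair$overlapping, g$overlap_span[2L] + 1L, nchar(pair$overlapping))
  )
}

mutate_at <- function(seq, pos0, base) {
  # pos0 is 0-based
  paste0(substr(seq, 1L, pos0), base, substr(seq, pos0 + 2L, nchar(seq)))
}

# Brute-force knockout oracle: try all 9L single-base variants of the
# target; keep those that create a new stop codon (at codon index >= 1) or
# destroy the ATG, with the overlapping protein unchanged under Biostrings
# translation of the spliced mutant.
oracle_knockouts <- function(pair) {
  target <- pair$target
  wt_ov_protein <- bs_translate(pair$overlapping)
  n <- nchar(target)
  rows <- list()
  chars <- strsplit(target, "")[[1L]]
  for (pos0 in 0:(n - 1L)) {
    ci <- pos0 %/% 3L
    wt_codon <- substr(target, 3L * ci + 1L, 3L * ci + 3L)
    if (nchar(wt_codon) < 3L) next
    for (b in setdiff(BASES, chars[pos0 + 1L])) {
      mut_target <- mutate_at(target, pos0, b)
      new_codon <- substr(mut_target, 3L * ci + 1L, 3L * ci + 3L)
      kind <- if (ci == 0L && new_codon != "ATG" && wt_codon == "ATG") {
        "start_loss"
      } else if (ci >= 1L && new_codon %in% STOPS && !(wt_codon %in% STOPS)) {
        "premature_stop"
      } else {
        next
      }
      mut_ov <- splice_overlapping(pair, mut_target)
      if (bs_translate(mut_ov) != wt_ov_protein) next
      rows[[length(rows) + 1L]] <- data.frame(
        kind = kind, codon_index = ci, new_codon = new_codon,
        edits = sprintf("%d:%s>%s", pos0, chars[pos0 + 1L], b),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(kind = character(0L), codon_index = integer(0L),
                      new_codon = character(0L), edits = character(0L),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$codon_index, out$new_codon, out$edits), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Expand an IUPAC pattern into its set of concrete sequences.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

expand_pattern <- function(pattern) {
  sets <- IUPAC_SETS[strsplit(pattern, "")[[1L]]]
  grid <- do.call(expand.grid, c(unname(sets), stringsAsFactors = FALSE))
  apply(grid, 1L, paste, collapse = "")
}

# Occurrences (0-based starts) of any concrete expansion; a zero-width
# lookahead makes gregexpr report overlapping occurrences too.
concrete_starts <- function(concrete, seq) {
  hits <- integer(0L)
  for (p in concrete) {
    m <- gregexpr(paste0("(?=", p, ")"), seq, perl = TRUE)[[1L]]
    if (m[1L] != -1L) hits <- c(hits, as.integer(m) - 1L)
  }
  sort(unique(hits))
}

# Expand-and-scan restriction-site oracle, both strands, palindromes
# reported once on the forward strand.
oracle_sites <- function(seq, enzymes) {
  rows <- list()
  for (i in seq_len(nrow(enzymes))) {
    rec <- enzymes$recognition[i]
    fwd <- concrete_starts(expand_pattern(rec), seq)
    if (length(fwd)) {
      rows[[length(rows) + 1L]] <- data.frame(
        enzyme = enzymes$name[i], position = fwd, strand = "forward",
        stringsAsFactors = FALSE)
    }
    if (!enzymes$palindromic[i]) {
      rev_ <- concrete_starts(expand_pattern(reverse_complement(rec)), seq)
      if (length(rev_)) {
        rows[[length(rows) + 1L]] <- data.frame(
          enzyme = enzymes$name[i], position = rev_, strand = "reverse",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(enzyme = character(0L), position = integer(0L),
               strand = character(0L), stringsAsFactors = FALSE)
  out <- out[order(out$position, out$enzyme, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Canonical comparable form of a knockout_candidates table.
candidate_key <- function(ko) {
  df <- as.data.frame(ko)[, c("kind", "codon_index", "new_codon", "edits")]
  df <- df[order(df$codon_index, df$new_codon, df$edits), , drop = FALSE]
  rownames(df) <- NULL
  df
}
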