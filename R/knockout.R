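# Knockout search: enumerate minimal nucleotide substitutions that insert a
# premature stop codon into the target gene, or destroy its start codon,
# while leaving the overlapping gene's translated protein exactly unchanged.

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Start codons some viruses are known to initiate from; start-loss
# candidates mutating ATG into one of these are annotated, not filtered.
ALT_START_CODONS <- c("ACG", "GTG", "TTG", "CTG", "ATT", "ATA")

#' Search parameters for the knockout scan
#'
#' @param max_edits_per_codon Maximum substitutions per candidate, all
#'   within one target codon (1-3; the default 1 is a point mutation).
#' @param codon_window Only target codons with index `< codon_window` are
#'   searched for premature stops (`Inf` = whole gene). The survey statistic
#'   of "knockable within the first 20 codons" corresponds to
#'   `codon_window = 20`, i.e. 0-based stop codon index < 20.
#' @param allow_start_loss Also report mutations of codon 0 away from ATG.
#' @param site_change_mode `"none"`, `"added"`, `"removed"` or `"either"`:
#'   restriction-site filter applied to the candidate list (see
#'   [filter_by_site_change()]).
#' @param force Proceed even when the target does not begin with ATG.
#' @return A list of class `search_params`.
#' @export
search_params <- function(max_edits_per_codon = 1L,
                          codon_window = Inf,
                          allow_start_loss = TRUE,
                          site_change_mode = c("none", "added", "removed", "either"),
                          force = FALSE) {
  max_edits_per_codon <- as.integer(max_edits_per_codon)
  if (max_edits_per_codon < 1L || max_edits_per_codon > 3L) {
    stop("max_edits_per_codon must be 1, 2 or 3", call. = FALSE)
  }
  if (!is.infinite(codon_window)) {
    codon_window <- as.integer(codon_window)
    if (codon_window < 1L) stop("codon_window must be >= 1", call. = FALSE)
  }
  structure(
    list(
      max_edits_per_codon = max_edits_per_codon,
      codon_window = codon_window,
      allow_start_loss = isTRUE(allow_start_loss),
      site_change_mode = match.arg(site_change_mode),
      force = isTRUE(force)
    ),
    class = "search_params"
  )
}

# ---- mutations ------------------------------------------------------------

# A mutation is a data.frame of single-base substitutions:
# pos (0-based, target coordinates), wt, mut.
.mutation <- function(pos, wt, mut) {
  data.frame(pos = as.integer(pos), wt = wt, mut = mut,
             stringsAsFactors = FALSE)
}

.format_edits <- function(edits) {
  paste(sprintf("%d:%s>%s", edits$pos, edits$wt, edits$mut), collapse = ";")
}

#' Parse an edit string back into substitutions
#'
#' Inverse of the `"pos:WT>MUT;..."` serialisation used in candidate tables
#' and TSV reports.
#'
#' @param x Edit string such as `"10:C>A"` or `"1:T>C;2:G>A"`.
#' @return Data frame with columns `pos` (0-based), `wt`, `mut`.
#' @export
parse_edits <- function(x) {
  parts <- strsplit(x, ";", fixed = TRUE)[[1L]]
  m <- regmatches(parts, regexec("^([0-9]+):([ACGT])>([ACGT])$", parts))
  if (any(lengths(m) != 4L)) {
    stop("malformed edit string: '", x, "'", call. = FALSE)
  }
  .mutation(
    pos = vapply(m, function(g) as.integer(g[2L]), integer(1L)),
    wt = vapply(m, `[`, character(1L), 3L),
    mut = vapply(m, `[`, character(1L), 4L)
  )
}

#' Apply substitutions to a sequence
#'
#' @param seq Nucleotide sequence.
#' @param edits Data frame of edits (`pos` 0-based, `wt`, `mut`), e.g. from
#'   [parse_edits()]. Wild-type bases are checked before substitution.
#' @return The mutated sequence string.
#' @export
apply_mutation <- function(seq, edits) {
  seq <- nt_sequence(seq)
  chars <- .seq_chars(seq)
  idx <- edits$pos + 1L
  if (any(idx < 1L | idx > length(chars))) {
    stop("edit position outside sequence", call. = FALSE)
  }
  if (!all(chars[idx] == edits$wt)) {
    bad <- which(chars[idx] != edits$wt)[1L]
    stop("wild-type base mismatch at position ", edits$pos[bad], ": sequence has '",
         chars[idx[bad]], "', edit expects '", edits$wt[bad], "'", call. = FALSE)
  }
  chars[idx] <- edits$mut
  paste(chars, collapse = "")
}

# ---- stop reachability ----------------------------------------------------

#' Substitutions turning a codon into a stop codon
#'
#' For each stop codon (TAA, TAG, TGA) within `max_edits` Hamming distance
#' of `codon`, returns the stop reached and the codon-local substitutions
#' used. Results are ordered by edit count, then stop codon alphabetically.
#'
#' @param codon Unambiguous 3-mer that is not already a stop codon.
#' @param max_edits Maximum substitutions (1-3).
#' @return Data frame with columns `stop_codon`, `n_edits`, `edits`
#'   (codon-local 0-based positions, serialised `"pos:WT>MUT"`).
#' @examples
#' stop_substitutions("TCA")        # TAA and TGA, one edit each
#' stop_substitutions("GGG")        # no stop reachable with one edit
#' @export
stop_substitutions <- function(codon, max_edits = 1L) {
  codon <- nt_sequence(codon, allow_ambiguous = FALSE, what = "codon")
  if (nchar(codon) != 3L) stop("codon must be exactly 3 nt", call. = FALSE)
  if (codon %in% STOP_CODONS) {
    stop("codon is already a stop", call. = FALSE)
  }
  cc <- .seq_chars(codon)
  out <- lapply(STOP_CODONS, function(sc) {
    scc <- .seq_chars(sc)
    diff_pos <- which(cc != scc)
    if (length(diff_pos) > max_edits) return(NULL)
    edits <- .mutation(diff_pos - 1L, cc[diff_pos], scc[diff_pos])
    data.frame(
      stop_codon = sc,
      n_edits = length(diff_pos),
      edits = .format_edits(edits),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(stop_codon = character(0L), n_edits = integer(0L),
                      edits = character(0L), stringsAsFactors = FALSE)
  }
  out[order(out$n_edits, out$stop_codon), , drop = FALSE]
}

# ---- preservation of the overlapping protein ------------------------------

# Project target-coordinate edits into the overlapping gene and return the
# full mutant overlapping sequence. Edits outside the shared span leave the
# overlapping gene untouched.
.mutant_overlapping <- function(pair, edits) {
  g <- pair$geometry
  chars <- .seq_chars(pair$overlapping)
  for (i in seq_len(nrow(edits))) {
    p <- edits$pos[i]
    if (p < g$target_span[1L] || p >= g$target_span[2L]) next
    mp <- map_position(g, p)
    base <- edits$mut[i]
    if (g$strand == "opposite") base <- .complement_base(base)
    chars[mp$overlap_pos + 1L] <- base
  }
  paste(chars, collapse = "")
}

#' Does a mutation preserve the overlapping gene's protein?
#'
#' Projects the edits through the overlap geometry (complementing on the
#' opposite strand) and compares the translation of the mutant overlapping
#' gene with the wild type. Edits falling entirely outside the shared span
#' are unconstrained and return `TRUE`.
#'
#' @param pair A [gene_pair()].
#' @param edits Data frame of target-coordinate edits (see [parse_edits()]).
#' @return `TRUE` if the overlapping protein is unchanged.
#' @examples
#' pair <- sample_gene_pair()
#' preserves_overlap_protein(pair, parse_edits("1:T>C"))  # TAT -> TAC, TRUE
#' @export
preserves_overlap_protein <- function(pair, edits) {
  stopifnot(inherits(pair, "gene_pair"))
  if (any(edits$pos < 0L | edits$pos >= nchar(pair$target))) {
    stop("edit position outside the target gene", call. = FALSE)
  }
  g <- pair$geometry
  in_span <- edits$pos >= g$target_span[1L] & edits$pos < g$target_span[2L]
  if (!any(in_span)) return(TRUE)
  e <- edits[in_span, , drop = FALSE]
  # Only codons of the overlapping gene touched by an edit can change, so
  # comparing those codons' translations equals comparing the full mutant
  # and wild-type proteins (the independent full-translation check is a
  # test-suite invariant).
  maps <- lapply(e$pos, function(p) map_position(g, p))
  ci <- vapply(maps, function(m) m$codon_index, integer(1L))
  for (codon_idx in unique(ci)) {
    wt_codon <- substr(pair$overlapping, 3L * codon_idx + 1L,
                       3L * codon_idx + 3L)
    if (nchar(wt_codon) < 3L) next  # trailing partial codon: untranslated
    cc <- .seq_chars(wt_codon)
    for (j in which(ci == codon_idx)) {
      b <- e$mut[j]
      if (g$strand == "opposite") b <- .complement_base(b)
      cc[maps[[j]]$offset_in_codon + 1L] <- b
    }
    if (.GENETIC_CODE[[paste(cc, collapse = "")]] !=
        .GENETIC_CODE[[wt_codon]]) {
      return(FALSE)
    }
  }
  TRUE
}

# ---- candidate search -----------------------------------------------------

.codon_at <- function(seq, codon_index) {
  substr(seq, 3L * codon_index + 1L, 3L * codon_index + 3L)
}

# All codons within `max_edits` Hamming distance of `codon` (excluding
# codon itself), with their edit sets in codon-local coordinates.
.codon_neighbourhood <- function(codon, max_edits) {
  cc <- .seq_chars(codon)
  bases <- c("A", "C", "G", "T")
  all_codons <- names(.GENETIC_CODE)
  res <- lapply(all_codons, function(v) {
    vc <- .seq_chars(v)
    d <- which(vc != cc)
    if (length(d) == 0L || length(d) > max_edits) return(NULL)
    list(codon = v, edits = .mutation(d - 1L, cc[d], vc[d]))
  })
  res[!vapply(res, is.null, logical(1L))]
}

.empty_candidates <- function() {
  data.frame(
    kind = character(0L), codon_index = integer(0L),
    stop_codon_index = integer(0L), wt_codon = character(0L),
    new_codon = character(0L), edits = character(0L), n_edits = integer(0L),
    alt_start = logical(0L), sites_added = character(0L),
    sites_removed = character(0L), mutant_target = character(0L),
    mutant_overlapping = character(0L), stringsAsFactors = FALSE
  )
}

# Shift codon-local edits to absolute target coordinates.
.globalise <- function(edits, codon_index) {
  edits$pos <- edits$pos + 3L * codon_index
  edits
}

#' Find knockout mutations for the target gene
#'
#' Enumerates every candidate in which a single target codon is mutated
#' with at most `max_edits_per_codon` substitutions so that (a) a codon at
#' index 1 or later becomes a stop codon (premature stop), or (b) codon 0
#' loses its ATG (start loss), in both cases leaving the overlapping gene's
#' translated protein exactly unchanged. Start-loss candidates whose mutant
#' codon is a known alternate start (ACG, GTG, TTG, CTG, ATT, ATA) carry
#' `alt_start = TRUE`: some viruses initiate from such codons, so these
#' knockouts need biological validation.
#'
#' Candidates are sorted by codon index, then edit count, then mutant codon
#' alphabetically; start-loss candidates (codon 0) come first. The ordering
#' is fully deterministic so reports reproduce byte for byte.
#'
#' When `params$site_change_mode != "none"`, candidates are annotated with
#' restriction-site changes over the full mutant target and filtered; pass
#' `enzymes` to control the table used (default: the builtin table).
#'
#' @param pair A [gene_pair()]; the target must begin with ATG unless
#'   `params$force` is set.
#' @param params A [search_params()].
#' @param enzymes Enzyme table for site-change annotation (see
#'   [load_enzymes()]); only consulted when the mode requires it.
#' @return A data frame of class `knockout_candidates`; one row per
#'   candidate with the mutation (`edits`, 0-based target coordinates), the
#'   affected codon, the resulting full mutant sequences, and restriction
#'   site changes (`"."` when not annotated).
#' @examples
#' ko <- find_knockouts(sample_gene_pair())
#' ko[, c("kind", "codon_index", "wt_codon", "new_codon", "edits")]
#' @export
find_knockouts <- function(pair, params = search_params(), enzymes = NULL) {
  stopifnot(inherits(pair, "gene_pair"), inherits(params, "search_params"))
  target <- pair$target
  n_codons <- nchar(target) %/% 3L
  if (.codon_at(target, 0L) != "ATG" && !params$force) {
    stop("target does not begin with ATG; set search_params(force = TRUE) ",
         "to search anyway", call. = FALSE)
  }
  wt_protein <- translate(substr(target, 1L, 3L * n_codons))
  internal <- substr(wt_protein, 1L, n_codons - 1L)
  if (grepl("*", internal, fixed = TRUE)) {
    warning("wild-type target contains an internal stop codon; ",
            "input may be misannotated", call. = FALSE)
  }

  rows <- list()

  # (b) start loss: codon 0 mutated away from ATG.
  if (params$allow_start_loss && .codon_at(target, 0L) == "ATG") {
    for (nb in .codon_neighbourhood("ATG", params$max_edits_per_codon)) {
      edits <- .globalise(nb$edits, 0L)
      if (!preserves_overlap_protein(pair, edits)) next
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "start_loss", codon_index = 0L, stop_codon_index = NA_integer_,
        wt_codon = "ATG", new_codon = nb$codon,
        edits = .format_edits(edits), n_edits = nrow(edits),
        alt_start = nb$codon %in% ALT_START_CODONS,
        stringsAsFactors = FALSE
      )
    }
  }

  # (a) premature stops in codons [1, codon_window), never codon 0 and never
  # a codon that is already a stop in the wild type.
  last <- min(n_codons - 1L, if (is.infinite(params$codon_window))
    n_codons - 1L else params$codon_window - 1L)
  for (ci in seq_len(max(0L, last))) {
    wt_codon <- .codon_at(target, ci)
    if (wt_codon %in% STOP_CODONS) next
    subs <- stop_substitutions(wt_codon, params$max_edits_per_codon)
    for (k in seq_len(nrow(subs))) {
      edits <- .globalise(parse_edits(subs$edits[k]), ci)
      if (!preserves_overlap_protein(pair, edits)) next
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "premature_stop", codon_index = ci, stop_codon_index = ci,
        wt_codon = wt_codon, new_codon = subs$stop_codon[k],
        edits = .format_edits(edits), n_edits = nrow(edits),
        alt_start = NA, stringsAsFactors = FALSE
      )
    }
  }

  if (length(rows) == 0L) {
    out <- .empty_candidates()
  } else {
    out <- do.call(rbind, rows)
    out <- out[order(out$codon_index, out$n_edits, out$new_codon), ,
               drop = FALSE]
    out$sites_added <- "."
    out$sites_removed <- "."
    out$mutant_target <- vapply(out$edits, function(e)
      apply_mutation(target, parse_edits(e)), character(1L), USE.NAMES = FALSE)
    out$mutant_overlapping <- vapply(out$edits, function(e)
      .mutant_overlapping(pair, parse_edits(e)), character(1L),
      USE.NAMES = FALSE)
    out <- out[, names(.empty_candidates())]
    rownames(out) <- NULL
  }
  class(out) <- c("knockout_candidates", "data.frame")
  attr(out, "pair") <- pair
  attr(out, "params") <- params

  if (params$site_change_mode != "none") {
    out <- annotate_site_changes(out, enzymes = if (is.null(enzymes))
      "builtin" else enzymes)
    out <- filter_by_site_change(out, params$site_change_mode)
  } else if (!is.null(enzymes)) {
    out <- annotate_site_changes(out, enzymes = enzymes)
  }
  out
}

#' @export
print.knockout_candidates <- function(x, ...) {
  if (!all(c("kind", "codon_index") %in% names(x))) {
    return(NextMethod())  # column-subset views print as plain data frames
  }
  cat("knockout candidates: ", nrow(x), " (",
      sum(x$kind == "start_loss"), " start-loss, ",
      sum(x$kind == "premature_stop"), " premature-stop)\n", sep = "")
  if (nrow(x)) {
    cols <- intersect(c("kind", "codon_index", "wt_codon", "new_codon",
                        "edits", "n_edits", "alt_start", "sites_added",
                        "sites_removed"), names(x))
    print.data.frame(x[, cols, drop = FALSE], row.names = FALSE)
  }
  invisible(x)
}

#' First codon index at which a premature stop can be inserted
#'
#' The per-gene survey statistic: the minimum stop codon index over all
#' premature-stop candidates (start-loss candidates are excluded), or `NA`
#' if no premature stop is reachable under the given parameters. A stop
#' within the first 20 codons (`first_knockout_codon(...) < 20`) truncates
#' the protein to at most 20 residues, which is very unlikely to retain
#' function.
#'
#' @inheritParams find_knockouts
#' @return Integer codon index (0-based) or `NA_integer_`.
#' @examples
#' first_knockout_codon(sample_gene_pair())  # 3
#' @export
first_knockout_codon <- function(pair, params = search_params(), enzymes = NULL) {
  stopifnot(inherits(pair, "gene_pair"), inherits(params, "search_params"))
  target <- pair$target
  n_codons <- nchar(target) %/% 3L
  if (.codon_at(target, 0L) != "ATG" && !params$force) {
    stop("target does not begin with ATG; set search_params(force = TRUE) ",
         "to search anyway", call. = FALSE)
  }
  need_sites <- params$site_change_mode != "none"
  enz <- if (need_sites) {
    .resolve_enzymes(if (is.null(enzymes)) "builtin" else enzymes)
  } else NULL
  last <- min(n_codons - 1L, if (is.infinite(params$codon_window))
    n_codons - 1L else params$codon_window - 1L)
  # Candidates are examined in increasing codon index, so the first hit is
  # the minimum -- no need to enumerate the rest of the gene.
  for (ci in seq_len(max(0L, last))) {
    wt_codon <- .codon_at(target, ci)
    if (wt_codon %in% STOP_CODONS) next
    subs <- stop_substitutions(wt_codon, params$max_edits_per_codon)
    for (k in seq_len(nrow(subs))) {
      edits <- .globalise(parse_edits(subs$edits[k]), ci)
      if (!preserves_overlap_protein(pair, edits)) next
      if (!need_sites) return(ci)
      sc <- site_changes(target, apply_mutation(target, edits), enz)
      hit <- switch(params$site_change_mode,
                    added = nrow(sc$added) > 0L,
                    removed = nrow(sc$removed) > 0L,
                    either = nrow(sc$added) > 0L || nrow(sc$removed) > 0L)
      if (hit) return(ci)
    }
  }
  NA_integer_
}

#' Enumerate mutations silent with respect to the overlapping gene
#'
#' All single-base substitutions at target positions inside the shared span
#' that leave the overlapping gene's protein unchanged, regardless of their
#' effect on the target. This is the raw material for any constrained
#' mutagenesis of the overprinted region.
#'
#' @param pair A [gene_pair()].
#' @return Data frame with columns `pos` (0-based target coordinate), `wt`,
#'   `mut`, ordered by position then mutant base.
#' @export
enumerate_neutral_mutations <- function(pair) {
  stopifnot(inherits(pair, "gene_pair"))
  g <- pair$geometry
  span <- seq.int(g$target_span[1L], g$target_span[2L] - 1L)
  chars <- .seq_chars(pair$target)
  bases <- c("A", "C", "G", "T")
  rows <- list()
  for (p in span) {
    wt <- chars[p + 1L]
    for (b in setdiff(bases, wt)) {
      if (preserves_overlap_protein(pair, .mutation(p, wt, b))) {
        rows[[length(rows) + 1L]] <- .mutation(p, wt, b)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(pos = integer(0L), wt = character(0L),
                      mut = character(0L), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$pos, out$mut), , drop = FALSE]
}

#' Residue-class constrained mutagenesis
#'
#' Generalises the knockout search to arbitrary amino-acid classes: for
#' every target codon whose residue satisfies `from_class`, enumerate every
#' codon reachable with at most `max_edits_per_codon` substitutions whose
#' residue satisfies `to_class` and which preserves the overlapping gene's
#' protein. With `from_class = is_residue("S")` and
#' `to_class = is_stop_residue()` this reproduces the premature-stop search
#' restricted to serine codons.
#'
#' @param pair A [gene_pair()].
#' @param from_class,to_class Predicates over one-letter residues
#'   (vectorised, total over the 20 amino acids and `"*"`); see
#'   [is_hydrophobic()], [is_residue()], [is_stop_residue()].
#' @param params A [search_params()]; `codon_window` limits the codons
#'   scanned, codon 0 is included here (this is not a stop-specific search).
#' @return Data frame with columns `codon_index`, `wt_codon`, `new_codon`,
#'   `wt_aa`, `new_aa`, `edits`, `n_edits`, `mutant_target`, ordered like
#'   [find_knockouts()].
#' @export
constrained_codon_mutagenesis <- function(pair, from_class, to_class,
                                          params = search_params()) {
  stopifnot(inherits(pair, "gene_pair"), inherits(params, "search_params"))
  target <- pair$target
  n_codons <- nchar(target) %/% 3L
  last <- if (is.infinite(params$codon_window)) n_codons - 1L else
    min(n_codons - 1L, params$codon_window - 1L)
  rows <- list()
  for (ci in 0L:last) {
    wt_codon <- .codon_at(target, ci)
    wt_aa <- unname(.GENETIC_CODE[wt_codon])
    if (!isTRUE(from_class(wt_aa))) next
    for (nb in .codon_neighbourhood(wt_codon, params$max_edits_per_codon)) {
      new_aa <- unname(.GENETIC_CODE[nb$codon])
      if (!isTRUE(to_class(new_aa))) next
      edits <- .globalise(nb$edits, ci)
      if (!preserves_overlap_protein(pair, edits)) next
      rows[[length(rows) + 1L]] <- data.frame(
        codon_index = ci, wt_codon = wt_codon, new_codon = nb$codon,
        wt_aa = wt_aa, new_aa = new_aa, edits = .format_edits(edits),
        n_edits = nrow(edits), stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(codon_index = integer(0L), wt_codon = character(0L),
                      new_codon = character(0L), wt_aa = character(0L),
                      new_aa = character(0L), edits = character(0L),
                      n_edits = integer(0L), mutant_target = character(0L),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$codon_index, out$n_edits, out$new_codon), , drop = FALSE]
  out$mutant_target <- vapply(out$edits, function(e)
    apply_mutation(target, parse_edits(e)), character(1L), USE.NAMES = FALSE)
  rownames(out) <- NULL
  out
}

#' Amino-acid class predicates
#'
#' Helpers for [constrained_codon_mutagenesis()]. The hydrophobic set
#' {A, V, L, I, M, F, W, P} is a common convention, not a universal
#' definition; supply your own predicate for a different classification.
#'
#' @param aa One-letter residue code (`"*"` is the stop symbol).
#' @param residues For [is_residue()], the set of one-letter codes the
#'   returned predicate accepts.
#' @return `is_hydrophobic` returns a logical; `is_residue` and
#'   `is_stop_residue` return predicate functions.
#' @export
is_hydrophobic <- function(aa) aa %in% c("A", "V", "L", "I", "M", "F", "W", "P")

#' @rdname is_hydrophobic
#' @export
is_residue <- function(residues) {
  force(residues)
  function(aa) aa %in% residues
}

#' @rdname is_hydrophobic
#' @export
is_stop_residue <- function() function(aa) aa == "*"
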