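# Restriction-site scanning and site-change accounting. Designed mutations
# that add or remove a recognition site can be traced by digest instead of
# sequencing, so every knockout candidate can be annotated with the sites
# it gains or loses on the full mutant target (the construct being cloned).

#' Load a restriction enzyme table
#'
#' Parses a plain-text enzyme table, one `Name Recognition` pair per line
#' (any whitespace separator), `#` comments and blank lines ignored.
#' Recognition sequences are 4-8 nt and may contain IUPAC ambiguity codes
#' (e.g. HinfI GANTC). `source = "builtin"` loads the bundled table of
#' 80 common commercial enzymes shipped with the package in the same
#' format (`system.file("extdata", "enzymes_builtin.txt", package =
#' "overko")`). Exact duplicate lines are dropped; two different
#' recognition sequences under one name are an error.
#'
#' @param source `"builtin"`, a file path, or a character vector of lines.
#' @return Data frame with columns `name`, `recognition`, `palindromic`
#'   (recognition equals its own reverse complement under IUPAC equality).
#' @examples
#' load_enzymes(c("EcoRI GAATTC", "HinfI GANTC"))
#' @export
load_enzymes <- function(source = "builtin") {
  if (identical(source, "builtin")) {
    source <- system.file("extdata", "enzymes_builtin.txt", package = "overko",
                          mustWork = TRUE)
  }
  lines <- if (is.character(source) && length(source) > 1L) source
           else if (is.character(source) && !file.exists(source) &&
                    grepl("\\s", source)) source
           else readLines(source)
  lines_raw <- sub("\r$", "", lines)
  stripped <- sub("#.*$", "", lines_raw)
  keep <- which(nzchar(trimws(stripped)))
  names_ <- character(0L)
  recs <- character(0L)
  for (ln in keep) {
    tokens <- strsplit(trimws(stripped[ln]), "\\s+")[[1L]]
    if (length(tokens) != 2L) {
      stop("enzyme table line ", ln, ": expected 'Name Recognition', got '",
           trimws(lines_raw[ln]), "'", call. = FALSE)
    }
    rec <- tryCatch(
      nt_sequence(tokens[2L], what = paste0("enzyme ", tokens[1L])),
      error = function(e) stop("enzyme table line ", ln, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    if (nchar(rec) < 4L || nchar(rec) > 8L) {
      stop("enzyme table line ", ln, ": recognition sequence must be 4-8 nt, '",
           rec, "' is ", nchar(rec), call. = FALSE)
    }
    dup <- which(names_ == tokens[1L])
    if (length(dup)) {
      if (recs[dup] == rec) next  # exact duplicate entry: drop silently
      stop("enzyme table line ", ln, ": duplicate name '", tokens[1L],
           "' with a different recognition sequence", call. = FALSE)
    }
    names_ <- c(names_, tokens[1L])
    recs <- c(recs, rec)
  }
  if (length(names_) == 0L) {
    stop("enzyme table is empty", call. = FALSE)
  }
  data.frame(
    name = names_,
    recognition = recs,
    palindromic = vapply(recs, function(r) r == reverse_complement(r),
                         logical(1L), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

.resolve_enzymes <- function(enzymes) {
  if (is.data.frame(enzymes)) {
    stopifnot(all(c("name", "recognition", "palindromic") %in% names(enzymes)))
    enzymes
  } else {
    load_enzymes(enzymes)
  }
}

#' Scan a sequence for restriction sites
#'
#' Every window of each enzyme's recognition length is tested with IUPAC
#' degenerate matching. Non-palindromic enzymes are scanned on both strands
#' (double-stranded DNA is cut regardless of written orientation); a match
#' of the reverse-complemented recognition sequence is reported with
#' `strand = "reverse"` at its forward-strand position. For palindromic
#' enzymes only the forward match is reported -- one site, not two.
#'
#' @param seq Unambiguous nucleotide sequence.
#' @param enzymes Enzyme table (data frame from [load_enzymes()], a path,
#'   or `"builtin"`).
#' @return Data frame with columns `enzyme`, `position` (0-based index of
#'   the 5'-most matched base on the forward strand), `strand`
#'   (`"forward"`/`"reverse"`), sorted by position then enzyme name.
#' @examples
#' find_sites("AAGAATTCAA", load_enzymes(c("EcoRI GAATTC")))
#' @export
find_sites <- function(seq, enzymes = "builtin") {
  seq <- nt_sequence(seq, allow_ambiguous = FALSE)
  enzymes <- .resolve_enzymes(enzymes)
  bits <- .seq_bits(seq)
  rows <- vector("list", nrow(enzymes))
  for (i in seq_len(nrow(enzymes))) {
    rec <- enzymes$recognition[i]
    fwd <- .match_positions(.seq_bits(rec), bits)
    pos <- fwd - 1L
    strand <- rep("forward", length(fwd))
    if (!enzymes$palindromic[i]) {
      rev_ <- .match_positions(.seq_bits(reverse_complement(rec)), bits)
      pos <- c(pos, rev_ - 1L)
      strand <- c(strand, rep("reverse", length(rev_)))
    }
    if (length(pos)) {
      rows[[i]] <- data.frame(enzyme = enzymes$name[i], position = pos,
                              strand = strand, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out)) {
    out <- data.frame(enzyme = character(0L), position = integer(0L),
                      strand = character(0L), stringsAsFactors = FALSE)
  }
  out <- out[order(out$position, out$enzyme, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restriction-site changes between a wild-type and a mutant sequence
#'
#' Set difference of [find_sites()] results keyed by (enzyme, position,
#' strand): sites present only in the mutant are `added`, sites present
#' only in the wild type are `removed`. The two sequences must have equal
#' length (substitution-only model). When the sequences differ only at a
#' few positions the scan is restricted to windows around the edits --
#' a site can only change if its window overlaps a changed base -- but the
#' result is identical to the whole-sequence set difference.
#'
#' @param wild,mutant Equal-length unambiguous sequences.
#' @param enzymes Enzyme table (see [find_sites()]).
#' @return List of class `site_change_set` with data-frame elements
#'   `added` and `removed`.
#' @examples
#' site_changes("TTGAATTCTT", "TTGACTTCTT", load_enzymes(c("EcoRI GAATTC")))
#' @export
site_changes <- function(wild, mutant, enzymes = "builtin") {
  wild <- nt_sequence(wild, allow_ambiguous = FALSE, what = "wild")
  mutant <- nt_sequence(mutant, allow_ambiguous = FALSE, what = "mutant")
  if (nchar(wild) != nchar(mutant)) {
    stop("wild and mutant must have equal length (substitutions only)",
         call. = FALSE)
  }
  enzymes <- .resolve_enzymes(enzymes)
  diff_pos <- which(.seq_chars(wild) != .seq_chars(mutant))  # 1-based
  if (length(diff_pos) == 0L) {
    empty <- data.frame(enzyme = character(0L), position = integer(0L),
                        strand = character(0L), stringsAsFactors = FALSE)
    return(structure(list(added = empty, removed = empty),
                     class = "site_change_set"))
  }
  max_k <- max(nchar(enzymes$recognition))
  # Any changed site's window must overlap a changed base; scan just the
  # covering window (clipped), then diff. Offsetting restores full-sequence
  # coordinates, so this equals the whole-sequence set difference.
  lo <- max(1L, min(diff_pos) - max_k + 1L)
  hi <- min(nchar(wild), max(diff_pos) + max_k - 1L)
  w_sites <- find_sites(substr(wild, lo, hi), enzymes)
  m_sites <- find_sites(substr(mutant, lo, hi), enzymes)
  w_sites$position <- w_sites$position + lo - 1L
  m_sites$position <- m_sites$position + lo - 1L
  key <- function(df) paste(df$enzyme, df$position, df$strand)
  added <- m_sites[!(key(m_sites) %in% key(w_sites)), , drop = FALSE]
  removed <- w_sites[!(key(w_sites) %in% key(m_sites)), , drop = FALSE]
  rownames(added) <- rownames(removed) <- NULL
  structure(list(added = added, removed = removed), class = "site_change_set")
}

#' @export
print.site_change_set <- function(x, ...) {
  cat("site changes: ", nrow(x$added), " added, ", nrow(x$removed),
      " removed\n", sep = "")
  if (nrow(x$added)) { cat("added:\n"); print.data.frame(x$added, row.names = FALSE) }
  if (nrow(x$removed)) { cat("removed:\n"); print.data.frame(x$removed, row.names = FALSE) }
  invisible(x)
}

.format_sites <- function(df) {
  if (nrow(df) == 0L) return(".")
  paste(sprintf("%s@%d%s", df$enzyme, df$position,
                ifelse(df$strand == "reverse", "(-)", "")), collapse = ";")
}

#' Annotate knockout candidates with restriction-site changes
#'
#' Scans the full mutant target of each candidate against the wild type and
#' fills the `sites_added` / `sites_removed` columns
#' (`"Enzyme@pos"`, semicolon-joined, `"(-)"` marking reverse-strand
#' matches of non-palindromic enzymes, `"."` for none).
#'
#' @param candidates A `knockout_candidates` table from [find_knockouts()].
#' @param enzymes Enzyme table (see [find_sites()]).
#' @return The candidate table with site columns populated.
#' @export
annotate_site_changes <- function(candidates, enzymes = "builtin") {
  stopifnot(inherits(candidates, "knockout_candidates"))
  enzymes <- .resolve_enzymes(enzymes)
  pair <- attr(candidates, "pair")
  wild <- if (!is.null(pair)) pair$target else NULL
  for (i in seq_len(nrow(candidates))) {
    w <- if (is.null(wild)) {
      # reconstruct the wild type by reverting the edits
      e <- parse_edits(candidates$edits[i])
      apply_mutation(candidates$mutant_target[i],
                     .mutation(e$pos, e$mut, e$wt))
    } else wild
    sc <- site_changes(w, candidates$mutant_target[i], enzymes)
    candidates$sites_added[i] <- .format_sites(sc$added)
    candidates$sites_removed[i] <- .format_sites(sc$removed)
  }
  candidates
}

#' Filter candidates by restriction-site change
#'
#' @param candidates A `knockout_candidates` table with populated site
#'   columns (see [annotate_site_changes()]).
#' @param mode `"none"` returns all candidates; `"added"` keeps those
#'   gaining at least one site; `"removed"` those losing at least one;
#'   `"either"` those doing either. Order is preserved.
#' @return The filtered candidate table.
#' @export
filter_by_site_change <- function(candidates,
                                  mode = c("none", "added", "removed", "either")) {
  mode <- match.arg(mode)
  if (mode == "none" || nrow(candidates) == 0L) return(candidates)
  has_added <- candidates$sites_added != "."
  has_removed <- candidates$sites_removed != "."
  keep <- switch(mode,
                 added = has_added,
                 removed = has_removed,
                 either = has_added | has_removed)
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
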