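# Batch engine: pair up targets and overlapping genes from FASTA files, run
# the knockout search on every pair, and write a machine-parseable TSV
# report plus the mutant target sequences as FASTA. Deterministic by
# construction: identical inputs and configuration give byte-identical
# outputs.

REPORT_COLUMNS <- c(
  "pair_id", "rank", "kind", "codon_index", "edits", "mutant_codon",
  "stop_codon", "sites_added", "sites_removed", "strand", "frame_shift",
  "note"
)

#' Batch run configuration
#'
#' @param target Path to the FASTA file of target genes (or a data frame
#'   from [read_fasta()]).
#' @param overlap Path to the FASTA file of overlapping genes (or a data
#'   frame).
#' @param pair_by `"order"` pairs records positionally (warning when counts
#'   differ, extras dropped); `"id"` pairs records whose identifiers (first
#'   whitespace-delimited header token) match, and errors listing unmatched
#'   ids.
#' @param params A [search_params()].
#' @param enzymes Enzyme table source (`"builtin"`, a path, or a data
#'   frame); used when `params$site_change_mode != "none"` or when
#'   `annotate = TRUE`.
#' @param annotate Populate site-change columns even when no site filter is
#'   requested.
#' @param min_overlap Minimum overlap length for [find_overlap()].
#' @param out_report,out_fasta Optional output paths (TSV report, mutant
#'   FASTA).
#' @return A list of class `run_config`.
#' @export
run_config <- function(target, overlap, pair_by = c("order", "id"),
                       params = search_params(), enzymes = "builtin",
                       annotate = TRUE, min_overlap = 15L,
                       out_report = NULL, out_fasta = NULL) {
  structure(
    list(
      target = target, overlap = overlap, pair_by = match.arg(pair_by),
      params = params, enzymes = enzymes, annotate = isTRUE(annotate),
      min_overlap = as.integer(min_overlap),
      out_report = out_report, out_fasta = out_fasta
    ),
    class = "run_config"
  )
}

.as_records <- function(x, what) {
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "seq") %in% names(x)))
    x
  } else {
    tryCatch(read_fasta(x), error = function(e)
      stop("cannot read ", what, " input: ", conditionMessage(e),
           call. = FALSE))
  }
}

.pair_records <- function(targets, overlaps, pair_by) {
  if (pair_by == "id") {
    unmatched <- c(setdiff(targets$id, overlaps$id),
                   setdiff(overlaps$id, targets$id))
    if (length(unmatched)) {
      stop("pairing by id failed; unmatched identifiers: ",
           paste(unique(unmatched), collapse = ", "), call. = FALSE)
    }
    overlaps <- overlaps[match(targets$id, overlaps$id), , drop = FALSE]
  } else if (nrow(targets) != nrow(overlaps)) {
    warning("target and overlapping FASTA files have different record ",
            "counts (", nrow(targets), " vs ", nrow(overlaps),
            "); pairing by order over the shorter file", call. = FALSE)
    n <- min(nrow(targets), nrow(overlaps))
    targets <- targets[seq_len(n), , drop = FALSE]
    overlaps <- overlaps[seq_len(n), , drop = FALSE]
  }
  list(targets = targets, overlaps = overlaps)
}

.diagnostic_row <- function(pair_id, note, strand = ".", frame_shift = ".") {
  data.frame(
    pair_id = pair_id, rank = ".", kind = ".", codon_index = ".",
    edits = ".", mutant_codon = ".", stop_codon = ".", sites_added = ".",
    sites_removed = ".", strand = strand, frame_shift = frame_shift,
    note = note, stringsAsFactors = FALSE
  )
}

#' Run the knockout search over batched FASTA input
#'
#' For each target / overlapping gene pair: detect the overlap, search for
#' knockout candidates, annotate restriction-site changes, apply the site
#' filter, and emit one report row per candidate plus one FASTA record per
#' mutant target (named `<pairid>|cand<rank>`). A pair whose overlap cannot
#' be detected, or that yields no candidate, contributes a diagnostic row
#' instead of failing the batch. Progress and warnings go to standard
#' error; data only to the returned values and the configured output files.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `report` (data frame in report-column
#'   order), `fasta` (data frame of mutant records), and `ok` (`TRUE` iff
#'   every pair was processed without diagnostics).
#' @export
run_find <- function(config) {
  stopifnot(inherits(config, "run_config"))
  targets <- .as_records(config$target, "target")
  overlaps <- .as_records(config$overlap, "overlapping")
  pr <- .pair_records(targets, overlaps, config$pair_by)
  targets <- pr$targets; overlaps <- pr$overlaps
  enz <- if (config$annotate || config$params$site_change_mode != "none") {
    .resolve_enzymes(config$enzymes)
  } else NULL

  report <- list()
  fasta <- list()
  all_ok <- TRUE
  for (i in seq_len(nrow(targets))) {
    pid <- targets$id[i]
    res <- tryCatch({
      pair <- gene_pair(targets$seq[i], overlaps$seq[i],
                        min_overlap = config$min_overlap)
      ko <- find_knockouts(pair, config$params, enzymes = enz)
      list(pair = pair, ko = ko)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      message("pair ", pid, ": ", res)
      report[[length(report) + 1L]] <- .diagnostic_row(pid, res)
      all_ok <- FALSE
      next
    }
    ko <- res$ko
    g <- res$pair$geometry
    if (nrow(ko) == 0L) {
      report[[length(report) + 1L]] <- .diagnostic_row(
        pid, "no knockout found", g$strand, as.character(g$frame_shift))
      next
    }
    rows <- data.frame(
      pair_id = pid,
      rank = as.character(seq_len(nrow(ko))),
      kind = ko$kind,
      codon_index = as.character(ko$codon_index),
      edits = ko$edits,
      mutant_codon = ko$new_codon,
      stop_codon = ifelse(ko$kind == "premature_stop", ko$new_codon, "."),
      sites_added = ko$sites_added,
      sites_removed = ko$sites_removed,
      strand = g$strand,
      frame_shift = as.character(g$frame_shift),
      note = ifelse(!is.na(ko$alt_start) & ko$alt_start,
                    "possible alternate start codon", "."),
      stringsAsFactors = FALSE
    )
    report[[length(report) + 1L]] <- rows
    fasta[[length(fasta) + 1L]] <- data.frame(
      id = sprintf("%s|cand%d", pid, seq_len(nrow(ko))),
      desc = sprintf("%s codon %d %s", ko$kind, ko$codon_index, ko$edits),
      seq = ko$mutant_target,
      stringsAsFactors = FALSE
    )
  }

  report <- if (length(report)) do.call(rbind, report) else
    stats::setNames(as.data.frame(matrix(character(0L), ncol =
      length(REPORT_COLUMNS))), REPORT_COLUMNS)
  fasta <- if (length(fasta)) do.call(rbind, fasta) else
    data.frame(id = character(0L), desc = character(0L),
               seq = character(0L), stringsAsFactors = FALSE)

  if (!is.null(config$out_report)) {
    utils::write.table(report[, REPORT_COLUMNS], config$out_report,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(config$out_fasta) && nrow(fasta)) {
    write_fasta(fasta, config$out_fasta)
  }
  invisible(list(report = report, fasta = fasta, ok = all_ok))
}

#' Scan FASTA records for restriction sites
#'
#' Runs [find_sites()] on every record of a FASTA input and returns (and
#' optionally writes) a TSV of matches: `record`, `enzyme`, `position`
#' (0-based), `strand`. Records with zero sites contribute no rows.
#'
#' @param input FASTA path or data frame from [read_fasta()].
#' @param enzymes Enzyme table source.
#' @param out Optional TSV output path.
#' @return Invisibly, the site data frame.
#' @export
run_scan <- function(input, enzymes = "builtin", out = NULL) {
  records <- .as_records(input, "scan")
  enz <- .resolve_enzymes(enzymes)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    s <- find_sites(records$seq[i], enz)
    if (nrow(s) == 0L) return(NULL)
    cbind(record = records$id[i], s, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  out_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(record = character(0L), enzyme = character(0L),
               position = integer(0L), strand = character(0L),
               stringsAsFactors = FALSE)
  if (!is.null(out)) {
    utils::write.table(out_df, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(out_df)
}
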