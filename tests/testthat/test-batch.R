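# Batch engine: FASTA in, TSV report + mutant FASTA out.

write_pair_fastas <- function(pairs, ids = sprintf("pair%d", seq_along(pairs))) {
  tf <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  of <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  write_fasta(data.frame(id = ids, desc = "",
                         seq = vapply(pairs, `[[`, character(1), "target")), tf)
  write_fasta(data.frame(id = ids, desc = "",
                         seq = vapply(pairs, `[[`, character(1), "overlapping")), of)
  list(target = tf, overlap = of)
}

test_that("the worked example produces the expected report rows", {
  paths <- write_pair_fastas(list(sample_gene_pair()), ids = "sample")
  report_path <- withr::local_tempfile(fileext = ".tsv")
  fasta_path <- withr::local_tempfile(fileext = ".fasta")
  res <- run_find(run_config(paths$target, paths$overlap,
                             out_report = report_path, out_fasta = fasta_path))
  expect_true(res$ok)
  rep <- read.delim(report_path, colClasses = "character")
  expect_identical(rep$kind, c("start_loss", "premature_stop", "premature_stop"))
  expect_identical(rep$codon_index, c("0", "3", "3"))
  expect_identical(rep$rank, c("1", "2", "3"))
  expect_identical(rep$mutant_codon[1], "ACG")
  expect_setequal(rep$stop_codon[2:3], c("TAA", "TGA"))
  expect_identical(unique(rep$strand), "same")
  expect_identical(unique(rep$frame_shift), "1")
  expect_identical(rep$note[1], "possible alternate start codon")

  fa <- read_fasta(fasta_path)
  expect_identical(fa$id, sprintf("sample|cand%d", 1:3))
  # each mutant differs from the wild type exactly at its reported edits
  for (i in seq_len(nrow(fa))) {
    e <- parse_edits(rep$edits[i])
    diffs <- which(strsplit(sample_gene_pair()$target, "")[[1]] !=
                   strsplit(fa$seq[i], "")[[1]]) - 1L
    expect_identical(sort(diffs), sort(e$pos))
  }
})

test_that("pairs without overlap or candidates yield diagnostic rows", {
  set.seed(127)
  # pair 1: fine; pair 2: unrelated sequences (no overlap)
  good <- sample_gene_pair()
  paths <- write_pair_fastas(
    list(good, list(target = paste0("ATG", random_dna(27)),
                    overlapping = random_dna(40))),
    ids = c("ok", "orphan"))
  report_path <- withr::local_tempfile(fileext = ".tsv")
  res <- run_find(run_config(paths$target, paths$overlap,
                             out_report = report_path))
  expect_false(res$ok)
  rep <- read.delim(report_path, colClasses = "character")
  expect_true(any(rep$pair_id == "orphan" &
                  grepl("no overlap detected", rep$note)))
  expect_true(all(rep$kind[rep$pair_id == "ok"] != "."))
})

test_that("a pair with no admissible knockout reports a diagnostic row", {
  # the target sits in the overlapping gene's own frame and the shared
  # codons are all Met/Trp/stop, which have no synonyms: every
  # stop-creating or start-destroying edit changes the overlapping protein
  ov <- "ATGTGGATGTGGATGTGGATGTGGTAA"
  target <- substr(ov, 7, 27)  # 21 nt, starts ATG
  expect_identical(substr(target, 1, 3), "ATG")
  pair <- gene_pair(target, ov,
                    geometry = overlap_geometry(c(0L, 21L), c(6L, 27L), "same"))
  expect_identical(nrow(find_knockouts(pair)), 0L)

  paths <- write_pair_fastas(list(pair), ids = "locked")
  report_path <- withr::local_tempfile(fileext = ".tsv")
  res <- run_find(run_config(paths$target, paths$overlap, min_overlap = 15,
                             out_report = report_path))
  rep <- read.delim(report_path, colClasses = "character")
  expect_identical(rep$note, "no knockout found")
})

test_that("batch accounting: row count equals the sum over pairs", {
  set.seed(131)
  pairs <- generate_pairs(sim_params(n_pairs = 3, len_codons = c(12, 25),
                                     seed = 131))
  paths <- write_pair_fastas(pairs)
  res <- run_find(run_config(paths$target, paths$overlap))
  per_pair <- vapply(pairs, function(p) nrow(find_knockouts(p)), integer(1))
  expect_identical(nrow(res$report), sum(per_pair))
  expect_identical(nrow(res$fasta), sum(per_pair))
  expect_identical(as.integer(table(res$report$pair_id)[sprintf("pair%d", 1:3)]),
                   per_pair)
})

test_that("pairing by id matches records and flags unmatched ids", {
  pair <- sample_gene_pair()
  tf <- withr::local_tempfile(fileext = ".fasta")
  of <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(data.frame(id = c("a", "b"), desc = "",
                         seq = rep(pair$target, 2)), tf)
  # overlap file in reversed order: by-id must still pair correctly
  write_fasta(data.frame(id = c("b", "a"), desc = "",
                         seq = rep(pair$overlapping, 2)), of)
  res <- run_find(run_config(tf, of, pair_by = "id"))
  expect_true(res$ok)
  expect_identical(sort(unique(res$report$pair_id)), c("a", "b"))

  write_fasta(data.frame(id = c("b", "c"), desc = "",
                         seq = rep(pair$overlapping, 2)), of)
  expect_error(run_find(run_config(tf, of, pair_by = "id")),
               "unmatched identifiers: a, c")
})

test_that("mismatched counts warn under by-order pairing", {
  pair <- sample_gene_pair()
  tf <- withr::local_tempfile(fileext = ".fasta")
  of <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(data.frame(id = c("a", "b"), desc = "",
                         seq = rep(pair$target, 2)), tf)
  write_fasta(data.frame(id = "a", desc = "", seq = pair$overlapping), of)
  expect_warning(run_find(run_config(tf, of)), "different record counts")
})

test_that("repeated runs are byte-identical", {
  set.seed(137)
  pairs <- generate_pairs(sim_params(n_pairs = 3, len_codons = c(12, 25),
                                     seed = 137))
  paths <- write_pair_fastas(pairs)
  out <- replicate(2, {
    report_path <- tempfile(fileext = ".tsv")
    fasta_path <- tempfile(fileext = ".fasta")
    run_find(run_config(paths$target, paths$overlap,
                        params = search_params(site_change_mode = "either"),
                        out_report = report_path, out_fasta = fasta_path))
    c(paste(readLines(report_path), collapse = "\n"),
      paste(readLines(fasta_path), collapse = "\n"))
  })
  expect_identical(out[, 1], out[, 2])
})

test_that("run_scan reports per-record sites in TSV", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(data.frame(id = c("hit", "empty"), desc = "",
                         seq = c("TTGAATTCTT", "TTTTTTTTTT")), tf)
  out <- withr::local_tempfile(fileext = ".tsv")
  res <- run_scan(tf, enzymes = load_enzymes(c("EcoRI GAATTC")), out = out)
  expect_identical(res$record, "hit")
  expect_identical(res$position, 2L)
  tsv <- read.delim(out)
  expect_identical(nrow(tsv), 1L)
  # delegation: agrees with find_sites on every record
  expect_identical(res$position,
                   find_sites("TTGAATTCTT", load_enzymes(c("EcoRI GAATTC")))$position)
})
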