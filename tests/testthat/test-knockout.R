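test_that("stop_substitutions enumerates reachable stops in order", {
  tca <- stop_substitutions("TCA", 1)
  expect_identical(tca$stop_codon, c("TAA", "TGA"))
  expect_identical(tca$edits, c("1:C>A", "1:C>G"))

  expect_identical(nrow(stop_substitutions("GGG", 1)), 0L)

  tgg <- stop_substitutions("TGG", 1)
  expect_identical(tgg$stop_codon, c("TAG", "TGA"))
  expect_identical(tgg$edits, c("1:G>A", "2:G>A"))

  expect_error(stop_substitutions("TAA"), "already a stop")

  # brute-force cross-check over every non-stop codon at max_edits 1 and 2
  all_codons <- names(standard_genetic_code())
  for (codon in setdiff(all_codons, c("TAA", "TAG", "TGA"))) {
    for (me in 1:2) {
      got <- stop_substitutions(codon, me)$stop_codon
      want <- Filter(function(sc) {
        sum(strsplit(sc, "")[[1]] != strsplit(codon, "")[[1]]) <= me
      }, c("TAA", "TAG", "TGA"))
      expect_setequal(got, want)
    }
  }
})

test_that("preservation check follows the worked-example codon pairings", {
  pair <- sample_gene_pair()
  # ATG->ACG: overlapping TAT -> TAC, both tyrosine
  expect_true(preserves_overlap_protein(pair, parse_edits("1:T>C")))
  # TCA->TGA: overlapping CTC -> CTG, both leucine
  expect_true(preserves_overlap_protein(pair, parse_edits("10:C>G")))
  # ATG->TTG would turn overlapping TAT into TTT (Tyr -> Phe)
  expect_false(preserves_overlap_protein(pair, parse_edits("0:A>T")))
})

test_that("preservation agrees with independent full-sequence translation", {
  set.seed(53)
  pairs <- generate_pairs(sim_params(n_pairs = 10, len_codons = c(12, 30),
                                     seed = 53))
  for (pair in pairs) {
    chars <- strsplit(pair$target, "")[[1]]
    positions <- sample(seq_along(chars) - 1L, 12)
    for (p in positions) {
      b <- sample(setdiff(BASES, chars[p + 1]), 1)
      edits <- parse_edits(sprintf("%d:%s>%s", p, chars[p + 1], b))
      spliced <- splice_overlapping(pair, apply_mutation(pair$target, edits))
      expect_identical(
        preserves_overlap_protein(pair, edits),
        bs_translate(spliced) == bs_translate(pair$overlapping)
      )
    }
  }
})

test_that("the worked example yields the expected candidate list", {
  ko <- find_knockouts(sample_gene_pair())
  expect_s3_class(ko, "knockout_candidates")
  start_loss <- ko[ko$kind == "start_loss", ]
  expect_identical(start_loss$new_codon, "ACG")
  expect_identical(start_loss$codon_index, 0L)
  expect_true(start_loss$alt_start)  # ACG is a known alternate start
  stops <- ko[ko$kind == "premature_stop", ]
  expect_identical(stops$codon_index, c(3L, 3L))
  expect_identical(sort(stops$new_codon), c("TAA", "TGA"))
  expect_identical(stops$wt_codon, c("TCA", "TCA"))
  # start-loss candidates listed first
  expect_identical(ko$kind[1], "start_loss")
})

test_that("every emitted candidate verifies against independent translation", {
  set.seed(59)
  pairs <- generate_pairs(sim_params(n_pairs = 8, len_codons = c(12, 30),
                                     seed = 59))
  for (pair in pairs) {
    ko <- find_knockouts(pair)
    for (i in seq_len(nrow(ko))) {
      expect_identical(bs_translate(ko$mutant_overlapping[i]),
                       bs_translate(pair$overlapping))
      if (ko$kind[i] == "premature_stop") {
        prot <- bs_translate(ko$mutant_target[i])
        idx <- ko$stop_codon_index[i]
        expect_identical(substr(prot, idx + 1, idx + 1), "*")
        expect_false(substr(bs_translate(pair$target), idx + 1, idx + 1) == "*")
      } else {
        expect_false(startsWith(ko$mutant_target[i], "ATG"))
      }
      # the mutant differs from the wild type exactly at the edit positions
      e <- parse_edits(ko$edits[i])
      diffs <- which(strsplit(pair$target, "")[[1]] !=
                     strsplit(ko$mutant_target[i], "")[[1]]) - 1L
      expect_identical(sort(diffs), sort(e$pos))
    }
  }
})

test_that("search equals the 9L brute-force oracle on generated pairs", {
  set.seed(61)
  pairs <- generate_pairs(sim_params(n_pairs = 25, len_codons = c(12, 35),
                                     p_opposite = 0.4, seed = 61))
  for (pair in pairs) {
    ko <- find_knockouts(pair)
    expect_identical(candidate_key(ko), oracle_knockouts(pair))
  }
})

test_that("candidate sets grow monotonically with the edit budget", {
  set.seed(67)
  pairs <- generate_pairs(sim_params(n_pairs = 4, len_codons = c(12, 20),
                                     seed = 67))
  for (pair in pairs) {
    keys <- lapply(1:3, function(me) {
      ko <- find_knockouts(pair, search_params(max_edits_per_codon = me))
      paste(ko$kind, ko$codon_index, ko$new_codon)
    })
    expect_true(all(keys[[1]] %in% keys[[2]]))
    expect_true(all(keys[[2]] %in% keys[[3]]))
  }
})

test_that("codon window and start-loss switches bound the search", {
  pair <- sample_gene_pair()
  ko <- find_knockouts(pair, search_params(codon_window = 3,
                                           allow_start_loss = FALSE))
  expect_identical(nrow(ko), 0L)  # first stop is at codon 3, excluded
  ko2 <- find_knockouts(pair, search_params(codon_window = 4,
                                            allow_start_loss = FALSE))
  expect_identical(unique(ko2$codon_index), 3L)
  expect_error(find_knockouts(
    gene_pair("CTGGGGGGCTCAAAACCCGAGCACAACTAA",
              paste0("T", "CTGGGGGGCTCAAAACCCGAGCACAACTAA", "CC")),
    search_params()), "does not begin with ATG")
})

test_that("deterministic output and edits outside the span are unconstrained", {
  pair <- sample_gene_pair()
  expect_identical(find_knockouts(pair), find_knockouts(pair))
  # target codon 1 is TCA and lies wholly outside the shared span
  target <- "ATGTCAGGGTAA"
  ov <- paste0("G", substr(target, 7, 12), "ACCTT")
  pair2 <- gene_pair(target, ov,
                     geometry = overlap_geometry(c(6L, 12L), c(1L, 7L), "same"))
  ko <- find_knockouts(pair2)
  expect_true(any(ko$kind == "premature_stop" & ko$codon_index == 1L))
})

test_that("first_knockout_codon matches the candidate-list minimum", {
  expect_identical(first_knockout_codon(sample_gene_pair()), 3L)
  set.seed(71)
  pairs <- generate_pairs(sim_params(n_pairs = 20, len_codons = c(12, 40),
                                     seed = 71))
  for (pair in pairs) {
    ko <- find_knockouts(pair)
    idx <- ko$stop_codon_index[ko$kind == "premature_stop"]
    want <- if (length(idx)) min(idx) else NA_integer_
    expect_identical(first_knockout_codon(pair), want)
    oracle_idx <- with(oracle_knockouts(pair), codon_index[kind == "premature_stop"])
    expect_identical(first_knockout_codon(pair),
                     if (length(oracle_idx)) min(oracle_idx) else NA_integer_)
  }
})

test_that("neutral-mutation enumeration equals brute force over the span", {
  pair <- sample_gene_pair()
  neutral <- enumerate_neutral_mutations(pair)
  key <- sprintf("%d:%s>%s", neutral$pos, neutral$wt, neutral$mut)
  # worked example: all three CTC-preserving edits at target position 10
  expect_true(all(c("10:C>A", "10:C>G", "10:C>T") %in% key))
  set.seed(73)
  pairs <- generate_pairs(sim_params(n_pairs = 6, len_codons = c(12, 25),
                                     p_opposite = 0.5, seed = 73))
  for (pair in pairs) {
    neutral <- enumerate_neutral_mutations(pair)
    g <- pair$geometry
    chars <- strsplit(pair$target, "")[[1]]
    want <- list()
    for (p in seq.int(g$target_span[1], g$target_span[2] - 1L)) {
      for (b in setdiff(BASES, chars[p + 1])) {
        spliced <- splice_overlapping(
          pair, apply_mutation(pair$target,
                               parse_edits(sprintf("%d:%s>%s", p, chars[p + 1], b))))
        if (bs_translate(spliced) == bs_translate(pair$overlapping)) {
          want[[length(want) + 1L]] <- sprintf("%d:%s>%s", p, chars[p + 1], b)
        }
      }
    }
    expect_setequal(sprintf("%d:%s>%s", neutral$pos, neutral$wt, neutral$mut),
                    unlist(want))
  }
})

test_that("a span of single-codon amino acids admits no neutral mutation", {
  # overlapping frame reads ATG/TGG codons (Met/Trp): no synonyms exist
  ov <- "ATGTGGATGTGGATGTGGTAA"
  target <- substr(ov, 2, 19)  # phase-1 window, 18 nt
  pair <- gene_pair(target, ov,
                    geometry = overlap_geometry(c(0L, 18L), c(1L, 19L), "same"))
  expect_identical(nrow(enumerate_neutral_mutations(pair)), 0L)
})

test_that("constrained mutagenesis specialises to the stop search", {
  pair <- sample_gene_pair()
  res <- constrained_codon_mutagenesis(pair, is_residue("S"), is_stop_residue())
  ko <- find_knockouts(pair, search_params(allow_start_loss = FALSE))
  ser_stops <- ko[ko$wt_codon %in% names(which(standard_genetic_code() == "S")), ]
  expect_identical(res$edits, ser_stops$edits)
  expect_identical(res$new_codon, ser_stops$new_codon)

  # hydrophobic -> non-hydrophobic reports only residue-class moves that
  # keep the overlapping protein, cross-checked by brute force
  set.seed(79)
  pairs <- generate_pairs(sim_params(n_pairs = 4, len_codons = c(12, 20),
                                     seed = 79))
  gc <- standard_genetic_code()
  for (pair in pairs) {
    res <- constrained_codon_mutagenesis(
      pair, is_hydrophobic, function(aa) !is_hydrophobic(aa) & aa != "*")
    for (i in seq_len(nrow(res))) {
      expect_true(is_hydrophobic(unname(gc[res$wt_codon[i]])))
      expect_false(is_hydrophobic(unname(gc[res$new_codon[i]])))
      spliced <- splice_overlapping(pair, res$mutant_target[i])
      expect_identical(bs_translate(spliced), bs_translate(pair$overlapping))
    }
  }
})

test_that("internal wild-type stops warn but do not abort the search", {
  target <- "ATGTAAGGGTCATAA"   # internal TAA at codon 1
  ov <- paste0("G", target, "CC")
  pair <- gene_pair(target, ov,
                    geometry = overlap_geometry(c(0L, 15L), c(1L, 16L), "same"))
  expect_warning(find_knockouts(pair), "internal stop")
})
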