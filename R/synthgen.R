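# Seeded generator of synthetic overlapping gene pairs with planted
# geometry, and a desk-scale survey of where the first reachable premature
# stop codon falls along the gene. The generator emulates the *structure*
# of real overprinted loci (two valid ORFs sharing a contiguous region in
# shifted frames or on opposite strands); it makes no attempt to reproduce
# the codon usage or composition of harvested viral genomes.

#' Simulation parameters for synthetic gene pairs
#'
#' @param n_pairs Number of pairs to generate.
#' @param len_codons Length-2 range for the target gene length in codons,
#'   including the final stop codon. Defaults to 30-150, typical of small
#'   viral accessory / overprinted genes.
#' @param overlap_frac Length-2 range for the fraction of the target
#'   covered by the shared region, in (0, 1].
#' @param p_opposite Probability that the overlapping gene lies on the
#'   opposite strand.
#' @param frame_shift_probs Probabilities of same-strand frame shifts 1 and
#'   2 (shift 0 would put both genes in the same frame, which is not
#'   overprinting).
#' @param base_probs Sampling probabilities for A, C, G, T (uniform by
#'   default).
#' @param seed Integer seed; generation is reproducible from it.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_pairs = 100L,
                       len_codons = c(30L, 150L),
                       overlap_frac = c(0.4, 1),
                       p_opposite = 0.25,
                       frame_shift_probs = c(0.5, 0.5),
                       base_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       seed = 1L) {
  stopifnot(
    n_pairs >= 0L,
    length(len_codons) == 2L, len_codons[1L] >= 10L,
    len_codons[1L] <= len_codons[2L],
    length(overlap_frac) == 2L, overlap_frac[1L] > 0,
    overlap_frac[2L] <= 1, overlap_frac[1L] <= overlap_frac[2L],
    p_opposite >= 0, p_opposite <= 1,
    length(frame_shift_probs) == 2L, all(frame_shift_probs >= 0),
    length(base_probs) == 4L, all(base_probs > 0)
  )
  if (abs(sum(base_probs) - 1) > 1e-8) {
    stop("base_probs must sum to 1", call. = FALSE)
  }
  structure(
    list(
      n_pairs = as.integer(n_pairs),
      len_codons = as.integer(len_codons),
      overlap_frac = as.numeric(overlap_frac),
      p_opposite = as.numeric(p_opposite),
      frame_shift_probs = frame_shift_probs / sum(frame_shift_probs),
      base_probs = stats::setNames(as.numeric(base_probs), c("A", "C", "G", "T")),
      seed = as.integer(seed)
    ),
    class = "sim_params"
  )
}

# sample() treats a length-1 numeric first argument as 1:n; this draws
# uniformly from the given vector regardless of its length.
.resample <- function(x) x[sample.int(length(x), 1L)]

.sample_bases <- function(n, probs) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs)
}

# A random non-stop codon under the base composition.
.sample_codon <- function(probs) {
  repeat {
    codon <- paste(.sample_bases(3L, probs), collapse = "")
    if (!(codon %in% STOP_CODONS)) return(codon)
  }
}

# Random ORF of `n_codons` codons: starts ATG, ends with one stop, no
# internal stop. Returned as a character vector of codons.
.sample_orf_codons <- function(n_codons, probs) {
  c("ATG",
    vapply(seq_len(n_codons - 2L), function(i) .sample_codon(probs),
           character(1L)),
    sample(STOP_CODONS, 1L, prob = c(1, 1, 1) / 3))
}

#' Generate one synthetic overlapping gene pair
#'
#' Plants a contiguous shared region between a freshly sampled target ORF
#' and an overlapping ORF built around it. Both genes are valid ORFs (start
#' ATG, exactly one stop at the end, no internal stop in their own frames);
#' the overlapping gene reads the shared region in a shifted frame (same
#' strand) or reverse-complemented (opposite strand). Construction uses
#' repair sampling: codons whose projection into the other frame creates a
#' stop are resampled until both frames are clean, which preserves the
#' planted geometry exactly.
#'
#' Uses the current RNG state; seed externally (or via [generate_pairs()])
#' for reproducibility.
#'
#' @param params A [sim_params()].
#' @return A [gene_pair()] whose `geometry` records the planted overlap.
#' @export
generate_pair <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  probs <- params$base_probs
  for (attempt in seq_len(50L)) {
    L <- .resample(params$len_codons[1L]:params$len_codons[2L])
    f <- stats::runif(1L, params$overlap_frac[1L], params$overlap_frac[2L])
    k <- max(2L, min(L, as.integer(round(f * L))))  # span length in codons
    c0 <- .resample(0L:(L - k))                     # span start codon
    opposite <- stats::runif(1L) < params$p_opposite
    shift <- if (opposite) sample(0L:2L, 1L) else
      sample(1L:2L, 1L, prob = params$frame_shift_probs)

    target_codons <- .sample_orf_codons(L, probs)

    # Overlapping gene: left flank (length == shift mod 3, >= 3 so the ATG
    # fits), the embedded span, right flank (total a codon multiple, >= 3
    # so the final stop fits).
    span_nt <- 3L * k
    ell <- shift + 3L * (1L + sample(0L:3L, 1L))
    r <- ((3L - shift) %% 3L) + 3L * (1L + sample(0L:3L, 1L))
    M_nt <- ell + span_nt + r

    ov <- character(M_nt)
    ov[seq_len(ell)] <- .sample_bases(ell, probs)
    ov[(ell + span_nt + 1L):M_nt] <- .sample_bases(r, probs)

    .place_span <- function(ov, target_codons) {
      span_seq <- paste(target_codons[(c0 + 1L):(c0 + k)], collapse = "")
      if (opposite) span_seq <- reverse_complement(span_seq)
      ov[(ell + 1L):(ell + span_nt)] <- .seq_chars(span_seq)
      ov
    }
    ov <- .place_span(ov, target_codons)
    ov[1L:3L] <- c("A", "T", "G")
    ov[(M_nt - 2L):M_nt] <- .seq_chars(.resample(STOP_CODONS))

    # The planted span must be exactly recoverable as the longest common
    # substring, so the flank bases immediately adjacent to it must not
    # extend the match by chance. 1-based overlap position -> banned base.
    .boundary_bans <- function(target_codons) {
      tchars <- .seq_chars(paste(target_codons, collapse = ""))
      bans <- list()
      if (c0 > 0L) {            # target has a base before the span
        tb <- tchars[3L * c0]   # 1-based position 3*c0
        if (opposite) bans[[length(bans) + 1L]] <-
            c(pos = ell + span_nt + 1L, ban = .complement_base(tb))
        else bans[[length(bans) + 1L]] <- c(pos = ell, ban = tb)
      }
      if (c0 + k < L) {         # target has a base after the span
        tb <- tchars[3L * (c0 + k) + 1L]
        if (opposite) bans[[length(bans) + 1L]] <-
            c(pos = ell, ban = .complement_base(tb))
        else bans[[length(bans) + 1L]] <- c(pos = ell + span_nt + 1L, ban = tb)
      }
      bans
    }

    ok <- FALSE
    for (iter in seq_len(200L)) {
      n_ov_codons <- M_nt %/% 3L
      starts <- 3L * (seq_len(n_ov_codons) - 1L) + 1L
      codons <- vapply(starts, function(s)
        paste(ov[s:(s + 2L)], collapse = ""), character(1L))
      bad <- which(codons %in% STOP_CODONS)
      bad <- bad[bad != n_ov_codons]  # final stop is wanted
      if (length(bad) == 0L) {
        # No internal stop: now enforce the boundary mismatches.
        bans <- .boundary_bans(target_codons)
        violated <- Filter(function(b)
          ov[as.integer(b["pos"])] == b["ban"], bans)
        if (length(violated) == 0L) { ok <- TRUE; break }
        vb <- violated[[1L]]
        p <- as.integer(vb["pos"])
        if (p <= 3L || p > M_nt - 3L) break  # inside the ATG/stop: restart
        ov[p] <- .resample(setdiff(c("A", "C", "G", "T"), vb["ban"]))
        next  # re-check stops: the new base may have created one
      }

      b <- bad[1L]
      nt <- (starts[b]):(starts[b] + 2L)           # 1-based overlap nt
      in_span <- nt > ell & nt <= ell + span_nt
      if (any(!in_span)) {
        # At least one base is flank: resample the flank bases. The
        # overlapping gene's own ATG and final stop codons can never be the
        # offending codon, so they are never touched here.
        ov[nt[!in_span]] <- .sample_bases(sum(!in_span), probs)
      } else {
        # Codon fully inside the span: resample the target codons that
        # project onto it (never the target's ATG or final stop).
        sp <- nt - ell                              # 1-based span positions
        tpos <- if (opposite) span_nt - sp + 1L else sp
        tcod <- unique((3L * c0 + tpos - 1L) %/% 3L)  # 0-based target codons
        tcod <- tcod[tcod != 0L & tcod != L - 1L]
        if (length(tcod) == 0L) break  # unrepairable layout; restart pair
        for (tc in tcod) target_codons[tc + 1L] <- .sample_codon(probs)
        ov <- .place_span(ov, target_codons)
      }
    }
    if (!ok) next

    target <- paste(target_codons, collapse = "")
    # Repair can only touch non-terminal codons with non-stop resamples,
    # but assert target validity anyway.
    prot <- translate(target)
    if (substr(prot, nchar(prot), nchar(prot)) != "*" ||
        grepl("*", substr(prot, 1L, nchar(prot) - 1L), fixed = TRUE)) next

    geom <- overlap_geometry(
      target_span = c(3L * c0, 3L * c0 + span_nt),
      overlap_span = c(ell, ell + span_nt),
      strand = if (opposite) "opposite" else "same"
    )
    return(gene_pair(target, paste(ov, collapse = ""), geometry = geom))
  }
  stop("failed to generate a valid pair; parameters may be unsatisfiable",
       call. = FALSE)
}

#' Generate a reproducible set of synthetic pairs
#'
#' Seeds the RNG from `params$seed` and draws `params$n_pairs` pairs.
#'
#' @param params A [sim_params()].
#' @return List of [gene_pair()] objects.
#' @export
generate_pairs <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(params$seed)
  lapply(seq_len(params$n_pairs), function(i) generate_pair(params))
}

#' Survey first-knockout positions over synthetic pairs
#'
#' Generates pairs, runs [first_knockout_codon()] on each with and without
#' a restriction-site-change requirement, and aggregates: the fraction of
#' pairs with any reachable premature stop, the fraction knockable within
#' the first 20 codons, and histograms of the first-stop codon index and of
#' its position as a fraction of gene length (unit-length ratio). Adding
#' the site-change requirement can only shrink the candidate set, so every
#' "with sites" fraction is at most its unconstrained counterpart.
#'
#' @param params A [sim_params()].
#' @param search A [search_params()] applied to every pair
#'   (`site_change_mode` is ignored; both variants are always computed).
#' @param enzymes Enzyme table for the site-change variant.
#' @param out_hist Optional path: writes the two histograms as TSV
#'   (columns: statistic, bin, count).
#' @param out_summary Optional path: writes the scalar summary as TSV.
#' @return List of class `survey_summary`: `n_pairs`, per-variant
#'   (`no_sites`, `with_sites`) lists holding `frac_any`, `frac_lt20`,
#'   `first_codon` (integer vector, `NA` = not knockable), `gene_len`
#'   (codons), plus `hist_index` and `hist_ratio` tables.
#' @export
run_survey <- function(params = sim_params(),
                       search = search_params(),
                       enzymes = "builtin",
                       out_hist = NULL, out_summary = NULL) {
  stopifnot(inherits(params, "sim_params"), inherits(search, "search_params"))
  pairs <- generate_pairs(params)
  n <- length(pairs)
  enz <- if (n > 0L) .resolve_enzymes(enzymes) else NULL

  p_none <- search; p_none$site_change_mode <- "none"
  p_site <- search; p_site$site_change_mode <- "either"

  gene_len <- vapply(pairs, function(p) nchar(p$target) %/% 3L, integer(1L))
  fk <- vapply(pairs, function(p) first_knockout_codon(p, p_none), integer(1L))
  fk_site <- vapply(pairs, function(p)
    first_knockout_codon(p, p_site, enzymes = enz), integer(1L))

  variant <- function(first_codon) {
    known <- !is.na(first_codon)
    list(
      frac_any = if (n) mean(known) else NA_real_,
      frac_lt20 = if (n) mean(known & first_codon < 20L) else NA_real_,
      first_codon = first_codon,
      hist_index = if (any(known)) as.data.frame(table(
        index = first_codon[known]), stringsAsFactors = FALSE) else
        data.frame(index = character(0L), Freq = integer(0L)),
      hist_ratio = if (any(known)) as.data.frame(table(
        ratio = sprintf("%.2f", first_codon[known] / gene_len[known])),
        stringsAsFactors = FALSE) else
        data.frame(ratio = character(0L), Freq = integer(0L))
    )
  }

  out <- structure(
    list(
      n_pairs = n,
      gene_len = gene_len,
      no_sites = variant(fk),
      with_sites = variant(fk_site)
    ),
    class = "survey_summary"
  )

  if (!is.null(out_hist)) {
    h <- rbind(
      data.frame(statistic = "first_stop_index", constraint = "none",
                 bin = out$no_sites$hist_index$index,
                 count = out$no_sites$hist_index$Freq),
      data.frame(statistic = "first_stop_index", constraint = "site_change",
                 bin = out$with_sites$hist_index$index,
                 count = out$with_sites$hist_index$Freq),
      data.frame(statistic = "first_stop_ratio", constraint = "none",
                 bin = out$no_sites$hist_ratio$ratio,
                 count = out$no_sites$hist_ratio$Freq),
      data.frame(statistic = "first_stop_ratio", constraint = "site_change",
                 bin = out$with_sites$hist_ratio$ratio,
                 count = out$with_sites$hist_ratio$Freq)
    )
    utils::write.table(h, out_hist, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(out_summary)) {
    s <- data.frame(
      n_pairs = n,
      frac_any = out$no_sites$frac_any,
      frac_lt20 = out$no_sites$frac_lt20,
      frac_any_site_change = out$with_sites$frac_any,
      frac_lt20_site_change = out$with_sites$frac_lt20
    )
    utils::write.table(s, out_summary, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}

#' @export
print.survey_summary <- function(x, ...) {
  cat("survey of ", x$n_pairs, " synthetic pairs\n", sep = "")
  if (x$n_pairs == 0L) return(invisible(x))
  cat(sprintf("  knockable at all:        %.1f%% (with site change: %.1f%%)\n",
              100 * x$no_sites$frac_any, 100 * x$with_sites$frac_any))
  cat(sprintf("  first stop < 20 codons:  %.1f%% (with site change: %.1f%%)\n",
              100 * x$no_sites$frac_lt20, 100 * x$with_sites$frac_lt20))
  invisible(x)
}
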