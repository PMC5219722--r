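# Bundled worked example: a small target / overlapping gene pair with the
# classic textbook structure of an overprinted locus.

#' Sample overlapping gene pair
#'
#' A synthetic 10-codon target gene overprinted (same strand, frame shift 1)
#' on an 11-codon overlapping gene, constructed so that the two standard
#' knockout routes are both available and easy to inspect:
#'
#' * mutating the initiation codon (index 0) ATG to ACG changes the
#'   overlapping codon TAT to TAC -- both code for tyrosine, so the
#'   overlapping protein is unchanged;
#' * the TCA (serine) codon at index 3 of the target can be mutated to a
#'   stop codon (TGA or TAA) while the affected overlapping codon CTC
#'   becomes CTG or CTA -- CTC, CTA and CTG all encode leucine.
#'
#' Codons 1 and 2 (GGG, GGC) are not within one substitution of any stop
#' codon, so index 3 is the earliest premature stop reachable by a point
#' mutation.
#'
#' @return A [gene_pair()] with the geometry detected by [find_overlap()].
#' @examples
#' pair <- sample_gene_pair()
#' find_knockouts(pair)
#' @export
sample_gene_pair <- function() {
  target <- "ATGGGGGGCTCAAAACCCGAGCACAACTAA"
  overlapping <- paste0("T", target, "CC")
  gene_pair(target, overlapping)
}
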