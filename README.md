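# overko

Design gene knockouts in sequences with overlapping (overprinted) reading
frames.

Viral genomes are dense: a single stretch of nucleotides frequently codes
for two proteins at once, read in different frames or on opposite strands.
That rules out excising a gene to study its function — the cut would
destroy its partner too. The practical alternative is a minimal set of
nucleotide substitutions that knocks out the *target* gene while leaving
the *overlapping* gene's protein exactly intact, exploiting the degeneracy
of the genetic code.

`overko` automates that design. Given a target coding sequence and the
gene overlapping it, it:

* detects the shared region, strand and codon phase between the two genes;
* enumerates every mutation, confined to a single target codon and at most
  three substitutions (default one: a point mutation), that either inserts
  a **premature stop codon** (TAA/TAG/TGA) at codon index ≥ 1 or destroys
  the **start codon**, such that the overlapping gene's translated protein
  is unchanged;
* annotates each candidate with the restriction-enzyme recognition sites
  it adds or removes on the full mutant gene — usable as cloning tracers,
  so clones can be screened by digest instead of sequencing;
* scales to batch FASTA input with a TSV report, and ships a seeded
  generator of synthetic overlapping gene pairs for simulation studies.

Formally: let the target be codons $c_0 c_1 \dots c_{n-1}$ with $c_0 =$
ATG, and let $\phi$ map each target nucleotide position in the shared
region to a (codon, offset) of the overlapping gene (complemented on the
opposite strand). A candidate is a set of ≤ `max_edits_per_codon`
substitutions inside one codon $c_i$ such that either $c_i$ becomes a stop
($i \ge 1$) or $c_0 \ne$ ATG, subject to $\mathrm{aa}(x') = \mathrm{aa}(x)$
for every overlapping-gene codon $x$ touched through $\phi$. Candidates
are reported in deterministic order (codon index, edit count, mutant
codon). All coordinates are 0-based; the initiation codon is index 0.

## Worked example

The bundled sample pair is a 10-codon target overprinted on an 11-codon
gene in frame shift 1:

```r
library(overko)
pair <- sample_gene_pair()
pair
#> gene pair: target 30 nt, overlapping 33 nt
#> overlap geometry: target [0, 30) <-> overlapping [1, 31), strand same, frame shift 1

find_knockouts(pair)
#> knockout candidates: 3 (1 start-loss, 2 premature-stop)
#>            kind codon_index wt_codon new_codon  edits n_edits alt_start
#>      start_loss           0      ATG       ACG  1:T>C       1      TRUE
#>  premature_stop           3      TCA       TAA 10:C>A       1        NA
#>  premature_stop           3      TCA       TGA 10:C>G       1        NA

first_knockout_codon(pair)
#> [1] 3
```

Reading the table: mutating the initiation codon (index 0) to ACG knocks
out the target while the overlapping gene's affected codon changes
TAT→TAC — both tyrosine, so its protein is untouched (`alt_start = TRUE`
flags that ACG is a known alternate start codon in some viruses, so this
knockout deserves biological validation). Alternatively the serine codon
TCA at index 3 can become a stop (TAA or TGA) while the overlapping codon
CTC becomes CTA or CTG — all leucine. The earliest premature stop is at
codon 3, truncating the protein after three residues.

Restriction-site tracers work on any pair of equal-length sequences:

```r
site_changes("TTGAATTCTT", "TTGACTTCTT")   # A>C destroys the EcoRI site
#> site changes: 0 added, 1 removed
#> removed:
#>  enzyme position strand
#>   EcoRI        2 forward
```

The enzyme table format is one `Name Recognition` pair per line
(whitespace-separated, IUPAC codes allowed, 4–8 nt, `#` comments); the
builtin table of 80 common commercial enzymes is at
`system.file("extdata", "enzymes_builtin.txt", package = "overko")`.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("exec", "overko.R", package = "overko"))')
Rscript $CLI find --target targets.fasta --overlap overlaps.fasta \
    --site-change either --out-report report.tsv --out-fasta mutants.fasta
Rscript $CLI scan --in plasmid.fasta
Rscript $CLI simulate --n 1000 --seed 1 --out-summary survey.tsv
```

`find` writes one TSV row per candidate (rank, kind, codon index, edits as
`pos:WT>MUT`, sites added/removed as `Enzyme@pos`) and each mutant target
as `<pairid>|cand<rank>`. Pairs with no detectable overlap or no
admissible knockout produce a diagnostic row, not a crash.

## Simulation

`generate_pairs(sim_params(...))` builds valid ORF pairs with a planted,
exactly recoverable overlap geometry on either strand; `run_survey()`
reports where along the gene the first reachable premature stop falls,
with and without requiring a restriction-site change. See the methods
vignette (`vignettes/knockout-design.Rmd`) for the model, parameter
defaults, and what the synthetic pairs do and do not emulate.

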