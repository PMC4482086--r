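---
title: "Methods: discovering dusA-associated genomic islands and reconstructing their excision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering dusA-associated genomic islands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dusaGEI)
```

## The biological model

A family of tyrosine-recombinase integrases targets the 5' end of the
tRNA-dihydrouridine synthase gene *dusA* (and occasionally its *dusB* /
*dusC* paralogues). Integration does not simply disrupt the gene: the
incoming island provides a replacement 5' coding segment, so the
integrated locus still encodes a functional chimeric DusA, while the
original 5' fragment is left stranded at the island's far boundary.
Recombination between a ~21 bp chromosomal attachment site (attB, inside
the *dusA* 5' region) and the island attachment site (attP, on the
circular island form) leaves the integrated island flanked by a pair of
imperfect direct repeats, attL and attR. The integrase gene itself lies
immediately adjacent to the chimeric gene's new 5' end, divergently
oriented, with a catalytic R-H-R-H tetrad plus nucleophilic tyrosine.

Excision reverses the reaction: recombination across the attL/attR cores
releases a covalently closed circular island (carrying one hybrid core,
attP) and reforms the wild-type chromosome (carrying attB), reuniting the
original 5' fragment with the gene body. Junction PCR detects both
products: one primer pair amplifies only across the circle junction, the
other only across the restored chromosomal junction.

`dusaGEI` implements this discovery procedure end to end: target and
integrase association, direct-repeat boundary calling, excision-product
reconstruction with restored-gene validation, in silico junction PCR,
composition descriptors, and the comparative layer used to characterise
island families (identity matrices, neighbour-joining trees with
bootstrap, attachment-site logos, reciprocal-best-hit orthology).

## The association criterion

`find_target_genes()` matches gene names (`dusA`, `dusB`, `dusC`,
case-insensitive) or the full product phrase "tRNA-dihydrouridine
synthase" as an exact substring; a bare fragment such as "dihydrouridine"
does not qualify. `find_adjacent_integrase()` operationalises "the 5' end
of the integrase gene adjoins the 5' end of the target gene" as:
opposite strands, start-codon-proximal boundaries facing each other
across a gap of at most `max_gap` (default 1000 bp — deliberately
generous, since real intergenic spacers at these loci are a few hundred
bp; configurable, and a permissive any-orientation mode exists for
surveys). Ties between equally near candidates are an explicit error
rather than an arbitrary choice. `motif_check()` is a cheap character
screen for the ordered R...H...R...H...Y pentad in the C-terminal 60% of
the protein; it filters obvious non-recombinases but is not proof of
family membership, so candidates failing it are flagged, not dropped.
`homology_screen()` replaces a database search (which is not reproducible
across database versions) with a local-alignment score-ratio screen
against a user-supplied reference panel: BLOSUM62, affine gaps open
11 / extend 1, pass when best score >= 0.3 of the reference self-score.
The threshold was calibrated so that composition-matched shuffled
proteins essentially never pass (the test suite checks >= 99/100 seeded
shuffles fail).

## Boundary calling

`find_direct_repeats()` is a seed-and-extend search: exact `seed_len`-mer
matches (default 12 bp) between an anchor window centred on the target
gene's 5' end (default +/- 2 kb) and a flanking search window (default
200 kb) are extended to `core_len` (default 21 bp, the canonical att core
length; the 26-28 bp extended sites seen in some strains are available
via `extend_bp`) at the mismatch-minimising offset, keeping pairs within
`max_mismatches` (default 3). Only same-strand (direct) repeats are
considered. Windows containing N are excluded outright — a conservative
choice that avoids spurious matches through ambiguity codes.

Ranking is (1) fewest mismatches, (2) implied island size inside the
30-60 kb prior band (the typical size range for these islands) before
out-of-band pairs, longer first within the band, (3) ascending
coordinate. The prior band only orders candidates; it never excludes a
pair, so unusually small or large islands remain callable.

`call_island()` then applies the mechanistic constraints: the winning
pair must enclose the integrase CDS, and exactly one core copy must
touch the target gene's annotated extent (the attR copy inside the
chimeric gene; attL sits at the far boundary). Everything failing these
rules is returned in a no-call diagnostic table with the reason per
pair. The island interval is `[attL first base, attR last base]`, the
convention under which published termini satisfy
size = end - start + 1 (e.g. `span_size(595655, 642997)` = 47343).

The seed length 12 / 3-mismatch combination is coherent with the
biology: strand exchange duplicates the crossover overlap exactly, so
attL/attR differences concentrate in the arm positions and a clean
central seed exists in practice. A planted pair whose divergence is
confined to the arms is therefore always seedable.

## Excision reconstruction and its two bookkeeping conventions

`reconstruct_excision()` keeps the downstream (attR) copy on the
chromosome: `circle_seq` is `[attL_start, attR_start - 1]` circularised
— a true circular molecule carrying exactly one core copy (attP) — and
`restored_seq` is the replicon with that interval deleted, which
reunites the original 5' fragment with the gene body. Keeping attR is
what reforms the wild-type gene; the mirrored convention would instead
leave the island-derived core on the chromosome.

Two length conventions coexist in the literature and both are exposed:
the circular molecule satisfies |circle| + |restored| = |replicon|,
while the linearised island span `island_span_seq` (core written at both
termini, as excised islands are usually drawn) satisfies
|island span| + |restored| - core_len = |replicon|. The package reports
both strings; sizes in tables always refer to the island span.

The restored gene is re-extracted by locating the maximal open reading
frame (bacterial code table 11; starts ATG/GTG/TTG) spanning the
retained core, and validated for start codon, internal stops, length,
and — when the wild-type CDS is available — global-alignment identity.

`in_silico_pcr()` models the excision assay: forward-primer sites on the
plus strand, reverse-primer sites on the minus strand, at most
`max_mismatches` each but with the 3 bases at each primer's 3' terminus
required exact (modelling polymerase extension specificity; the width of
3 bases is our default), convergent pairings up to 10 kb, origin-spanning
products on circular templates. `design_junction_primers()` builds the
two diagnostic pairs from reconstructed products; by construction each
amplifies only the template carrying its junction.

## Composition descriptors

`gc_percent()` excludes N from numerator and denominator and reports one
decimal, the precision used in island tables. Trinucleotide atypicality
is deliberately simple and distribution-free, since no specific statistic
is canonical: the region's 64 overlapping-3-mer frequencies are
standardised against the empirical mean and SD of `n_null` (default
1000) equally long windows drawn uniformly from the host replicon under
a fixed seed, and the score is the mean absolute z over the 64
components (SD floored at 1e-6). Only the given strand is counted — the
profile is not strand-symmetrised — and no significance threshold is
asserted; the score ranks candidate regions, nothing more.

## Comparative layer

Pairwise protein identity/similarity uses global affine-gap alignment
(BLOSUM62, open 11 / extend 1); identity is matches over alignment
columns with terminal-gap columns excluded from the denominator (one of
several matrix-program conventions; configurable), and similarity
additionally counts positive-scoring substitutions. Distances for
neighbour joining are 1 - identity/100 from these pairwise alignments
rather than from a progressive multiple alignment — a deliberate
divergence from MSA-based toolchains, chosen because pairwise distances
are deterministic and oracle-testable; no numeric reproduction of any
published tree is claimed. Labels are sorted before agglomeration so
tied joins resolve deterministically, and negative NJ branch estimates
are clamped to zero and flagged. Bootstrap support resamples alignment
columns with replacement, rebuilds p-distance NJ trees, and reports
per-bipartition replicate fractions (default 1000 replicates), exactly
reproducible under a seed.

Attachment-site logos use the standard information-content formula
IC = 2 - H - 3/(2 ln2 n) bits with the small-sample correction, clamped
at zero, gaps excluded per column.

Reciprocal-best-hit orthology replaces an e-value cutoff (which depends
on database composition) with a score surrogate: an edge requires
mutual best hits, raw local-alignment score >= 50 and score >= 0.2 of
the larger self-score. Clusters are connected components of the edge
graph — the granularity a many-way uniqueness statistic needs, not
strict triangle-complete orthogroups. Uniqueness is counted per gene
(a gene is unique when its cluster touches exactly one island); core
clusters touch every island.

## The synthetic-data generator

`make_wildtype()` emits a 200 kb linear replicon at 40% GC with a valid
1035 bp *dusA*-like ORF (plus-strand, away from the origin) and a
same-strand neighbour CDS upstream. `implant_island()` draws an island
size uniformly from 30-60 kb and implants, at a core 102 bp into the
target CDS (the offset is a parameter, since the real in-gene offset is
not derivable from published text), an island with the full
architecture: displaced copy of the original 5' fragment at the far
boundary, GC-shifted cargo (+10 points), a divergent integrase CDS
(1200 bp, catalytic pentad planted in its C-terminal region) 150 bp
from the new gene start, and a synonymously recoded replacement 5'
segment ending in frame at attR. Synonymous recoding preserves the
protein exactly while diverging at the nucleotide level, emulating "the
island provides a suitable replacement" without modelling structure.
Two decoy repeat pairs are planted inside the cargo. Expected excision
products are assembled from the construction records — string
concatenation of the construction pieces, never a call into the
boundary-calling code — so round-trip tests compare two independent
routes.

Three generator choices make the planted truth well-defined rather than
probabilistically ambiguous, and deserve explanation:

* attL/attR divergence is confined to core arm positions 2-4, keeping
  the crossover overlap exact (as recombination itself would); attR
  retains the wild-type core, so the attR copy is attB and excision
  restores the wild type exactly at any configured divergence (the
  round-trip contract only requires this at divergence 0; the generator
  is stricter).
* the single bases flanking attL and attR are forced to disagree (a
  synonymous third-base swap on the replacement's last codon on the
  left; a 3 bp tag at the interior start on the right). At a real locus
  these flanks are unrelated island-vs-chromosome sequence and agree
  only by chance; without the constraint a shifted 21 bp window can tie
  the planted one and the "true" boundary is genuinely ill-defined.
* an in-frame stop codon is planted immediately upstream of each
  implanted gene start, so the maximal ORF recovered across the core is
  exactly the annotated gene rather than an accidental upstream
  extension.

What the generator does not emulate: real genomes have gene-dense
backgrounds, repeat families, skewed oligonucleotide composition and
mobile elements, all of which can offer more tempting decoy repeats than
uniform random sequence does; cargo is plain GC-shifted sequence rather
than annotated genes; islands are implanted singly (no tandem or nested
elements); and protein families for the orthology test bed evolve by
i.i.d. substitution, not along a phylogeny. Passing the synthetic suite
therefore demonstrates correctness of the machinery under the stated
conditions, not survey-scale performance on real chromosomes.

## Problem sizes and numerical choices in the test suite

The suite exercises the study conditions at sizes chosen to keep a
single-CPU run comfortable: 100 seeded genomes (200 kb each) for the
zero-divergence restoration contract, 100 more at divergence 0-2 with
two decoys for exact coordinate recovery (contract: >= 95/100), 20
fixtures for junction-PCR exclusivity, 50 random sequences (<= 5 kb)
against the exhaustive all-pairs Hamming oracle, 50 random additive
trees (n <= 8) for NJ topology recovery against the generating tree and
a least-squares quartet oracle, and brute-force orthology on inputs of
at most 4 islands x 6 genes. Bootstrap and trinucleotide-null sizes are
reduced in unit tests (100-300 replicates) relative to the 1000-replicate
defaults; determinism under a fixed seed is asserted separately.

One published check is intentionally left failing: the survey summary
(94 islands; mean 42.6 kb, minimum 4758 bp, maximum 184 808 bp) can only
be recomputed from the survey's per-island size column, which lives in
journal supplementary material that cannot be redistributed with the
package. `load_survey_sizes()` accepts the column as a one-column TSV
when the user has it; the corresponding test documents the expected
values and fails cleanly without the file.

## Known limitations

Compound (join) GenBank locations are rejected, not flattened; wrapped
(origin-spanning) features are not stored. Forward integration into
naive genomes is only simulated, never predicted. Inverted repeats,
tandem multi-copy islands and non-cognate target sites beyond what the
generic repeat search finds are out of scope. The homology and orthology
thresholds are surrogates chosen for reproducibility; they are not
calibrated against any specific sequence database.
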