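---
title: "Methods: cleavage geometry, library simulation and site statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cleavage geometry, library simulation and site statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starcutter)
```

`starcutter` models a Type IIS/IIG restriction endonuclease with a
degenerate recognition sequence and strand-asymmetric downstream cleavage,
and the shotgun-junction experiment used to characterize its relaxed
("star") specificity. This vignette records the model, the conventions, and
the design decisions that were genuinely open.

## Cleavage geometry and coordinate conventions

All coordinates are 1-based on the top strand. A scission point is written
"cut after coordinate `c`": the phosphodiester bond between positions `c`
and `c + 1`, with bottom-strand bonds indexed by the top-strand base to
their left. For TthHB27I (`tthHB27I()`), a plus-strand site whose hexamer
spans `[s, s+5]` is cut after the 11th spacer nucleotide on the recognition
strand and the 9th on the complementary strand, counted from the last base
of the hexamer, exclusive:

```
top_cut_after    = s + 5 + 11
bottom_cut_after = s + 5 + 9
```

Minus-strand sites use the mirror-symmetric arithmetic (downstream runs
leftward). The "downstream, exclusive" reading is not arbitrary: it is the
only one of the four offset conventions (inclusive/exclusive × from
first/last base) that simultaneously yields 2-nt protruding **3'** ends and
reproduces the complete-digest core lengths of the two-site worked
substrate (311/602/872 bp, below). The top cut always falls 2 nt to the
right of the bottom cut, so each daughter fragment's protruding strand is a
3' end.

A site whose spacer runs off the molecule end returns no cut
(`cut_positions()` drops it). The alternative — a bound-but-uncut or
partially nicked site — is not modeled; nicking is out of scope, and a
half-cleavable terminal site has no observable product in any analysis this
package performs.

Methylation is a boolean flag on a site hit, set by the caller; flagged
sites contribute no cuts. It is a site property, not a sequence
modification, which mirrors how methylation is manipulated experimentally
(pre-methylation of cognate sites blocks their cleavage while star sites
remain cuttable).

## Duplex-core length accounting

Fragment lengths are reported as **duplex-core** lengths: the extent over
which both strands are paired, excluding 2-nt single-stranded 3'
extensions. For a linear molecule with `k` cuts the cores sum to
`L − 2k`. A partial-digest species spanning complete fragments `i..j`
regains the 2 bp of duplex at each of its `j − i` uncut internal sites:

```
length(i..j) = sum(core_i..core_j) + 2 (j − i)
```

This is the unique convention reproducing all six species of the worked
1789-bp substrate — 311, 602, 872 (complete), 915 = 311+602+2,
1476 = 602+872+2 (single-cut partials), and 1789 (uncut). Whether the
original band-size arithmetic intended this overhang accounting cannot be
confirmed from the published sizes alone; the convention is exact for all
six and is flagged as derived. Blunting (T4-polymerase style) trims each
fragment back to its duplex core, which is why blunt cloning junctions sit
exactly on core boundaries.

The worked substrate itself (`make_worked_example_substrate()`) is
synthetic: a seeded random background free of CAARCA matches on either
strand, with CAAACA planted top-strand at 297–302 and a bottom-strand
CAAGCA site spanning top coordinates 927–932. The positions are derived
from the printed core lengths assuming the fragment order 311 | 602 | 872;
since the real order is not recoverable, all tests compare length
*multisets*, never orders. A second fixture
(`make_nosite_substrate()`, 1850 bp) carries no cognate site at all and
stands in for the cognate-free control amplicon.

## Partial digestion

Partial digestion is modeled by a single per-site cut probability
(`sample_partial_digest()`, and per-variant probabilities in the library
simulator). Experimentally the partial extent is controlled by
temperature, time and enzyme amount; no quantitative kinetic model for
those knobs is published, so none is implemented — the probability is the
package's abstraction of that one-dimensional control. Species
identities under partial digestion are exactly the contiguous runs of
complete-digest fragments, `(k+1)(k+2)/2` of them when all run lengths are
distinct; the enumeration is validated against brute-force subset
digestion in the tests.

## The library simulator

`simulate_star_library()` emulates the shotgun experiment per clone:

1. one molecule of the reference is digested — every occurrence of a star-model
   word (both strands) is cut independently with its per-variant probability;
2. 3' overhangs are blunted back to the duplex core;
3. one insert is size-selected uniformly from the eligible fragments
   (`insert_min`–`insert_max` bp core length) and ligated in a random
   orientation between two synthetic vector flanks; with probability
   `concatemer_rate` a clone carries two inserts;
4. both vector–insert junction reads are emitted (vector tail + cloned
   sequence), with full ground truth in a manifest.

Defaults and why:

* `p_canonical = 0.9`, `p_relaxed = 0.5` — a two-tier efficiency model.
  Published per-variant efficiencies do not exist in machine-readable form,
  so canonical sites are simply modeled as better substrates than relaxed
  ones; the values are synthetic and labeled as such.
* `insert_max = 1000` bp — clones under ~1 kb were the ones the original
  junction sequencing targeted; `insert_min = 20` bp keeps every insert
  mappable by the decoder's 20-nt anchor.
* `concatemer_rate = 0.05` — multi-insert recombinants were observed but
  rare; only their vector–insert junctions are decoded.
* Reads are error-free: junction decoding in the source experiment used
  Sanger reads whose per-base quality is not the quantity of interest.
  The simulator is the study-condition generator, not a sequencing-error
  model.
* By default only inserts bounded by **two cuts** are cloned
  (`include_terminal = FALSE`). A molecule-end fragment has one terminus
  junction with no responsible recognition site; such junctions carry no
  signal and, decoded blindly, would occasionally be attributed to a
  background hexamer. Terminal fragments can be included explicitly when
  the full fragment pool matters (e.g. reproducing the three-species insert
  spectrum of the worked substrate).
* The vector is an abstract flank pair (`make_vector_flanks()`, 300 bp per
  side, cognate-free, seeded); any real vector sequence can be supplied.

What the generator deliberately does **not** emulate: ligation and
transformation bias, coverage bias along the genome, chimeras beyond the
two-insert concatemer, and chromatogram-level artifacts. Tests that pass
on these libraries therefore validate the *arithmetic* of digestion,
blunting, cloning and decoding — not robustness to real-world noise.

## Junction decoding

Mapping is exact-substring anchoring: the read's vector prefix is verified
and stripped, and the first 20 insert nucleotides are matched against both
reference strands with a unique-hit requirement (`decode_junctions()`).
This replaces similarity search deliberately — references are desk-scale
and the mapping fidelity of the original study is not the subject here.

A mapped junction is a duplex-core boundary, and inverting the cleavage
geometry yields exactly two site hypotheses: for an insert-start junction
at `p`, either a plus-strand site upstream (outside the insert), hexamer
`reference[p−17 .. p−12]`, or a minus-strand site inside the insert,
hexamer `revcomp(reference[p+9 .. p+14])`; insert-end junctions mirror
this. The offsets are derived from the blunting convention and are
validated by the simulate→decode round-trip tests rather than trusted; they
follow from `enzyme_spec`, so a different geometry changes them without
code edits.

Resolution between the two hypotheses is the one genuinely open design
decision. The default policy is **conservative**: a candidate is plausible
if it has ≤ 2 mismatches to CAARCA (the observed relaxation spectrum is
one- and two-mismatch variants), and a junction counts only when exactly
one candidate is plausible; two plausible candidates make it ambiguous,
which is surfaced, never guessed. A pure minimum-mismatch rule
(`policy = "min_mismatch"`, also provided) is subtly unsound for exact
variant inventories: when the true site carries two mismatches, the
opposite hypothesis's background hexamer falls within one mismatch of
CAARCA for ~0.8 % of junctions on random sequence, and those background
wins plant spurious "variants". The conservative rule pays for its safety
with a ~6–10 % ambiguous-junction rate, which is acceptable because
variant discovery needs each variant observed once, not every junction
counted.

## Site statistics

With `n` recognized 6-mers, the mean per-strand spacing of recognition
events on random sequence is `4^6 / n` bp and the effective site length is
`log4` of the unrounded spacing (`mean_spacing()`,
`theoretical_site_length()`). Note the convention: the word set is not
reverse-complement closed, so the *duplex* sees recognition events at
roughly twice the per-strand density; the spacing statistic is the
per-strand figure, which is the one conventionally quoted. Rounding is
half-up to one decimal, applied once at presentation — half-up (not R's
round-half-even) is required to reproduce the printed one-decimal values,
and internal computations stay unrounded.

Position frequency matrices weight each junction observation once by
default (`build_pfm(..., "count")`), matching a logo built over all
observed sites; a per-distinct-variant mode exists because the alternative
reading is defensible. Information content is `2 − H` bits per position
with no small-sample correction — the simplest defensible choice, and
switchable by weighting mode rather than hidden constants.

## Numerical and scale choices

All stochastic operations take an explicit integer seed and are
deterministic given it (byte-identical FASTA/manifest output). Degenerate
inputs are handled as stated errors: non-ACGT substrates name the offending
position, cut coordinates outside `[1, L−1]` are rejected or dropped,
malformed manifests report the offending line.

The test suite and the analysis scripts run the full-scale experiment at a
48.5-kb reference with 2,000 clones per condition (seconds per run); the
parameter-recovery checks use planted variant counts of 10, 48 and 66 and
require exact recovery, which the closed-form spacing and site-length
figures then follow from. Oracle-style checks (naive window scanning,
brute-force subset digestion, binomial closed forms) run at reduced sizes
— 2–8-kb sequences, up to ~10 cuts, 10⁴ molecules — chosen so each oracle
remains exhaustive or statistically sharp.

## Known limitations

* Per-variant cleavage efficiencies are a synthetic two-tier model; real
  relaxed sites surely span a continuum, which would change observation
  *counts* but not the variant inventory logic.
* The spacing statistic treats all recognized words as equally cuttable;
  it is a density statement about sequence space, not a kinetic one.
* Linear substrates only in the digestion front-end used here; the
  geometry itself is end-agnostic except for the uncleavable-terminal rule.
* The decoder assumes blunt junctions exactly at core boundaries; imperfect
  blunting or end-repair chew-back would shift junctions and is not
  modeled.
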