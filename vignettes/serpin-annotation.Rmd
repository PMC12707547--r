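---
title: "Methods: rule-based serpin annotation and its design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based serpin annotation and its design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serpinscope)
```

## The annotation model

Serpins are ~350–450 aa single-domain proteins whose inhibitory mechanism
hinges (literally) on the **reactive center loop (RCL)**: an exposed
C-terminal loop of 21 residues, P17→P4′ in Schechter–Berger subsite
notation, presenting the scissile P1–P1′ bond to the target protease. Two
sequence features identify a serpin and its loop without any structure:

* a conserved **hinge consensus** at the loop's N-terminal end —
  P17 [E], P16 [E/K/R], P15 [G], P14 [T/S], P13 [x], P12–P9 [A/G/S] —
  required for loop insertion into β-sheet A after cleavage;
* the family-level **serpin signature** (a PROSITE pattern shipped as
  data) and the N-terminal consensus motif `NAVYFKG` (the s3A region).

The pipeline turns these into explicit, testable rules. A protein is
screened for the signature and the N-terminal motif; the C-terminal region
is scanned for hinge-conforming windows; the best window anchors the
21-residue extraction; the residue at offset 16 from the hinge start (the
17th loop position, counting P17 as the first) is the P1 site. P1
chemistry predicts the target family: basic P1 → trypsin/thrombin-like
proteases, polar uncharged → elastase/chymotrypsin-like; acidic and
hydrophobic P1 sites get no target call. The assumptions are those of the
rule set itself: hinge conservation, a single functional RCL per
sequence, and P1 chemistry as a proxy for specificity — all reasonable for
inhibitory serpins, all wrong for non-inhibitory family members (see
Limitations).

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `orf_min_codons` | 100 | codons | serpins are large; 100 removes spurious ORFs while keeping truncated fragments |
| `nterm_motif`, `nterm_max_mismatches` | `NAVYFKG`, 2 | residues | the motif is a consensus; exact matching would reject natural variants. Searched only in the N-terminal half, where the s3A region lies |
| `hinge_max_noncritical_mismatches` | 2 | subsites | P17/P15/P14/P12 are critical and must match; known inhibitory serpins deviate at P16 or P9, so the non-critical subsites (P16, P11, P10, P9) get a budget of 2 |
| `hinge_scan_window` | 80 | residues | RCLs sit ~30–50 residues from the C-terminus; 80 is safely generous without inviting mid-domain false hits |
| `full_length_min/max` | 350 / 450 | aa | the canonical serpin size range. Sequences failing only this criterion are tagged (`length outside configured range`) rather than silently dropped, because borderline natural serpins (e.g. ~336 aa) exist |
| alignment | BLOSUM62, gap open 10, extend 0.5 | — | conventional protein-alignment defaults; all configurable |
| `log2` pseudocount | 1 | TPM | zeros are guaranteed by the presence–absence structure; `log2(TPM + 1)` keeps them finite and maps TPM 0 to 0 |

## Numerical and procedural choices

* **Coordinates** are 0-based half-open internally; all user-facing report
  output is 1-based inclusive.
* **Percentages** (P1 class shares, sex-partition shares) use
  *round-half-up* to 2 decimals, the convention that reproduces 8/17 →
  47.06, 7/17 → 41.18, 2/17 → 11.76. Base R's banker's rounding would
  disagree on exact ties.
* **Hinge tie-breaks**: among equal-score candidates the most C-terminal
  wins — the RCL is by definition the C-terminal-most hinge-like element.
  A candidate must leave ≥ 21 residues to the sequence end.
* **RCL uniqueness**: identical 21-mer loops collapse to one full-length
  representative, chosen by highest summed TPM, ties broken by
  lexicographic id; the others are demoted to partial with
  `rcl_unique = FALSE`.
* **P1 class table** is total and disjoint over the 20 standard residues;
  G and P are grouped with the hydrophobics so the function is total
  (neither occurs at observed tick-serpin P1 sites). An `X` at P1 voids
  the annotation rather than guessing.
* **Logo matrix** reports true information content,
  `IC = log2(20) − H` bits (max ≈ 4.32 for a fully conserved column), and
  is deliberately not rescaled to a 0–4 axis; no small-sample correction
  is applied.
* **Distances and trees**: pairwise p-distance (`1 − identity/100`) from
  global alignments feeds Saitou–Nei neighbor joining. Maximum-likelihood
  estimation under an empirical substitution model is out of scope, so
  published likelihood-based trees are not reproduced — only the
  distance-based guide-tree stage. Negative NJ branch lengths are clamped
  to zero with the deficit moved to the sibling branch, preserving path
  lengths through the join. Taxa are processed in sorted order, making
  the topology input-order-invariant. Midpoint rooting bisects the
  longest leaf-to-leaf path; outgroup rooting splits the outgroup's
  pendant edge in half.
* **Degenerate inputs**: empty FASTA → empty table (the pipeline aborts
  with a typed error); all-zero count samples → zero TPM with a warning;
  proteins shorter than 21 residues or hinge-free → partial, tagged
  `truncated C-terminus`; a trailing partial codon in translation is
  dropped with a warning; codons containing N translate to X.
* **Similarity** in alignment reports is the fraction of columns with a
  positive substitution-matrix score. There is no universal definition of
  "similarity"; this one is stated here because published similarity
  percentages depend on the chosen convention and are not directly
  comparable.

## What the synthetic generator emulates — and what it does not

`generate_serpins()` plants the exact architecture the screen looks for:
initiator Met, `NAVYFKG` in the N-terminal third, a signature-conforming
segment, and a hinge-conforming RCL placed so that 10–40 residues remain
downstream (the loop sits near the C-terminus), with P1 drawn from a
configurable distribution or planted exactly. Partial sequences are the
same scaffolds truncated uniformly upstream of the hinge. Scaffolds are
rejection-sampled so the planted hinge is the unique top-ranked candidate
(or, for truncations, so that no candidate survives); recovery of the
planted truth is therefore exact by construction, which is precisely what
makes it a sharp regression oracle. Nucleotide records are exact
back-translations with 25-nt UTRs, an in-frame stop, and an ATG-free
5′ UTR so the planted ORF is the longest.

Background residues are i.i.d. uniform over the 20 standard amino acids.
Real serpins are not: they share a conserved fold, biased composition, and
homologous non-loop regions. Consequently, passing the recovery tests
demonstrates the rules are implemented correctly, **not** that the rule
set has any particular sensitivity/specificity on real transcriptomes —
real partial sequences may retain hinge-like windows, and real full-length
serpins may violate the hinge consensus at critical subsites.

`generate_expression()` emulates the two-sex presence–absence structure
with negative-binomial counts (mean 200, dispersion 0.5 — over-dispersed,
RNA-seq-like) for expressed transcript/sex pairs and exact zeros
elsewhere, with at least one positive sample per expressed sex enforced.
It does not model library-size variation, within-sex biological
variability of interest, or mapping noise; it exists to exercise the
zero-TPM rule, which depends only on the zero pattern.

The default study-shaped preset (`synth_preset("paper")`) uses 110
sequences with 17 complete serpins and a 4/15/91
female-only/male-only/shared partition, with the 17 P1 residues of the
published full-length set planted in id order. The test suite exercises
smaller cohorts (10–20 sequences) for speed; the full preset is used in
the end-to-end acceptance checks.

## Limitations

* Signal peptides and O-glycosylation are **ingested**, not predicted;
  N-glycosylation output is the sequon rule (necessary condition), not an
  occupancy prediction.
* Molecular weights require fully standard sequences (no X) and use
  average isotopic masses.
* BLAST-based homology annotation, profile HMMs, likelihood-based
  phylogenetics and any structural validation of the RCL are out of
  scope; the rule-based calls are starting points for experimental
  follow-up, not functional proof.
* The zero-TPM presence rule is deliberately strict (no epsilon); with
  deeply sequenced libraries a single stray read makes a transcript
  "expressed", so upstream count filtering is the user's responsibility.
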