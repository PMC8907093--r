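---
title: "Phylogenetic placement of AMF LSU amplicons: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic placement of AMF LSU amplicons: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amfplacer)
library(ape)
```

## The problem

Arbuscular mycorrhizal fungi (AMF, phylum Glomeromycota) resist
database-matching identification: a large fraction of environmental AMF is
undescribed, so sequences absent from databases would simply be discarded.
Phylogenetic placement sidesteps this: a study sequence is attached to a
fixed, curated backbone phylogeny of reference LSU (28S rRNA) sequences, and
whether it falls inside the Glomeromycota clade — and inside one of the 11
described family clades — is read off the attachment edge. The LSU region
between the LROR and FLR2 primers evolves fast enough to separate families
and slow enough to build reliable trees, which makes it a practical marker
for paired-end Illumina amplicon surveys.

`amfplacer` implements the complete path from paired reads (or pre-denoised
ASVs) to clade-filtered feature tables:

1. **Reference curation** — trim references to the primer-bounded region,
   pad short entries, annotate family labels.
2. **Read preparation** — primer clipping, truncation, filtering, merging,
   dereplication.
3. **Homology pre-screen** — a permissive local-alignment filter against the
   reference database.
4. **Features** — greedy OTU clustering at an identity threshold, or ASV
   passthrough.
5. **Split alignment** — R1 and R2 fragments aligned separately against
   read-length-cut reference alignments, then concatenated.
6. **Placement** — minimum-parsimony attachment of each query onto the
   backbone tree.
7. **Clade extraction** — Glomeromycota and family tables via MRCA-delimited
   clades.

## Reference curation

Every reference is searched for the forward primer and the reverse
complement of the reverse primer, on both strands, allowing a mismatch
fraction of up to `max_error_rate` (default 0.1, the convention of common
read-trimming tools). Matching is mismatch-only — no indels — which keeps
primer location deterministic and is adequate for primer-length (17–21 bp)
patterns. IUPAC degeneracy is honoured on both sides and `N` matches
anything. The region between the two sites becomes the curated sequence.

References in which no primer pair is found (database entries amplified with
interior primers are genuinely shorter than the LROR–FLR2 region) are kept
whole and padded with `N` to the common target length; `strict = TRUE` drops
them instead. Padding is 5′-anchored by default (`anchor = "start"`): the
choice is exposed because either convention is defensible, and `N` columns
are wildcards downstream, so the effect is limited to which columns a short
reference informs.

The shipped LROR/FLR2 primer strings are the published primer sequences from
the primary literature. They are defaults in a `primer_pair()` object, not
constants: any primer system can be configured.

### Cutting references to read lengths

Placement compares only regions present in both study and reference
sequences: each curated region is cut to an R1 fragment (first `r1_len`
bases) and an R2 fragment (last `r2_len` bases, reverse-complemented into
read orientation), mirroring what the sequencer sees. The default 150/150 bp
matches a conservative quality cutoff for Illumina paired-end data.

## The homology pre-screen

Non-homologous reads (chimeras, non-target amplification, artefacts) must be
removed before tree building: placed anyway, they attract each other and
produce spurious long-branch clusters. The screen keeps any query whose best
local alignment against *any* reference reaches `min_score`.

The aligner is an affine-gap Smith–Waterman (both query strands) under the
scheme match +1, mismatch −2, gap open −5, gap extend −2; `N` scores 0
against everything, and a gap of length $L$ costs $5 + 2L$. The default
`min_score = 40` therefore corresponds to roughly a 40 bp perfect match —
deliberately permissive, since the filter's job is to detect *any* homology,
not to classify. Both the scheme and the threshold are tunables; raising
`min_score` can only shrink the retained set (a property the tests assert).
An optional seed-and-extend accelerator (`accelerate = TRUE`) orders subjects
by shared 7-mers and stops at the first sufficient hit; it never changes
which queries are retained, only which subject is reported for retained
queries.

## Features: OTUs or ASVs

Dereplication aggregates identical sequences and orders features by
abundance (ties broken lexicographically, so tables are reproducible).
Greedy centroid clustering then processes features in that order; a sequence
joins the first centroid whose end-to-end global-alignment identity reaches
the threshold (identity = matching columns / all alignment columns, gaps
counting against identity — stated explicitly because "identity" has many
dialects). The default threshold 0.97 is the field convention. ASV mode
simply skips clustering; it is exactly `cluster_otus(ft, 1.0)`, and the test
suite asserts table equality between the two.

The built-in truncate/filter/merge step is a deliberately simple stand-in
for a full denoising algorithm: it truncates R1/R2, drops pairs containing
`N`, and concatenates R1 with the reverse complement of R2 (the two
fragments cover disjoint ends of the region, so no overlap assembly is
attempted and no error model is learned). When sequencing-error correction
matters, supply externally denoised ASVs via `features =` instead.

## Split R1/R2 alignment

The R1 and R2 fragments represent two separate stretches of the LSU, so they
are aligned in two independent blocks and concatenated afterwards. This
makes it structurally impossible for the R1 of one sequence to align against
the R2 of another — a failure mode of aligning full concatenated sequences
in one pass.

The reference block is built progressively (guide order = input order, so
the result is deterministic): each fragment is aligned to the column profile
of the rows so far, and an insertion it carries opens a new all-gap column.
Queries are then aligned one at a time against the *frozen* reference
profile: reference columns are immutable, query insertions relative to the
reference coordinate system are dropped (and counted in the insertion
report). This was a genuinely open design point — a general MSA tool would
re-align everything per batch — and the profile approach was chosen because
it is deterministic, order-independent across queries, and preserves the
reference coordinate system that placement and clade extraction depend on.

Profile scoring uses the expected match score against the column's base
frequencies; `N` and gap cells contribute nothing ("gap-neutral" missing
data). Terminal gaps of the fragment are free — fragments are partial reads
and should not be penalised for not spanning the block — but insertions are
always penalised, so a fragment cannot drift off the profile.

## Parsimony placement

Each aligned query is attached, one at a time, to every edge of the rooted
backbone (plus the root itself) and each augmented tree is scored by
small parsimony: the Fitch count for binary nodes, its counting
generalisation (Hartigan) at multifurcations. `N` and `-` are wildcard
states, so columns with no data in the query contribute nothing. The
attachment with the minimum score wins; ties go to the edge closest to the
root, then the smallest edge id — a conservative choice that prefers *less*
specific claims when the data cannot distinguish attachment depths.

Queries are placed independently by design. Joint placement of a batch lets
query-query attraction distort the tree (the long-branch clusters the
pre-screen exists to prevent); independent placement makes results invariant
to batch composition and order, which the tests assert directly.
`batch_size` therefore affects only audit-tree emission, never results. The
implementation rescoring is incremental (only the path from the attachment
edge to the root is recomputed per column), and the test suite proves it
equal to an independently coded brute-force oracle that grafts the query
with `ape::bind.tree` and rescores the whole tree.

Parsimony was chosen over maximum-likelihood placement deliberately: it is
deterministic, dependency-free, and desk-scale, and the placement contract
(`placer` adapter) leaves room for an external ML placer without changing
any downstream interface. Placements are written as standard jplace (version
3) JSON with `{edge_id}` numbering on the backbone Newick.

## Clade extraction

A clade is delimited by the MRCA of its defining reference tips; its member
edges are all edges strictly inside the MRCA's subtree. Attachments on a
clade's **stem** edge count as *outside* by default: a sequence attaching
below the Glomeromycota MRCA may be sister to the phylum, and claiming it as
AMF would overstate the evidence. `include_stem = TRUE` flips this for
sensitivity analyses. Within the AMF clade, a placement gets the smallest
enclosing family clade, or `Glomeromycota_unclassified` when it falls
between family clades — the smallest-clade rule is safe even if clades were
ever nested. Features that were screened out or are unplaceable are written
to a separate discarded bucket rather than silently dropped, since such
sequences may well represent undescribed taxa worth revisiting.

The per-clade summary reports both the percentage of AMF *features* and of
AMF *reads* in each family — the two can diverge sharply when few features
carry most of the reads, which is exactly the pattern expected from
spore-derived material.

## The synthetic study design

`make_fixture()` generates the fixed conditions under which the package
validates itself, emulating a placement study with known truth:

* a rooted binary backbone with an outgroup subtree and an AMF subtree in
  which each of the 11 families is a clean clade (family subtrees grafted
  onto a family backbone);
* branch lengths chosen to mimic LSU-like divergence: within-family
  branches 0.02 + Exp(0.06), family stems and backbone branches
  0.08 + Exp(0.05), outgroup branches 0.04 + Exp(0.08), with a per-site
  substitution probability of `min(rate × branch length, 0.75)` and
  `substitution_rate = 0.5` — giving roughly 1–7% divergence within
  families, 10–25% between families, and 25%+ to the outgroups. The
  within-family minimum keeps sibling references distinguishable on the cut
  region;
* reference "raw" sequences that carry the primer pair around the evolved
  region, so curation is exercised rather than bypassed;
* 100 query read pairs drawn from random tips and further mutated at 2%
  per site (`query_divergence`), with primers at the 5′ ends and constant
  Q37 qualities;
* 15 junk read pairs of i.i.d. uniform bases, emulating the non-homologous
  artefacts the pre-screen removes.

Substitutions follow a symmetric (Jukes–Cantor-style) model without indels;
an indel-free generator cannot stress the insertion-dropping logic of the
profile aligner, which is therefore tested separately on constructed cases.
Junk reads are uniform-random rather than real contaminants — sufficient to
reproduce the class of artefact (no homology to any reference), but a real
contaminant with partial rRNA homology would be a harder case than anything
the fixture contains. Passing the synthetic suite therefore demonstrates the
machinery is correct under the stated model, not that real soil data are
this clean: real reads bring quality decay, chimeras, and length variation
that the fixture deliberately omits.

Everything is deterministic given `seed` (fixture files are byte-identical
across reruns; the suite asserts it).

## A worked run

```{r example, eval = FALSE}
library(amfplacer)

fx <- make_fixture(sim_config(seed = 42))
res <- pipeline_run(pipeline_config(
  reference_fasta = fx$ref_raw, family_map = fx$family_map,
  tree_newick = fx$tree, reads_r1 = fx$reads$r1, reads_r2 = fx$reads$r2,
  mode = "asv", seed = 42))

res$manifest$feature_counts  # the stage funnel
res$summary                  # per-family % of AMF features and reads
```

The problem sizes used throughout the package's own validation — an 80-tip
backbone (60 AMF / 20 outgroup), 600 bp regions, 150 + 150 bp reads, 100
queries — were chosen as the smallest configuration that still exercises 11
non-trivial family clades; the oracle-equivalence checks run on hundreds of
small random instances (≤ 15 tips × 50 columns for placement, ≤ 200 bp pairs
for the aligner) where exhaustive rescoring is cheap.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; reports are 1-based closed.
* Primer-site ties break leftmost; abundance ties break lexicographically;
  placement ties break root-most, then smallest edge id. Every tie-break is
  fixed so identical inputs give identical outputs.
* All-`N` (or all-gap) query rows are flagged unplaceable and land in the
  discarded bucket; empty query sets, empty screens, and zero-AMF summaries
  return empty, well-formed objects rather than errors.
* `r1_len + r2_len` must not exceed the curated region length; violating
  configurations error at validation, not mid-run.

## Known limitations

* Parsimony placement carries no branch-length or support information; the
  jplace `parsimony_score`/`score_margin` fields are integers, not
  likelihood weights.
* The denoising stand-in corrects no sequencing errors; with raw error-prone
  reads, ASV counts will be inflated relative to a real denoiser.
* The profile aligner drops query insertions; a query with a genuine large
  insertion relative to all references loses that signal (the insertion
  report makes this visible).
* Species-level assignment is out of scope: the deliverable is phylum- and
  family-level membership.
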