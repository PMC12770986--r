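---
title: "Transparent gene clustering and pangenome inference with panfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transparent gene clustering and pangenome inference with panfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panfam)
```

## The problem

A prokaryotic pangenome partitions a species' gene repertoire into core
genes (present in essentially every genome) and accessory genes (shell and
cloud) that carry adaptive variation. The partition rests entirely on
sequence clustering, and clustering is far less deterministic than it looks:
identity thresholds interact with length-difference cutoffs, greedy
incremental algorithms depend on processing order, heuristic prefilters
depend on resource allocation, and even the floating-point precision with
which a threshold is written can move genes between families. panfam
implements the full pipeline — genome ingest, clustering, family
classification, pangenome outputs, reclustering — with every one of those
decisions explicit, exact where exactness is possible, and reproducible
byte-for-byte.

## Pipeline and model

The pipeline has three modes. **Full Mode** parses a directory of GFF3
genomes (embedded `##FASTA` or sibling FASTA), extracts the requested
feature types, tags every gene ID with its genome of origin
(`genome|gene`), clusters the combined gene set, and classifies the
resulting families. **Partial Mode** starts from an existing clustering — a
CD-HIT `.clstr` file or a two-column edge list whose connected components
define the clusters — and performs the identical downstream inference, so
the two modes agree bit-exactly given equivalent clusterings. **Recluster
Mode** integrates second-round sequences into a finished pangenome without
mutating it, labelling each combined cluster by how the additions changed
it.

### Family classification

A family present in $k$ of $n$ genomes belongs to the band whose interval
contains $100k/n$. The default scheme is the conventional one:

| band | interval |
|------|----------|
| `First_core_99` (core) | $[99, 100]$ |
| `First_core_95` (soft-core) | $[95, 99)$ |
| `First_core_15` (shell) | $[15, 95)$ |
| `First_core_0` (cloud) | $[0, 15)$ |

Bands are lower-inclusive with 100% included in the top band — the only
reading consistent with the conventional core definition in which full
presence is core. The comparison $100k/n \ge \ell$ is evaluated by integer
cross-multiplication ($10000\,k \ge \ell_{100}\,n$, with $\ell_{100}$ the
bound in hundredths of a percent), so boundary cases such as $19/20 = 95\%$
are exact and no floating-point representation can flip them. Users can
substitute any strictly decreasing set of named bounds ending in 0.

### The clusterer

`greedy_cluster()` is a deliberately transparent greedy incremental
clusterer with CD-HIT-compatible parameter semantics. Sequences are
processed longest-first (ties broken lexicographically by ID); each joins
the first existing representative that passes

* the **length-difference cutoff** `s`: member length / representative
  length $\ge s$, and
* the **identity threshold** `c`: alignment matches / member length
  $\ge c$,

or founds a new cluster. Both thresholds are tested with exact integer
arithmetic after `c` and `s` are normalised to exactly two decimal places
at ingest — a user's `0.9` and `0.90` are one and the same run, by
construction. The clusterer is single-threaded and carries no
resource-dependent state, so identical inputs give byte-identical `.clstr`
output regardless of declared thread or memory settings; those settings
exist only for external-tool invocation and are always recorded in the
provenance file.

Alignment uses Smith–Waterman local alignment (via Biostrings) with match
$+1$, mismatch $-1$, gap opening $-2$, gap extension $-1$. These constants
are this package's own and are centralised in `pairwise_identity()`;
nothing downstream depends on reproducing any external tool's internal
scores — only on the *threshold semantics*.

**The identity denominator matters more than it seems.** Three are
offered. The default, `shorter`, divides matches by the full length of the
shorter sequence — the global-identity convention CD-HIT applies by
default. The `overlap` denominator divides by the aligned span of the
shorter sequence only: under it, two sequences sharing a single conserved
domain score near 100% regardless of everything outside the domain, which
is precisely how vastly different-length sequences end up co-clustered
when length constraints are relaxed. The `alignment` denominator (strict
mode) counts gap columns as differences. The clusterer uses `shorter`:
with a purely local denominator, short chance-identical segments between
unrelated sequences would satisfy any identity threshold, and no planted
family structure could ever be recovered exactly — the local-overlap
behaviour is exposed for study, not used for inference. The
length-difference cutoff is what actually polices length disparity: at
`s = 0.80` a half-length gene fragment cannot join its source family and
falls into a lower presence band, while at `s = 0.00` (the CD-HIT default)
fully contained sequences co-cluster freely.

A shared-k-mer prefilter (`word_size`, default 8) skips candidate
comparisons that cannot reach the identity threshold. The pass bound,
$(m-k+1) - k\lceil (1-c)m \rceil$ shared k-mer occurrences for a member of
length $m$, is exact for ungapped alignments and heuristic once gaps are
involved; the filter is a pure optimisation (tests compare filter-on
against filter-off) and `word_size = NULL` disables it.

### Reclustering categories

Given a first-round pangenome and a clustering of old plus new sequences,
every combined cluster is mapped to the first-round families of its old
members and labelled, with precedence
`only_second > combined > extended > second > first`:

* `only_second` — no first-round sequences at all;
* `combined` — old members from two or more first-round families, merged
  by the additions;
* `extended` — a single origin family whose band over all members is
  strictly *higher* than its first-round band;
* `second` — the band over the cluster's old members alone is strictly
  lower than over all members: the band is attained only by counting
  new-sequence genomes (this arises when an origin family fragments and
  new sequences compensate);
* `first` — the cluster reproduces a first-round family unchanged.

The `extended`/`second` boundary is genuinely ambiguous in informal
descriptions of such schemes; the disambiguation above makes the five
labels mutually exclusive and collectively exhaustive, and is fixed as this
package's definition. Origin families whose members scatter over several
combined clusters are additionally reported in a fragmentation table — the
failure mode in which long additions (StORF-like stop-to-stop ORFs,
typically longer than standard annotations) break existing clusters under
length-first greedy clustering — rather than being folded into the five
labels.

### Robinson–Foulds concordance

Single-gene trees frequently disagree with each other and with the
concatenated "species" tree; normalised Robinson–Foulds (RF) distances
quantify this. `rf_distance()` counts non-trivial bipartitions present in
exactly one of the two trees and normalises by the total number of
non-trivial splits in both trees. For fully binary trees this equals the
usual $2(n-3)$ maximum; for multifurcating trees it shrinks with the
resolved split count, which keeps normalised values in $[0,1]$ and
comparable across resolutions (normalisation conventions differ between
tools precisely here, so ours is stated). RF analysis is restricted to
single-copy-per-genome core families when orchestrated by the workflow,
since multi-copy families require an undocumented representative choice.
Representative selection itself is exposed as three policies (`longest`,
`medoid_length`, `cluster_rep`) because the conventional longest-sequence
default can elect a gene functionally unlike every other family member.

## Synthetic pangenomes and what they do (not) show

`generate_pangenome()` plants known family structure: core families in all
genomes, accessory families with sampled presence fractions (default
uniform on $[0.1, 0.9]$, spreading families across shell and cloud),
optional within-genome paralogs, per-site substitution noise, and optional
gene fragmentation (a gene split into two features at a uniform internal
point, emulating annotation/assembly error). Ancestors are random codon
strings of 300–1500 nt (ATG, non-stop codons, terminal stop); about a
quarter of genes are placed on the reverse strand. Generation is a pure
function of the spec and seed, byte-identical across runs.

The generator controls identity structure, not biology: no recombination,
horizontal transfer, indel evolution, or compositional bias. Passing tests
on these fixtures demonstrates that the pipeline's logic is correct under
its own assumptions — exact family recovery when within-family identity
(~98–99% at the default 1% substitution rate) clears the 90% threshold and
between-family identity does not — and that band accounting, reclustering
labels and diagnostics are internally consistent. It does not demonstrate
that any particular threshold is biologically appropriate for real data,
where gene birth, pseudogenisation and domain sharing blur family
boundaries; the diagnostics exist precisely because no fixed threshold
handles those cases transparently.

Problem sizes used by the test-suite study conditions: 20 genomes with 100
core and 50 accessory families (~2,500 genes) for end-to-end recovery and
determinism; 6–10 genomes for the workflow and reclustering fixtures;
exhaustive sweeps to $n = 200$ genomes for classification boundaries;
sequences to 30 nt for the exhaustive alignment oracle; trees to 8 leaves
against an independent RF implementation.

## Numerical and design choices

* **Exactness where drift is possible.** Band boundaries and both
  clustering thresholds are integer comparisons; thresholds are two-decimal
  by construction. The only floating-point quantities in outputs are
  reported means and identities, printed at two decimals as is
  conventional for `.clstr`.
* **Determinism as a contract.** All orderings are explicit (radix sort,
  locale-independent): genomes lexicographic, sequences longest-first with
  lexicographic tie-break, presence–absence rows by descending isolate
  count then family ID. Two runs of any mode with the same configuration
  are byte-identical, and the declared thread count provably cannot leak
  into results.
* **Representative identity in summaries.** `.clstr` files print no
  identity for the representative; `group_summary()` counts it as 100.00
  by default (it is trivially identical to itself) with a flag to exclude
  it instead, since published per-cluster summaries do not state their
  convention.
* **Split/merge events** in `compare_partitions()` count fan-out: a
  cluster of run A whose members land in two or more clusters of run B is
  one split event, and symmetrically for merges. This is one of several
  defensible definitions (maximum-overlap mappings being another); the
  fan-out form is symmetric, order-free, and matches the intuitive reading
  of "a singleton was absorbed" as exactly one merge.
* **Truncated `.clstr` IDs** are stored as printed; `find_sequence()`
  resolves them by prefix matching with an explicit ambiguity flag, since
  producers may truncate long headers.
* **Degenerate inputs.** Empty cluster files yield header-only outputs
  with zero totals; empty second-round sets yield an all-`first` report;
  sequences with length not divisible by three are truncated and flagged,
  internal stops retained and flagged — no gene is silently dropped.
* **Multi-span (joined) CDS features are skipped with a warning** —
  single-span features only, adequate for the prokaryotic annotations this
  package targets.
* **Non-coding features** (rRNA, pseudogenes) are extracted as DNA only;
  amino-acid-mode clustering excludes records without a translation.

## Limitations

The internal clusterer trades speed for transparency: it is quadratic in
the worst case and not a performance substitute for CD-HIT at database
scale. Its identities are its own (stated scoring), so numeric identity
values will differ from CD-HIT's even when threshold decisions agree.
Paralog splitting by synteny is intentionally absent — it is an external
behaviour under study, not replicated. Alignment (MAFFT) and tree
inference (FastTree) are external subprocesses with logged command lines,
not reimplementations.
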