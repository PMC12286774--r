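---
title: "Discovering segmented RNA virus genomes by abundance co-occurrence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering segmented RNA virus genomes by abundance co-occurrence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virseg)
```

## The problem

Metatranscriptomic virus discovery is anchored on the RNA-dependent RNA
polymerase (RdRP), the only gene shared by all RNA viruses. For viruses
whose genome is split across several physically separate RNA molecules,
homology search finds the RdRP segment but routinely misses the other
segments: they encode fast-evolving structural or accessory proteins
with no detectable similarity to anything known. Those segments are not
invisible, though — they travel with their virus. In a collection of
sequencing libraries, every segment of one virus must be present in the
same libraries, at abundances that are proportional to each other
(transcription of all segments is driven by the same infection load).
`virseg` turns that ecological signal into genome reconstruction: it
correlates the per-library abundance profile of every assembled contig
with the profile of each RdRP-carrying contig and clusters the contigs
that co-vary with it.

## The model

Write \(t_{ij}\) for the TPM of contig \(i\) in library \(j\). For a
virus with per-library load \(L_j\) and per-segment scale factors
\(s_k\), the expected abundance of segment \(k\) in library \(j\) is

\[ t_{kj} \propto L_j \, s_k, \]

so any two segments of the same virus have abundance profiles that are
proportional across libraries — even in multipartite viruses, where the
\(s_k\) differ by more than an order of magnitude. Proportionality up to
a monotone transform is exactly what a rank correlation detects, so the
co-occurrence statistic is Spearman's rho between a candidate contig's
TPM profile and the anchor RdRP's profile, computed over **all**
libraries. Joint absence is informative (two segments of one virus are
both missing from uninfected libraries), so zeros stay in and ties —
including tied zeros — receive mid-ranks. A constant profile has no
rank signal at all; its correlation is undefined and is treated as
below any threshold rather than as perfect agreement.

A contig joins an anchor's cluster when its rho reaches the correlation
threshold (default 0.8, inclusive at equality; an exclusive mode is
available). One cluster is formed per anchor, and a contig may sit in
several clusters until quality control arbitrates.

## Anchor screening

A contig becomes an RdRP anchor only if it has a viral-protein hit at
e-value \(\le 10^{-4}\) **and** an RdRP-database hit at e-value
\(\le 10^{-5}\) (both searches are inputs, in BLAST/DIAMOND 12-column
tabular form). Anchors are then screened for:

* **chimeras** — a virus-free nucleotide hit of at least 100 nt lying
  essentially outside the RdRP region (overlapping it by less than half
  the hit's length) marks an assembly artifact joining viral and
  non-viral sequence. The flagged regions are recorded so a caller can
  trim instead of discard; the default is to discard, because a chimeric
  anchor contaminates every correlation it anchors.
* **coverage** — assembler coverage (megahit `multi=`, SPAdes `_cov_`,
  or a supplied table) must reach 50; exactly 50 passes. Low-coverage
  RdRPs are where false discoveries concentrate: fragmented assemblies
  of unsegmented genomes masquerade as "segments". Missing coverage
  fails the filter — this screen is mandatory for anchors.
* **length** (\(\ge\) 600 nt) and **coding potential** (at least one
  ORF of \(\ge\) 30 aa in six-frame stop-to-stop scanning, no start
  codon required; codons containing `N` translate to `X` and never
  terminate an ORF).

## Abundance matrix

Contigs below 600 nt or without a qualifying ORF are dropped. The
remaining contigs are dereplicated with a greedy k-mer containment
pass (k = 10, containment threshold 0.8, either strand, longest contig
first): a deterministic stand-in for alignment-based clustering that is
exact for the case that matters here — the same segment assembled
independently in several libraries. Member counts are summed into their
representative **before** TPM normalization, so each virus segment
contributes one row with a full cross-library profile; without pooling,
cross-library correlation would be undefined. TPM is computed per
library (counts divided by length in kb, rescaled to sum to \(10^6\));
all-zero libraries stay all-zero, and per-library rescaling of raw
counts provably leaves TPM unchanged.

## Cluster quality control

Five removal rules mirror the failure modes of correlation clustering.
Per member (checked in order, one primary reason each): cellular gene
(best cellular-protein hit above 30% amino-acid identity that also
outranks every viral hit by bitscore — a viral protein with weak
cellular similarity is kept), short (< 600 nt), low TPM (maximum
across libraries < 200), low coverage (< 10; exactly 10 is kept).
Per cluster: `rdrp_only` (no non-RdRP member survived — a lone RdRP is
not evidence of segmentation), `multi_rdrp` (more than one RdRP — two
viruses are entangled; the stricter of the two published phrasings is
the default, configurable to 2), `cellular` (more than half of the
original members were cellular removals), `low_abundance` (the anchor
itself fails coverage/TPM — re-checked because dereplication pooling
can change the anchor's profile after screening), and `low_prevalence`
(anchor detected in fewer than 3 libraries — too few points for a rank
correlation to mean anything). A removed cluster keeps its flags and
its removed members, so every decision is auditable. The TPM rule uses
the maximum across libraries, the most permissive reading consistent
with an "abundance threshold" on sparse profiles.

Satellite RNAs are the deliberate exception to "one virus, one
cluster": a satellite depends on its helper virus, co-occurs with it,
and legitimately joins the helper's cluster. Members retained in more
than one cluster are flagged ambiguous, never silently deleted.

## Terminal-motif verification

Segments of one virus often share conserved, sometimes
reverse-complementary, untranslated termini. As homology-independent
evidence, `virseg` enumerates every k-mer (k = 6–15) in the first and
last 50 nt of each retained member and reports motifs carried by at
least 80% of segments, at the 5' end, the 3' end, or in the cross
configuration (motif at 5', reverse complement at 3'). Exhaustive
exact enumeration replaces probabilistic PWM discovery: for a
presence/absence verdict on windows this small it is complete,
deterministic and order-independent; an optional one-substitution
tolerance absorbs ragged assembly ends. Reported motifs are maximal
(no substring of an equally supported longer motif), and a cluster
gains `homology_independent_support` when a motif of \(\ge\) 8 nt
reaches the support fraction. Verification attaches evidence to the
report; it never deletes a cluster. The 0.8 support default tolerates
one ragged end in a five-segment cluster; the 8-nt floor reflects that
shorter shared k-mers arise too easily by chance in 50-nt windows.

## The synthetic benchmark

`simulateBundle()` generates the full input bundle (FASTA with coverage
tokens, count table, annotation tables, ground-truth manifest) from a
generative model that matches the method's premise: per virus and
library, presence is Bernoulli (prevalence 0.6 by default), load is
lognormal (meanlog `log(3000)`, sdlog 1.2 — loads span roughly two
orders of magnitude across libraries), segment rates are load times a
per-segment scale (spanning 0.1–1.0, one order of magnitude) times
multiplicative lognormal noise (CV 0.1), and counts are Poisson draws,
so weak segments drop out stochastically exactly as real mapping counts
do. Host contigs get independent lognormal profiles; co-varying
confounder triplets share a load to prove that correlated non-viral
background does not form clusters (it has no anchor); a satellite rides
a helper's load; optional decoy "RdRP" contigs with low assembler
coverage track host profiles, reproducing the false-discovery regime
that the coverage threshold exists to kill. Every simulated contig
carries a planted ORF, so the coding filter passes by construction
rather than by luck, and chosen viruses carry planted terminal motifs.

`defaultBenchmark()` pins the desk-scale study condition used
throughout the tests: 100 libraries, 20 segmented viruses with segment
counts cycling 2, 2, 3, 3, 3, 4, 5, 8 (70 segments), 10 unsegmented
viruses, 1 satellite, 200 host contigs, noise CV 0.1, no explicit
dropout (Poisson counting already yields sparsity). At the default
thresholds the pipeline recovers all 70 segments in exactly 20 clusters
with zero cross-virus assignments, and on a decoy-spiked bundle the
false discovery rate falls monotonically to zero as the anchor coverage
threshold rises to 50 — the desk-scale analog of the parameter
optimization the thresholds came from.

What the simulator does **not** emulate: sequencing error and assembly
fragmentation, strain mixtures, compositional (closed-sum) coupling
between highly abundant taxa, uneven library sizes, or homologous
segments shared between related viruses. Passing tests on this
generator therefore demonstrate the statistical machinery — rank
correlation under zero inflation, threshold logic, QC rules — not
robustness to every artifact of real assemblies.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere (BLAST tabular
  convention); reverse-strand hits are canonicalized with a strand
  flag.
* Contig ids are namespaced `"<library>::<id>"` at read time; absent
  abundance is 0.0 (it carries co-occurrence information), absent
  coverage is `NA` (it does not — it fails mandatory coverage screens
  instead).
* Equality at thresholds: coverage 50 and 10 pass, length 600 passes,
  TPM at exactly the threshold passes, rho at the threshold joins by
  default. The published account of the correlation boundary is
  internally inconsistent (a segment at rho 0.83 was lost when the
  threshold was set to 0.83), so both inclusive and exclusive modes are
  exposed rather than guessed; inclusive is the default.
* Ties in anchor-hit selection break by lower e-value, then higher
  bitscore, then subject id — the run is fully deterministic, and
  cluster reports are byte-identical across reruns.
* Problem sizes in the tests (100-library benchmark, 30-library unit
  fixtures, 1000-vector correlation oracles) were chosen as the
  smallest sizes at which the statistical claims are comfortably
  separated from sampling noise.

## Known limitations

Two viruses that genuinely co-infect the same hosts at proportional
loads are indistinguishable by co-occurrence alone; the multi-RdRP rule
removes such entangled clusters rather than resolving them. Segments
below 600 nt or below the TPM floor are invisible by design — the
thresholds trade sensitivity for a near-zero false discovery rate, and
can be relaxed per run. The dereplication surrogate measures k-mer
containment, not alignment identity; highly repetitive contigs can
over-merge at the default threshold. Finally, the correlation is only
as good as the quantification: the package consumes counts, it does not
produce them.
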