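---
title: "Hidden-addressing fountain codes for DNA storage: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hidden-addressing fountain codes for DNA storage: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligostore)
```

## The model

A DNA storage pool is an unordered multiset of short sequences, each read
back (after synthesis and sequencing) with substitution errors. The codec
implemented here stores a byte payload as follows.

**Grouping.** The payload is split into independent groups of
`segments_per_group = 8` segments of `segment_bits = 36` bits (36 bytes per
group). Independence between groups is what buys random access: any group
can be decoded from its own sequence alone.

**Fountain coding within a group.** A Luby transform produces *droplets*:
a seed drawn from a linear-feedback shift register determines, through a
pinned pseudo-random generator, a degree $d$ from the robust soliton
distribution and a set of $d$ member segments whose XOR is the droplet
payload. The robust soliton is the standard
$\rho(d) + \tau(d)$ normalised by $\beta = \sum_d \rho(d)+\tau(d)$ with
$R = c\,\ln(n/\delta)\sqrt{n}$; at $n = 8$ the spike index
$\lfloor n/R \rfloor$ exceeds $n$, so the $\tau$ tail simply extends
through degree $n$ — `robust_soliton()` handles both regimes.

**Rendering and filtering.** A droplet renders as a 23-nt fragment: the
10-bit seed as 5 nt, then the 36 payload bits as 18 nt, under the 2-bit
map A=00, C=01, G=10, T=11 (used in both directions). The constraint
filter keeps a fragment only if its GC fraction lies in
$[0.45, 0.55]$ *inclusive* and it contains no homopolymer run of three or
more. At 23 nt the GC band admits exactly 11 or 12 G+C bases — a closed
form the tests assert against the filter. Both constraints are applied to
the full fragment including the seed bases, since the seed is synthesized
like any other base.

**Hidden addressing.** Instead of an explicit index field, one of the
group's own surviving droplets is promoted to *index fragment*. Groups are
processed in ascending ordinal; each takes the first pool fragment (in
seed-stream order) that (a) differs from every previously chosen index and
(b) has 10-mer Jaccard coefficient at most 0.2 against each of them. Seven
payload fragments are then chosen greedily such that each strictly
increases the GF(2) rank of the membership matrix (so the eight droplets
provably determine all eight segments) and no fragment junction creates a
homopolymer run. The sequence is the 184-nt concatenation plus two
Reed–Solomon parity bytes over GF($2^8$) rendered as 8 nt: 192 nt total.

**Decoding.** Sequences are RS-corrected, their index fragment is looked up
in the reference-order table, each droplet's equation is re-derived from
its 5-nt seed, and the group is solved by peeling plus Gauss–Jordan
elimination over GF(2). Decoding is order-independent, deduplicates exact
post-correction duplicates, and verifies every solution by re-XORing it
through the droplet equations.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `segments_per_group` | 8 | segments | one sequence carries exactly one group (1 index + 7 payload fragments) |
| `segment_bits` | 36 | bits | forced by the 23-nt fragment minus the 5-nt seed (18 nt × 2 bit) |
| `seed_bits` | 10 | bits | 1023 seeds per group; pools keep roughly 80–200 constraint-clean fragments |
| `fragment_nt` | 23 | nt | the fragment geometry of the reference scheme |
| `gc_lo`, `gc_hi` | 0.45, 0.55 | fraction | melting-temperature stability band for synthesis/sequencing |
| `max_homopolymer` | 2 | bases | runs of ≥ 3 are error-prone in synthesis and sequencing |
| `rs_parity_bytes` | 2 | bytes | 8 nt of parity; corrects any 1 corrupted byte per sequence |
| `soliton_c`, `soliton_delta` | 0.025, 0.001 | – | the customary parameterisation of the fountain scheme this extends |
| `index_k`, `index_jaccard_max` | 10, 0.2 | – | word length matches the dotplot evaluation; 0.2 keeps indices near-disjoint |

Changing geometry fields is validated jointly: `segment_bits` must equal
`2*(fragment_nt - seed_bits/2)` and groups must stay byte-aligned.

## Numerical and procedural choices

- **Pinned generators.** Cross-platform reproducibility of encode/decode
  requires bit-identical randomness, so the seed→plan mapping uses an
  explicitly specified linear congruential generator (multiplier
  1103515245, increment 12345, modulus $2^{31}$, implemented with split
  multiplication so every intermediate stays exact in doubles), and seeds
  are enumerated by a Galois LFSR with a fixed primitive polynomial per
  width ($x^{10}+x^7+1$ at 10 bits; the tests verify the full
  $2^{k}-1$ period). Seed 0 is reserved so the seed field can never be an
  accidental all-A run from an empty state.
- **Degree draw.** Inverse-CDF over the soliton probabilities on the first
  generator draw *after* advancing the state once — seeds are small
  integers, and using the raw seed as a uniform variate would collapse
  every plan to degree 1.
- **Index conflicts re-pick in the later group.** When group $i$ collides
  with an earlier group $j$, group $i$ picks another candidate. Re-opening
  the earlier group's already-accepted choice would invalidate previously
  emitted sequences and can cascade; resolving forward keeps selection a
  single deterministic pass.
- **Relaxation.** If no candidate in a pool meets the Jaccard threshold,
  the non-duplicate candidate minimising the maximum pairwise Jaccard is
  taken, with a warning. On random payloads this path is never exercised.
- **Parity appended, not embedded.** The 184-nt fragment region leaves no
  room for parity inside it, so the 8 parity nt are appended (192-nt
  sequences). The redundancy statistic nevertheless divides by the 184-nt
  region, which is the convention that yields the quoted 26% and
  1.48 bit/nt.
- **Padding is pseudo-random, not zero.** The final group is padded with a
  fixed deterministic byte stream. Zero padding would hand the filter an
  all-A payload rendering for every droplet touching only padding
  segments; a near-empty tail group would then have *no* admissible
  fragment and small payloads could not encode at all. The padding is
  identical on every platform and is discarded at decode by truncating to
  the recorded original length.
- **Population variance** (divide by $N$) is used for GC window
  statistics, matching the closed-form extreme-case bound
  $(0.55-0.45)^2/4 = 0.0025$ the tests assert.
- **Degenerate inputs.** Empty payloads, empty sequences, zero-length
  k-mer sets on both sides of a Jaccard comparison, and windows wider than
  every sequence are all refused with informative errors rather than
  returning NaN.

## What the fixture generator emulates — and what it does not

`fixture_bytes()` produces seeded pseudo-random bytes: the high-entropy
case typical of compressed or encrypted archives, and the regime in which
every group's pool is comfortably large. It does **not** emulate
low-entropy data. A payload containing an entire 36-byte group of (say)
zeros has no constraint-passing fragment and is refused with an
informative error — the scheme has no whitening stage, so in practice
payloads should be compressed or otherwise randomised first. Passing tests
on fixture payloads therefore demonstrate correctness of the codec
machinery, not encodability of arbitrary structured files.

The read simulator is likewise deliberately minimal: uniform read starts,
iid substitutions at 1% (the short-read per-base ballpark), no indels, and
constant quality. Real platform error profiles are position-dependent and
instrument-specific; the simulator is meant for coverage-detection
statistics, not error-model research.

## Known limitations

- **No cross-group erasure protection.** Exactly eight droplets are kept
  per group, so a lost sequence loses its group; the decoder reports the
  missing ordinals. Rateless operation (emitting extra droplets) is
  deliberately out of scope.
- **Double corruption beyond the parity budget.** Two parity bytes give a
  distance-3 code: one corrupted byte per sequence is always corrected,
  but no distance-3 code can *guarantee* detection of every two-byte
  pattern while correcting one. The decoder flags the vast majority
  (invalid locator positions, syndrome re-check, and re-validation of the
  constraint filter on all eight decoded fragments), and the tests pin the
  measured detection rate, but a small residue of silent miscorrections is
  information-theoretically unavoidable at this parity budget.
- **Index screening is greedy**, not globally optimal: it minimises
  nothing, it satisfies a threshold in one pass.

## Problem sizes used by the tests

The test suite exercises payloads from 1 byte to 100 KB (the largest
round-trips a 2845-sequence pool with one random substitution per
sequence), exhaustive single-byte corruption sweeps of whole codewords,
full-period LFSR enumeration at 10 bits, and 3-sigma statistical checks of
the soliton degree frequencies over all 1023 seeds and of the read
simulator's substitution rate over a million simulated bases. These sizes
keep the whole suite comfortably under two minutes on one CPU while still
covering every code path at realistic scale.
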