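---
title: "Quantifying nucleosome protection from Cas9 with tiled libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nucleosome protection from Cas9 with tiled libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nuctile)
```

## The measurement

A nucleosome wraps ~147 bp of DNA around a histone octamer, occluding
the DNA from large machines such as the Cas9:sgRNA complex. To measure
that occlusion at single-base resolution, `nuctile` implements the
computational side of a tiled-library digestion assay: a 20-nt Cas9
target plus its 3-bp NGG PAM is substituted into a Widom 601 backbone at
every base-pair position, the resulting nucleosome library is digested
with Cas9, and the *uncleaved* members are sequenced. A member whose
target was accessible is depleted from the digested pool; a member whose
target was occluded is not.

Positions are indexed by the superhelical location (SHL): bp offset from
the dyad divided by 10, negative upstream, positive downstream, dyad =
SHL 0. The nucleosome edge sits near SHL ±7 (±~73 bp).

Per member N, protection is the control-normalised log2 ratio

$$\mathrm{Protection} = \log_2\!\left(
  \frac{D_N / D_{CON}}{U_N / U_{CON}}\right),$$

with $D$/$U$ the digested/undigested read counts and CON the unmodified
backbone control, which absorbs PCR/library/sequencing variability. Raw
values are then Z-scored against nonspecific background members, per
replicate, before averaging (mean ± SEM) across replicates.

## The library design

`build_library()` assembles:

* **Backbone** — the canonical 147-bp Widom 601 core with deterministic
  flanks to 230 bp; dyad at the core centre (0-based backbone offset
  114). The exact flank sequence is immaterial to the geometry; it is
  generated once from a fixed seed so the backbone is a constant.
* **Tilings** — forward (PAM 3′ of target), reverse (PAM 5′ of target)
  and an 18-nt nontarget motif, substituted (never inserted) at every
  position from first core overlap through the linker. The PAM position
  of a member is the SHL of the *centre* base of its PAM: the centre is
  symmetric and matches the 0.2-SHL granularity at which edge positions
  are discussed (6.6, 7.4, 7.6).
* **Control** — exactly one unmodified backbone member.
* **Background fillers** — seeded random sequences at backbone GC,
  screened to share no 17-mer (either strand) with any target, so they
  are genuinely nonspecific; they define the Z-score moments.

Two deliberate deviations from a naive tiling:

1. **Amplification arms.** Every member of an amplicon pool — fillers
   included — must carry the common terminal primer sequences, so
   fillers keep the backbone's terminal 20 bp and the default tiling
   window stops before the arms. The PAM centre still reaches ~SHL 9,
   well past the edge, so no information about the accessibility
   transition is lost.
2. **Duplicate coincidences.** When the backbone happens to read the
   PAM adjacent to a tiling window, a forward tile and a reverse tile
   three positions apart can yield *identical* full sequences (the
   default design has exactly one such pair). Identical sequences are
   indistinguishable to identity-based read assignment, so the designer
   drops the later duplicate by default and records it; strict erroring
   is available via `on_duplicate = "error"`.

Coordinates are 0-based half-open internally; SHL is a signed decimal.

## Read processing

`process_reads()` re-implements the five pipeline stages with their
standard thresholds, in fixed order:

1. **3′ quality trimming** (q ≥ 30) by the running-partial-sum rule:
   walking in from the 3′ end, cut at the maximum of the accumulated
   `cutoff − q`.
2. **Overlap merging** (≥ 20 nt overlap, ≤ 2 mismatches): the longest
   overlap within the mismatch budget wins; at disagreeing columns the
   higher-quality base is kept, an exact quality tie yields `N` (Phred
   2) — conservative and deterministic.
3. **Primer removal**: terminal matches to each primer within a 10%
   mismatch budget.
4. **Length filter**: keep 174–220 nt inclusive (the removal rules are
   strictly-greater / strictly-less).
5. **Assignment** (≥ 150 columns, ≥ 98.5% identity, best hit only):
   semiglobal alignment — global in the read, member overhangs free —
   with identity = matching columns / aligned columns, internal gaps
   counting as columns and member overhangs excluded. Reads whose best
   identity is achieved by more than one member are *ambiguous* and
   discarded rather than arbitrarily resolved: adjacent tiling members
   differ by a handful of bases, and a biased tie-break would distort
   neighbouring positions. Both thresholds are inclusive.

The semiglobal form matters: with both sequences end-free, a wrong
member can hide its differing tiled window in an unpenalised overhang
and score identity 1.0. Anchoring the read makes the differing window
count.

Every input pair terminates in exactly one status (assigned or one
rejection reason); per-stage counts are returned as a run report, so
totals always reconcile with the input size.

## The digestion simulator

The simulator exists so the full pipeline and the statistics are
testable end to end without external sequencing data, and so parameter
recovery can be demonstrated. It is a deliberately simple stand-in for
biology the assay measures but does not parametrise:

* **Cleavage model** — cleavage probability rises logistically in the
  PAM-centre distance from the dyad, with midpoint `edge_offset`
  (default 73 bp, the edge of a 147-bp wrap), slope `steepness` (1/bp),
  ceiling `max_cleavage`, and a floor `nontarget_cleavage` for members
  with no complementary target. Forward-orientation members get their
  midpoint shifted `orientation_shift = 6` bp outward, encoding the
  observation that a target buried 5′ of its PAM stays protected ~6 bp
  longer than one exposed 3′ of it. sgRNA/target mismatches at the
  PAM-distal bases scale cleavage by penalties (defaults 0.30 at base
  19, 0.60 at base 20), reproducing the protection ordering
  mismatch-19 > mismatch-20 > on-target. The logistic form was chosen
  because it is monotone, two-parameter and recoverable by fitting —
  not as a mechanistic claim.
* **Counts** — undigested counts are multinomial over members;
  digested counts draw an independent multinomial and thin each member
  binomially by its survival probability, so a member's expected
  protection is `log2((1 − p)/(1 − p_control))` exactly.
* **Reads** — mates cover the two member ends with an overlapping
  middle. Per-base substitution errors follow an error profile whose
  qualities encode the per-base error probability. The default
  `"tail"` profile concentrates the error mass in a Phred-2 3′ tail
  (interior Phred 38, error 10^-3.8), emulating the 3′-degradation
  pattern of real Illumina reads — which is precisely what the q30
  trimming stage exists to remove. A `"uniform"` profile (constant
  Phred 40, errors everywhere) is kept as an adversarial layout for
  stress tests; under it the merge and identity thresholds reject reads
  at the rate binomial arithmetic dictates, as they would for real
  reads of uniformly poor quality.
* **MNase fragments** — each simulated molecule is cut at its termini
  and at interior boundaries per a cut-probability profile; fragments
  shorter than `min_len` (default 100 bp, mimicking mono-nucleosome
  size selection) are discarded. A core with zero interior cut
  probability therefore yields a per-bp protection plateau of exactly 1.
* **Determinism** — one top-level seed; per-replicate and per-sample
  streams are derived from it; identical config + seed reproduces
  byte-identical FASTQ.

What passing simulated tests does *not* show: sequence-dependent Cas9
efficacy, nucleosome breathing kinetics, MNase sequence bias, PCR
amplification bias, or indel sequencing errors. The simulator makes no
attempt at these; results on real libraries depend on them.

## MNase footprints

`mnase_track()` turns fragment intervals (0-based half-open) into
per-bp coverage (via `IRanges`) and protection = coverage / member
total reads, both per member. Because the quantity the assay reports
could be read either as a per-bp fraction or as a windowed mean around
an SHL, both are exposed (`mnase_protection()`, `mnase_window_mean()`).
`align_profiles()` joins a Cas9 protection profile and an MNase track
on backbone coordinates with explicit missingness.

## Structural clash scoring

`pair_chains()` aligns the residue sequences of a reference and a
mobile DNA chain (Needleman–Wunsch) and pairs one phosphorus atom per
aligned non-gap residue — robust and exactly one per nucleotide.
`kabsch_superpose()` solves the orthogonal Procrustes problem by SVD
(reflection-guarded), and `count_clashes()` counts atom pairs whose van
der Waals overlap `r_a + r_b − d` reaches 0.6 Å — the common default of
interactive clash detectors — using Bondi radii and a uniform spatial
grid that is exactly equivalent to full pair enumeration. Exclusions
(e.g. the directly bound duplex, or everything beyond a chosen SHL) are
caller-supplied predicates; the module hard-codes no nucleosome
annotation. Published clash counts for real nuclease/nucleosome
structures depend on hydrogen addition, base mutation and minimisation
steps that are out of scope here, so no attempt is made to reproduce
them; the module is tested on synthetic coordinates.

## Numerical and design choices

* **Pseudocount** — default 1 on all four counts of the protection
  ratio (counts of zero occur at depth); pseudocount 0 is honoured for
  exact identities and errors on zero denominators.
* **Z-scores** — population SD of the background members; per
  replicate before averaging.
* **Replicate correlation** — Pearson on log2(count + 1), since counts
  span orders of magnitude.
* **Identity ties** — discarded (ambiguous), never resolved by order.
* **Problem sizes** — the shipped tests run the full design
  (~560 members), count simulations at 10^5 reads per sample (the depth
  at which the edge fit resolves to ±2 bp), and read-level round trips
  on a 20-member toy at ~600 pairs per condition; these sizes give
  stable statistics while keeping the suite quick to run.
* **Edge fitting** — `fit_edge_offset()` is a 1-bp grid search over the
  logistic midpoint, with all other model parameters held at the
  template's values; at 10^5 reads it recovers a generating edge of 73
  bp within ±2 bp.

## Worked example

```{r example, eval = FALSE}
lib <- build_library(n_background = 30, seed = 6)
model <- digestion_model(edge_offset = 73)
cfg <- sim_config(n_reads = 1e5, seed = 19, n_replicates = 3)

counts <- simulate_counts(lib, model, cfg)
prot <- compute_protection(counts, lib)
profile <- profile_by_position(prot, lib, "reverse_target")

fit <- fit_edge_offset(profile, lib, model)
fit$edge_offset   # 73: the generating edge, recovered
```

## Limitations

The package analyses (and simulates) a *defined* reconstituted library
on one strong positioning sequence; it does not model genomic chromatin,
remodelling, or histone variants. The cleavage model is a fitting
device, not a biophysical model. Assignment near the 98.5% identity
threshold is sensitive to the error model of the instrument; the run
report's rejection breakdown is the first thing to inspect on real
data.
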