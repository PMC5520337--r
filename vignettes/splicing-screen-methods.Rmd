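---
title: "Methods: psi quantification and change calling for CE splicing screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: psi quantification and change calling for CE splicing screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psiscreen)
```

## The measurement model

An alternative splicing event (ASE) assayed by RT-PCR with primers in the
flanking constitutive exons yields two amplicons: a longer one from the
isoform that includes the alternative region and a shorter one from the
isoform that excludes it (for the SMN exon 7 cassette, `smn_ase()`, the
54-bp exon makes the inclusion amplicon 330 bp against a 276-bp exclusion
amplicon). Amplicons are kept between 150 and 700 bp, the window in which
microfluidic capillary electrophoresis resolves fragments cleanly.

The instrument reports a fluorescence-versus-migration-time trace per
reaction. `psiscreen` reconstructs quantification from that trace:

1. **Ladder calibration** (`calibrate_ladder()`). Migration time is fitted
   piecewise-linearly against log10(size) through the ladder points — the
   standard approximation to the instrument's proprietary sizing fit. The
   map is exact at the ladder knots and monotone in between; outside the
   ladder range the terminal segment is extended with a warning.
2. **Peak detection and integration** (`detect_peaks()`). A constant
   baseline offset, estimated as the trace's 5th signal percentile, is
   subtracted; peaks are local maxima above `min_height`, candidates closer
   than `min_separation` merge into the taller apex, and each peak is
   integrated by the trapezoid rule between its flanking valleys. This is
   deliberately simpler than instrument software (no sloping-baseline
   model); on clean traces the analytic Gaussian area is recovered well
   within 1%.
3. **Amplicon assignment** (`assign_amplicons()`). Each detected peak is
   considered only for the expected amplicon nearest its called size, and a
   match must lie within `rel_tol` (default 10%) relative size error —
   a tolerance motivated by typical expected-versus-found sizing
   discrepancies on these instruments. Ties on size distance go to the
   larger peak. If one expected size lies inside the other's tolerance
   window the event configuration is rejected as ambiguous rather than
   silently mis-assigned.
4. **Molar correction** (`quantify_molar()`). Intercalating-dye
   fluorescence is mass-proportional, so each peak area is divided by its
   called fragment length to obtain a quantity proportional to molecule
   count.

The percent splicing index is then the molar inclusion percentage

$$\psi = 100 \cdot \frac{m_\mathrm{inc}}{m_\mathrm{inc} + m_\mathrm{exc}},$$

so $\psi$ lives on a 0–100 scale, is invariant to common scaling of the two
amounts, and satisfies $\psi(a,b) + \psi(b,a) = 100$. Peaks beyond the two
catalog amplicons (e.g. an unexpected higher-molecular-weight splice
variant) are excluded from $\psi$ and counted per sample in
`n_extra_peaks`. An ASE with both amplicons absent, or with total molar
amount below `min_total`, is recorded as missing rather than forced to an
extreme $\psi$; a single missing slot is read as a pure isoform only when
the detected slot alone clears the floor.

## Change calling

Knockdown effects are measured as $\Delta\psi$: the $\psi$ of an siRNA
transfection minus the $\psi$ of the mock transfection performed on the
same batch day (`compute_delta_psi()`), so slow day-scale drifts cancel.
Positive $\Delta\psi$ means a shift toward inclusion.

A change is called (`call_change()`) when **both** independent siRNAs shift
$\psi$ by at least 8 percentage points — the threshold is inclusive — in
the same direction. The 8-point value is an assay-calibration constant
carried over from control-reaction variability in prior work with this
readout; this package treats it as a configurable threshold, not something
it re-derives. Two readings of the rule are defensible ("8 points or more"
for the pair, plus sign concordance): the strict reading used by default
requires both siRNAs over threshold; a `lenient` flag implements the
one-siRNA-over-threshold alternative. Strict is the conservative choice and
the one under which discordant off-target responses are doubly penalized.
Pairs with a missing $\Delta\psi$ are "not evaluable": never called, but
still counted in the assayed total.

Screen reports (`summarize_screen()`) store raw fractions and print them
under two conventions seen in screen write-ups: nearest integer with halves
up (28/96 prints as 29%) and truncation to one decimal (11/14 prints as
78.5%). `consensus_distribution()` tabulates in how many cell lines each
ASE changed.

## Clustering and enrichment

`build_dpsi_matrix()` arranges one row per changed ASE and one column per
cell line, each entry the mean of the two per-siRNA $\Delta\psi$ values.
Rows and columns are clustered (`hierarchical_cluster()`) with Euclidean
distance under average or Ward linkage; "ward" follows the classic ward.D
convention — the Lance–Williams Ward update applied to unsquared Euclidean
input distances — stated explicitly so results are reproducible across
ecosystems. Entries from non-evaluable (ASE, cell line) pairs are imputed
as 0 before distances are computed, 0 being the neutral "no shift" value on
the $\Delta\psi$ scale; pairwise-complete distances are available behind
`impute = "pairwise"`. A `k = 2` cut (`cut_k()`) separates consistent
inclusion responders from consistent exclusion responders when such
structure exists.

Changed genes are tested for pathway over-representation
(`test_overrepresentation()`) with a one-sided hypergeometric upper tail
$P(X \ge k)$ and Benjamini–Hochberg adjustment across sets, against GMT
collections (`read_gmt()`). The universe is deliberately the genes
represented in the assayed ASE pool, not the genome — the arrays were not a
random gene sample — and it is gene-level: a gene assayed at two events
counts once. The published analysis this reconstructs used an in-house,
undescribed statistic; the hypergeometric form here is the canonical
over-representation choice and is documented as such rather than claimed to
reproduce any particular printed p-value.

## What the simulator emulates

The synthetic-data module exists so every downstream stage is testable
without instrument data. It emulates:

- two-amplicon events with sizes in 150–700 bp and a resolvable size gap
  (`generate_ase_catalog()`; the gap is required to exceed both 20 bp and
  12% of the longer amplicon so the default 10% matching window is
  unambiguous);
- planted signed effects on the $\psi$ scale (`generate_truth()`): a
  configurable null fraction, direction conserved per ASE across cell
  lines, responses in a random subset of lines, and a small rate of
  discordant siRNA pairs that the concordance rule must veto. Effects are
  planted on $\psi$ (not on molar amounts) because the screen's statistic
  lives on that scale; molar amounts are back-computed from $\psi$ and a
  total-amount parameter;
- knockdown-dose scaling: each cell line has two protein-level knockdown
  fractions (`rbm10_kd_table()`: 0.53–0.93 across five lines), and the
  realized shift of siRNA $s$ is the planted effect times
  $\mathrm{kd}_s / \max(\mathrm{kd})$ within the line, so the stronger
  knockdown expresses the full effect — a quantitative stand-in for the
  observed dose relationship between knockdown depth and splicing shift.
  Knocked-down $\psi$ is clamped to $[0,100]$; `truth_calls()` derives the
  expected calls from the clamped values so zero-noise round trips are
  exact even at saturation;
- measurement noise (`noise_model()`): additive Gaussian baseline noise
  (default sd 8 signal units, putting mid-range peaks near SNR 50),
  multiplicative lognormal sizing error (default sd 0.02, so called sizes
  sit within a few percent of truth, comfortably inside the 10% matching
  window), and lognormal amount noise (default CV 0.05, which keeps null
  $|\Delta\psi|$ several sd below the 8-point threshold). The default
  baseline $\psi$ is uniform on 20–80 and effects are drawn from
  $|N(20, 5)|$ percentage points, comfortably above threshold. No published
  noise model exists for this assay; these are one-time choices of what a
  clean screen on this platform looks like, and the tests state what they
  show under exactly these conditions.

It does **not** model PCR amplification kinetics or bias, three-isoform
events, heteroduplex or primer-dimer artifacts, or between-day drifts
beyond the mock pairing structure. Passing round-trip tests therefore
demonstrate the correctness of the analysis chain, not robustness to every
pathology of real instrument data.

### Mock pairing and the null false-call bound

By default both siRNA transfections of a cell line share a batch day and
hence one mock ("shared"), matching how screens are usually run. For null
calibration the simulator also supports one mock per siRNA day
("separate"). The distinction matters: with a shared mock the two
$\Delta\psi$ values share the mock's noise and are positively correlated,
and the product-of-tails bound on the false-call rate
$P(\mathrm{call}) \le P(|\Delta\psi_1| \ge 8)\,P(|\Delta\psi_2| \ge 8)$
does not hold in general. With independent mocks it holds with a factor-2
margin (the sign-concordance factor). The null-rate validation therefore
runs with separate mocks — the design under which the bound's independence
assumption is true — at a deliberately inflated amount CV of 0.12 so the
tail probabilities are large enough to measure at 1000 replicates.

## Numerical choices and problem sizes

- Trace rendering uses a 0.05-unit time grid over the ladder range with
  Gaussian peaks of sd 0.15 time units; apex times are grid-quantized, so
  zero-noise $\psi$ recovery through the full trace route is exact to about
  0.002 $\psi$ points (the peak-table route is exact to float precision).
- Merging of peaks under `min_separation` keeps the taller apex; the merged
  valley-to-valley area then covers both components.
- Clustering tie-breaks follow the input row order of the agglomeration;
  memberships are invariant to row permutation (leaf order is not).
- Test and validation sizes were chosen to exercise each property at
  convincing scale: the zero-noise round trip runs 200 ASEs by five cell
  lines; the null-rate check runs 1000 replicate screens of 10 ASEs by two
  lines; linkage heights are checked against a Lance–Williams oracle on
  matrices up to 8 rows; hypergeometric p-values against full draw
  enumeration up to a 12-gene universe.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(n_ases = 96, seed = 1, out_dir = "screen_run")
res <- run_pipeline(cfg)
res$summary
head(res$calls[res$calls$changed, ])
```

## Known limitations

- The screen's headline counts depend on the original array measurements,
  which are not redistributable inputs; the package reproduces the
  reporting arithmetic and validates the method on synthetic screens with
  known truth instead.
- $\psi$ uses exactly the two catalog amplicons; events with genuine third
  isoforms need catalog redesign, not post-hoc peak inclusion.
- The hypergeometric universe choice (assayed genes) is a modeling
  decision; enrichment p-values shift with the universe and should be read
  comparatively.
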