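---
title: "In-depth lipid structure annotation from EAD-MS/MS spectra"
author: "eadlipid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-depth lipid structure annotation from EAD-MS/MS spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eadlipid)
```

## The problem

Electron-activated dissociation (EAD) fragments lipid cations along the
acyl chains by charge-remote fragmentation (CRF): every C–C bond cleaves
homolytically and produces three ions — H-loss, radical, and H-gain —
spaced by one hydrogen-atom mass. Because the intensity pattern of this
ion ladder deforms characteristically around a C=C double bond (a
V-shaped valley at the bond, amplified ions two carbons to either side)
and at the acidic methylene protons of polyunsaturated chains (amplified
H-gain), an EAD spectrum carries enough information to localize double
bonds, distinguish *sn*-positional isomers, and place hydroxyl groups —
structure detail that collision-induced dissociation does not give.

`eadlipid` turns that information into annotations: it enumerates a
constrained space of candidate structures for a lipid species, predicts
each candidate's EAD spectrum with a rule-based intensity model,
evaluates subclass/chain/position diagnostic ions under an instrument
noise model, and ranks the candidates by a composite score.

## The CRF fragment model

For a chain of $n$ carbons, the cleavage between carbons $k$ and $k+1$
(counted from the carbonyl or amino carbon, $k$ carbons retained on the
charged fragment) loses the neutral radical

$$\mathrm{C}_{n-k}\,\mathrm{H}_{2(n-k)+1-2d}\,\mathrm{O}_{o},$$

where $d$ is the number of chain double bonds at delta position
$\geq k$ (a bond spanning the cleaved position counts toward the lost
part — this convention is forced by the observed valley masses of the
monounsaturated PC isomer pair, 634.4442 and 662.4755), and $o$ counts
chain hydroxyls beyond carbon $k$. The radical ion is the precursor
minus this loss; H-loss and H-gain sit one hydrogen-atom mass below and
above. All charged-species masses carry the electron-mass correction;
without it the printed reference ions (184.073, 550.350, ...) are
missed at the third decimal.

### Abundance classes and intensities

Relative intensities for (H-loss, radical, H-gain) at each position:

| context                     | triplet            |
|-----------------------------|--------------------|
| saturated / plain position  | 0.5, 1.0, 0.05     |
| at the double bond (valley) | 0.25, 0.5, 0.05    |
| two carbons below the bond  | 4.0, 2.0, 0.05     |
| two carbons above the bond  | 2.0, 4.0, 0.05     |
| PUFA methylene H-gain       | H-gain factor 4.0  |

The two amplified triplets are reported in the literature without an
explicit mapping to the below-bond and above-bond positions. We assign
the H-loss-dominant triplet to $k = p-2$ and the radical-dominant
triplet to $k = p+2$, because the mechanistic account — McLafferty-type
stabilization of the H-loss fragment below the bond, allyl-resonance
stabilization of the radical above it — identifies the *labelled* ion
as the most amplified one at each position. The assignment also makes
the V-shape contrast of the major component survive realistic two-isomer
mixtures, which the opposite mapping does not. The PUFA H-gain
amplification is emitted for chains with three or more double bonds at
every methylene carbon between two methylene-interrupted bonds.

## The candidate space

The engine ranks within known lipid chemistry; it does not discover new
positions. Per chain:

* **Monounsaturated chains** — union of a curated per-chain-length
  position table (e.g. delta-9/11 for 18:1) and the omega-3/6/9 rule
  (delta = carbons − 3/6/9). The curated table is a reconstruction of
  the common mammalian positions drawn in public structure databases;
  it is deliberately user-overridable through a plain-text config so
  other organisms can be targeted. Delta-8 of 18:1 is not in the space.
* **Polyunsaturated chains** — methylene-interrupted n-3/n-6/n-9
  families, i.e. arithmetic series with step 3 whose last bond sits at
  carbons − family; families whose first bond would fall below delta 2
  are omitted. This covers very-long-chain PUFAs (e.g. 32:6 n-3 =
  14,17,20,23,26,29).
* **Sphingoid bases** — subsets of {4, 8, 14}; delta 6 is excluded as
  biologically unusual, and one double bond is fixed at delta 4.
  Hydroxyls default to positions 1,3 (di-) or 1,3,4 (tri-hydroxy).

Candidates are the Cartesian product of sn-slot permutations and
per-chain position sets, capped at 10,000 per query, ordered
deterministically: curated positions before omega-rule positions, then
ascending positions, then name. That ordering is also the tie-break for
equal scores.

## The decision tree and the score

Annotation proceeds species → molecular species → sn/OH → C=C. Class,
chain and position diagnostics are binary: 1 iff every required ion of
the role passes the detection rule. The double-bond component is

$$\text{double bond} = \text{reverse dot product} +
  \text{matched peaks percentage} + \text{V-shape bonus} +
  \text{PUFA H-gain bonus} \le 3,$$

and the total (class + chain + position + double bond) is at most 6; a
total strictly above 4.8 is flagged high-confidence. Candidates missing
any expected amplified ("C=C high") peak are eliminated before scoring,
except that a chain predicting more than five such peaks (three or more
double bonds) may miss exactly one.

Component conventions worth knowing:

* The reverse dot product uses the in-silico spectrum as the library
  template, square-root intensity weighting and no m/z weighting; only
  library peaks enter the computation, so extraneous experimental peaks
  do not dilute it.
* The matched-peaks percentage counts in-silico CRF ions with *any*
  experimental peak within tolerance (plain m/z matching). The stricter
  detection rule (below) applies to diagnostic and presence-check ions,
  where a false "present" would assert structure; spectral fitting is a
  correlation and deliberately uses plain matching — otherwise the
  weakest model ion (which by definition never exceeds twice the
  minimum intensity) could never be "matched" and the score ceiling
  would be unreachable.
* The V-shape bonus (0.5) requires the mean experimental intensity at
  predicted high positions to exceed 1.5 times the mean at the valley
  positions, strictly; the PUFA bonus (0.5) requires the PUFA H-gain
  peak to exceed three times the mean of the other H-gain ions,
  strictly. When no valley peak or no other H-gain ion is matched the
  bonus is 0.

### Diagnostic ions per subclass

Class ions: the phosphocholine head cation at *m/z* 184.073 (PC family
and SM, mandatory), head-group neutral losses for PE/PG/PI/PS and the
sphingolipids, the water loss for Cer and DG, the trimethylamine loss
for acylcarnitines, and the *m/z* 204.123 / 236.149 marker pair for the
betaine lipids, where the dominant member of the pair decides DGTS
(236 > 204) versus DGTA (204 > 236). Chain ions: neutral loss of each
acyl chain for glycerophospho- and glycerolipids, the sphingobase ion
plus the N-acyl neutral loss for sphingolipids, the acylium for
acylcarnitines. Position ions: the neutral loss of *sn1* + CH~2~ from
homolytic glycerol C1–C2 cleavage (practical for protonated PC, PC O-,
PC P-, and for sodiated species), the CH~2~OH loss specific to
sn2-lysolipids (an sn1 lysolipid is diagnosed by that ion's absence),
and radical cleavage ions flanking each sphingoid hydroxyl. Where a
subclass/adduct combination has no practical position rule (e.g.
ammonium-adduct PE, protonated TG), the position score is 0 and the
annotation level is capped accordingly. The exact neutral-loss
compositions outside PC are inferred from the PC arithmetic and
documented here as a reconstruction.

## Noise model and detection rule

On the reference instrument, centroided product-ion peaks below 11
counts appear uniformly over the m/z range ("barcode ions"). The engine
therefore (i) removes peaks with intensity strictly below the threshold,
(ii) defines the minimum peak intensity as the weakest retained peak,
and (iii) calls a diagnostic ion detected only if a peak within the m/z
tolerance is strictly above **both** the threshold and twice the minimum
peak intensity. The 2x comparison uses the minimum computed *after*
barcode filtering. Both constants are `noise_model()` parameters, since
the 11-count floor is instrument-specific. The default MS2 matching
tolerance is 0.025 Da; accumulation uses 0.05 Da bins with per-bin
average intensity, and background subtraction clamps at zero.

## What the synthetic generator emulates

`synth_spectrum()` scales a candidate's in-silico spectrum so that the
base peak is 2000 counts — a high-concentration standard for which
every model ion (the weakest is 1/100 of base) clears the 11-count
floor — and then applies, with the defaults representing routine
acquisition: 20% log-normal intensity jitter, 0.002 Da m/z jitter
(well inside the matching tolerance), 2% per-peak dropout, and 30
barcode peaks at 10 counts. `synth_mixture()` sums component spectra
before one noise pass, reproducing the co-elution overlap in which the
valley of one isomer coincides with the amplified peak of another.
`synth_dilution_series()` scales intensities linearly with
concentration so peaks vanish through the floor, mimicking
level-dependent annotation degradation.

The generator produces model-faithful spectra: it does **not** emulate
CID-type head-group chemistry beyond the diagnostic table, isotope
patterns, chimeric precursor selection, retention-time behaviour, or
intensity deviations of real EAD chemistry from the rule-based model.
Passing round-trip tests therefore demonstrates the internal
consistency and discriminating power of the scoring machinery on
model-distributed data — not accuracy on real instrument data, which
requires reference measurements.

### A genuine identifiability limit

CRF fragment masses depend only on the distance of each double bond
from the methyl (omega) terminus. Two chains of equal double-bond
count can therefore swap their omega offsets — e.g.
18:1(n-3)/22:1(n-6) versus 18:1(n-6)/22:1(n-3) — without changing a
single predicted peak. Such alias pairs are spectrally identical and
tie exactly in the score; the deterministic ordering picks a canonical
representative, and `random_resolved_lipid()` emits truths in that
canonical form so round trips are well defined. The same degeneracy
affects any EAD-based method and is documented here as a limitation,
not resolved by the score.

## Numerical choices

* In-silico peaks closer than 1e-4 Da merge by intensity summation
  (identical chains double their shared ions); experimental duplicates
  merge at 1e-6 Da.
* The low-mass reporting cutoff defaults to m/z 150 (the TOF start
  mass); expected peaks below it are neither generated nor required by
  the presence check.
* All bonus comparisons and the 4.8 confidence threshold are strict
  inequalities.
* Spectral entropy is Shannon entropy of the normalized intensities in
  nats (the base is a parameter). The modified dot product raises
  intensities to the 0.5 scale factor, rescales the base peak to 100,
  applies the 0.1% relative and 50-count absolute cutoffs, and bins at
  1.0 Da with 0.05 Da matching; this algebra is a reconstruction of the
  cited implementation convention.
* MSI processing bins at m/z 0.005 and drift time 0.01 ms, picks
  8-neighborhood local maxima (the reference picker is unspecified),
  matches at 0.01 Da / 20 Å², and builds ion images at 0.01 Da / 5 Å².
  CCS prediction is out of scope; the matcher consumes reference tables
  and an injectable drift-time-to-CCS calibration.

## Problem sizes in the shipped tests

The test suite exercises 216 seeded noise-free round trips (8 per
subclass across the 27 in-depth subclasses), 100 seeded 3:1 two-isomer
mixtures under the default noise model, and a 100x100-pixel MSI phantom
with four planted lipids in two regions — sizes chosen to give stable
pass/fail behaviour at interactive runtimes.

## Known limitations

* Sodium-adduct diagnostics are generated but unvalidated
  (experimental); negative mode is unsupported.
* HBMP, cardiolipin, gangliosides and other classes outside the 27
  in-depth subclasses are not modelled.
* E/Z geometry is parsed and discarded; |z| > 1 and isotopologue fine
  structure are out of scope.
* Quantitative isomer-ratio estimation from calibration curves is not
  part of the engine.
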