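---
title: "Screening virtual metaproteomes for domain-mediated interactors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening virtual metaproteomes for domain-mediated interactors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddiscreen)
```

## The problem

A protein secreted into the gut lumen — the packaged default is human S100B
(UniProt P04271), an EF-hand calcium-binding protein that behaves as a
diffusible cytokine/DAMP — is physically able to interact with any bacterial
protein that carries a domain known to contact one of its own domains.
Whether such bacterial partners exist, and whether their repertoire differs
between a healthy community and an inflamed one, can be asked entirely in
silico: community composition (genus-level metataxonomics) defines a
*virtual metaproteome* — the set of reference-database proteins attributable
to the observed taxa — and structure-derived domain–domain contacts (iPfam
style) define which of those proteins are candidate interactors.

`ddiscreen` implements that screen as a reusable pipeline:

1. **Architecture → partner set.** The query's Pfam domains (from an
   `hmmscan --domtblout` file, retained at independent E-value ≤ 0.01 by
   default) are expanded through a two-column domain–domain interaction
   table. For S100B, the S100 domain (PF01023) has 9 known partners and the
   EF-hand domain (PF00036) has 27; four are shared, so the union holds
   32 unique partner domains. The S100 domain is its own partner
   (homo-multimerisation), so self-edges are legal.
2. **Genus filter → virtual proteome.** An annotated protein table
   (accession, genus, Pfam domains, GO terms, optional localisation) is
   filtered per group by case-insensitive exact genus match. Sequence
   clusters without an unequivocal genus assignment contribute nothing:
   only named genera select proteins.
3. **Screen.** A protein is retained iff it carries ≥ 1 partner domain —
   presence, not copy number. Abundances are carried in the profile objects
   but never weight the screen: the community signature is used
   qualitatively.
4. **Partition.** Retained accessions from the three groups are partitioned
   into the 7 Venn regions; report writers print percentages of the union
   to one decimal.
5. **Per-domain statistics.** For each partner domain, the observed count
   O(d,c) of carrying proteins per group is compared with an expected count
   E(d,c) = f(d)·N(c), where N(c) is the group's proteome size and f(d) a
   background carrying rate, with Pearson's chi-squared test.
6. **GO enrichment.** One-sided Fisher tests on true-path-propagated
   annotations, per namespace, with Benjamini–Hochberg adjustment.

## The expected-count model

No closed definition of "expected by chance" accompanies the reference
occurrence table, but its printed expecteds satisfy
E(d,c)/E(d,c′) ≈ N(c)/N(c′) for every domain row (within printed rounding;
the package's acceptance checks verify all pairwise ratios agree within 2%
for rows with expecteds ≥ 30, below which integer rounding dominates). The
package therefore adopts the one model with that property:

> E(d,c) = f(d) · N(c)

with f(d) estimated either from the pooled groups (default) or from an
external reference count file (`background_mode: external`), mimicking a
whole-database background. Under pooled estimation the row test is the
standard one-row goodness-of-fit with df = k − 1; `df_mode = "k"` is
available for externally fixed expectations. Both conventions classify the
reference anchor rows identically.

Two caveats are worth knowing:

* With pooled estimation and presence/absence data the statistic is mildly
  conservative (deflated by roughly 1 − f(d)); at realistic carrying rates
  (f ≤ 0.05) the null rejection rate at α = 0.01 stays inside the 95%
  binomial band, which the test suite verifies on 20 seeded null
  communities of 3 × 10,000 proteins.
* Calibration statements require genus-disjoint groups. Groups that share
  genera share the very same protein rows, so their counts are not
  independent draws — a property of the study design, not a defect of the
  test.

## Domain triage

Domains are classified before testing: `absent` (never observed in any
group), `near_zero` (total observed below `near_zero_min`, default 10 —
a configuration key, not a constant, since the reference screen excluded
its seven near-zero domains without stating a cutoff), and otherwise tested
and labelled `significant` (p < 0.01), `not_significant` (p > 0.5) or
`intermediate`. Each tested domain also carries a direction profile, the
signs of O − E per group (`"+--"` = over-represented in the first group,
under-represented in the others). When re-classifying an already-triaged
published table, set `near_zero_min = 0`: its rows passed triage upstream,
and the default threshold would demote rows like the myosin-head one
(total O = 6).

One packaged reference row (PF13405, O 60/56/58 vs E 55/50/49) computes to
p ≈ 0.24 — between the significant and not-significant bands — and is
labelled `intermediate` rather than forced into either; its direction
profile is also all-positive, which is why direction summaries count two
"+++" rows while only the significant one (PF00149) supports a claim.

## GO enrichment choices

Enrichment is the "classic" Fisher scheme: annotations are closed upward
under `is_a` (true-path rule) and every term is tested independently;
decorrelating algorithms (weight/elim) are deliberately not replicated.
The universe is, per namespace, the group's virtual proteome restricted to
proteins with ≥ 1 propagated annotation in that namespace (switchable to
the screened set). BH adjustment is applied within each namespace. Because
the thresholds q ≤ 0.01 and raw p < 0.01 are both in circulation for this
kind of screen, the output carries both flags (`significant_q`,
`significant_p`) and neither filters rows.

The OBO reader covers the 1.2 subset the pipeline needs (`[Term]`, `id`,
`name`, `namespace`, `is_a`, `is_obsolete`), certifies acyclicity by
topological sort (reporting one offending cycle otherwise), and refuses
annotations to obsolete terms.

## The synthetic community generator

`simulate_metaproteome()` produces, from one integer seed, every input the
pipeline consumes plus a ground-truth record. Its defaults are the study
conditions the screen was designed around:

* **Genus structure.** 74 genera: 15 common to all groups, 13 CT-only,
  9 CD-only, 8 UC-only, and pairwise-only overlaps CT∩CD = 2, CT∩UC = 2,
  CD∩UC = 25 — the unique solution of the per-group totals (CT 32, CD 51,
  UC 50) given the common/exclusive counts.
* **Domain model.** Independent Bernoulli per catalogue domain, so
  multi-domain proteins arise naturally and presence-based counting is
  exact. The default catalogue holds the 32 partner domains in three tiers
  (nine testable, seven near-zero at 2×10⁻⁴, sixteen absent at rate 0 —
  mirroring the reference screen's triage, with testable rates scaled so a
  community of a few thousand proteins per group is informative) plus 20
  non-partner decoy domains so screening retains a proper subset.
* **Group effects.** A (domain, group, factor) effect multiplies the rate
  for genera of that group; genera shared between groups take the mean of
  their groups' factors. Effects are therefore exact for group-exclusive
  genera, which is how recovery experiments are configured.
* **GO.** A random single-rooted DAG per namespace (15 terms, ≤ 2 parents
  per term by default, one obsolete decoy term); annotations are drawn on
  leaves only and closed upward downstream, so true-path consistency is
  guaranteed by construction. Planted enrichment multiplies a leaf's
  probability for screened interactors of one group, creating
  study-vs-universe enrichment with recorded truth.
* **Truth record.** The generator records what it actually sampled
  (realised per-group domain counts, interactor counts, planted-term
  counts), not merely its parameters, so tests can demand exact agreement.

What the generator does **not** emulate: read-level 16S noise, abundance
dynamics, phylogenetic correlation between genera, domain co-occurrence
structure, or annotation bias. Passing tests therefore demonstrate
correctness of the screen's logic and statistics under its own model, not
robustness to those real-data features.

## Numerical and testing choices

* Fisher p-values are hypergeometric upper tails; the suite checks them
  against brute-force enumeration over all 2×2 tables with margins up to
  25 (exact to 10⁻¹⁰).
* The chi-squared p is validated against a 100,000-draw multinomial
  Monte-Carlo null on rows with expected counts of 200–1000 — small next
  to the real screen's tens of thousands, yet large enough that the
  continuous-tail approximation error sits inside the Monte-Carlo standard
  error; the null's discreteness is handled with the standard mid-p
  convention. At expected counts in the tens the approximation error
  itself exceeds 3 Monte-Carlo SEs, so no implementation could meet that
  bar there.
* Recovery experiments use 100 seeds each: a 3× rate effect on a domain
  with f = 0.01 in one of three genus-disjoint groups of 10,000 proteins
  (detected at p < 0.01 with the "+--" profile), and a 3× leaf-term
  enrichment in groups of 2,000 (detected at q ≤ 0.01). Problem sizes are
  the package's chosen simulation-study design and complete in a few
  minutes on one core.
* All writers sort lexicographically and the pipeline keeps no hidden
  state: `run_all()` output equals the composition of the stage functions,
  and reruns are byte-identical apart from the manifest's timestamp line.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_metaproteome(simulation_config(seed = 7))
paths <- write_simulation(sim, tempfile())

cfg <- read_pipeline_config(overrides = list(
  query_domains = "PF99001",
  interactions = unname(paths[["interactions"]]),
  proteins = unname(paths[["proteins"]]),
  taxa = unname(paths[["taxa"]]),
  obo = unname(paths[["obo"]]),
  out_dir = tempfile()))
res <- run_all(cfg)
res$partition
head(res$domain_results)
```

## Known limitations

* The screen is qualitative: a genus present at trace abundance selects its
  proteins exactly as a dominant genus does.
* Genus-level taxonomy is the finest filter; strain-level proteome
  differences are invisible.
* The interaction map is a file input; no live database client is included,
  so results are only as current as the supplied table.
* Chi-squared classes are reported without multiple-testing correction
  across domains (the partner set is small and fixed); GO enrichment, with
  hundreds of terms, is BH-adjusted.
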