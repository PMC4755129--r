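---
title: "Methods: regional disaggregation of Red List and protected-area indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional disaggregation of Red List and protected-area indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rlregions)
```

# The problem

Intergovernmental environmental assessments (GEO, IPBES) report on
biodiversity per policy region and subregion, but the underlying knowledge
products — Red List assessments, important-site inventories (IBAs, AZE
sites), protected-area databases — are global. `rlregions` implements the
disaggregation machinery that turns those global products into per-unit
statistics: species richness and endemism with threatened-fraction bounds,
spatially downscaled Red List Index (RLI) contributions, dissolved-polygon
coverage of sites and protected areas, and Monte Carlo trend estimation of
the proportion of sites wholly protected when establishment dates are
partly missing.

The licensed global datasets themselves cannot ship with a package, so a
synthetic-world generator with recorded ground truth stands in for them;
every stage of the pipeline is validated against that truth or against an
independent oracle.

# Region schemes

A scheme maps ISO3 codes to `(region, subregion)`; subregions partition
regions, and non-country *special units* ("ABNJ" for the high seas, and
"Excluded" for the Antarctic under IPBES) act as their own region. Two
transcribed regionalizations ship as fixtures (`builtin_scheme("GEO")`,
`builtin_scheme("IPBES")`, 206 countries each). Scheme membership is
purely table-driven — the loader accepts any ISO3-like token and encodes
no geography — so user-defined schemes work unchanged. Labels are trimmed
but case-preserved; duplicate codes and subregions spanning two regions
are validation errors.

# Species metrics

A species **occurs** in a unit if it has at least one occurrence record in
a member country after dropping records of vagrants, uncertain origin and
introduced populations; it is **endemic** if the filtered records place it
in no country outside the unit. Two consequences of taking "countries"
literally:

* occurrence records against ABNJ (not a country) never break endemism to
  a country-based unit, and endemism *to* ABNJ is rejected with a warning
  — no assessed species occurs only on the high seas;
* reintroduced populations count as native (only the three classes above
  are excluded), and unknown origin tokens default to native with a
  logged warning, since only those three classes can change a result.

The threatened fraction of a species set is bracketed by three
percentages over the category counts (threatened = CR + EN + VU, `EX`
excluded from every denominator, `EW` retained, `NE` outside
`total_assessed` entirely):

$$
\mathrm{lower} = \frac{CR+EN+VU}{N-EX},\qquad
\mathrm{best} = \frac{CR+EN+VU}{N-EX-DD},\qquad
\mathrm{upper} = \frac{CR+EN+VU+DD}{N-EX},
$$

corresponding to Data Deficient species being none / proportionally /
all threatened. Zero denominators yield `NA` ("not applicable"), never an
error; output files round percentages to one decimal while full precision
is kept internally.

```{r bounds}
threat_bounds(c(CR = 1, EN = 1, VU = 1, DD = 1, LC = 5, EX = 1))
```

# Downscaled Red List Index contributions

Only *genuine* category changes — real improvement or deterioration, not
revised knowledge or taxonomy — move the RLI. Categories are ranked
LC (0) < NT < VU < EN < CR (4), with EW, EX and CR flagged Possibly
Extinct (in the Wild) jointly at 5; DD and NE are unrankable and changes
touching them are dropped with a warning. A recorded multi-category change
decomposes into one ±1 event per single-category step (−1 per step of
increasing risk), so a genuine VU→CR change contributes −2.

The contribution of unit $u$ for a taxon over an assessment period of $T$
years is

$$ v(u) = \frac{1}{T}\sum_s n_s\, f_{s,u}, $$

with $n_s$ the species' net signed steps and $f_{s,u}$ the fraction of its
range in $u$. Because per-species fractions must sum to 1 over a level's
units (tolerance $10^{-6}$; violations are errors, never silently
renormalized), the unit values sum exactly to the global net annual
change — `additivity_check()` verifies the identity to $10^{-9}$. Netting
a species' steps before weighting or weighting each step independently is
mathematically equivalent under this linear form. Assessment periods are a
required input (`assessment_period(start, end)`); the taxon-specific
periods used for real data are not encoded in the package.

# Geometry

Every coverage statistic reduces to areas of unions and intersections of
polygons in an equal-area plane. The package computes these on the
*rectilinear* class — axis-aligned rectangles and rectilinear polygons
(holes included) — exactly, via a slab sweep over compressed coordinates
(`rectset`, `dissolve`, `rs_intersect`, `rs_area`). On this class there is
no tolerance and no approximation: dissolving first means overlapping
sites or protected areas are never double counted, and the union area
never exceeds the sum of parts by construction. Rectilinear GeoJSON layers
convert losslessly; non-rectilinear rings are rejected with a clear error.
Real-world curvilinear boundaries are out of scope for this engine — the
synthetic world is deliberately rectilinear so that the geometric claims
of the pipeline are testable exactly, with a 1000×1000 rasterization
oracle providing an independent check in the test suite.

Two distinct unit-assignment rules are used, intentionally:

* **counts and mean sizes** assign each site to the single unit containing
  its representative interior point, so "number of sites" stays an
  integer even for boundary-straddling sites;
* **percentage coverage** always uses the true geometric intersection of
  the dissolved layer with the unit.

Protected areas without polygon geometry (point-only records) are excluded
from coverage with a logged count. Land and sea are handled separately:
terrestrial protected areas are intersected with unit land, marine with
unit sea; a unit without sea reports `NA` for sea coverage.

# Protection trends under missing establishment dates

The indicator is, per year $y$, the percentage of sites whose area is
covered to at least a threshold by the union of protected areas
established by $y$. "Wholly covered" is not a quantified notion in the
source material; the default threshold is **0.98** of site area, chosen to
tolerate boundary-digitization slivers, with `threshold = 1` available as
strict mode. This is the module's most consequential free parameter and is
recorded in every output file's metadata line.

Undated protected areas get years imputed uniformly with replacement from
the dated protected areas of the same country and realm; countries with
fewer than five dated records of a realm fall back to the realm-wide pool
(terrestrial and marine pools are kept separate throughout; the fallback
pool is global per realm, not per region). Repeating the assignment
`n_reps` times (default 1000) yields per-year 2.5th/50th/97.5th empirical
percentiles (linear interpolation), i.e. a median with a 95% envelope.
Implementation notes:

* per-site protected-area overlap geometry is cached once; clipping
  distributes over union, so per-replicate coverage only unions the cached
  clips of the active subset — an exactness-preserving optimization;
* within a replicate, a site's first-cover year is found by accumulating
  clips in year order, so a series costs one pass per site;
* sites overlapped by no undated protected area have a fixed first-cover
  year and are computed once, outside the replicate loop;
* all series — every replicate, the median and both envelope bounds — are
  non-decreasing in year (degazettement is out of scope), and identical
  seed plus inputs reproduce the result exactly.

Units with no sites of a type, and ABNJ, are dropped from trend products
rather than reported as zeros, matching the dropped-unit convention of the
published regional tables.

# The synthetic world

`world_spec()` describes a planar world: a row of unit-square country
cells (lower half land, upper half sea), a sea-only ABNJ strip, and two
regionalizations built from contiguous country blocks (default 4×2 and
3×2 region×subregion layouts over 24 countries — two schemes so the
multi-scheme file products are exercised like the GEO/IPBES pair).
Defaults are fixed once, as the study conditions:

* 3 taxonomic groups × 60 species; category mixture
  (EX 2%, EW 1%, CR 6%, EN 8%, VU 10%, NT 12%, DD 12%, LC 49%) — a
  Red-List-like mixture with substantial DD mass so the bounds machinery
  is exercised;
* 75% of species confined to a single country, multi-country ranges as
  consecutive runs (mean 3 countries), 5% adding an ABNJ occurrence:
  single-region endemism dominates, which is the structural property the
  RLI downscaling relies on;
* 15% of species get one extra record of an excluded origin outside their
  true range — noise that correct filtering must remove exactly;
* genuine changes as a forward walk on the category ladder from the
  initial category (rate 0.25 per species, 75% deterioration bias,
  reflecting ladder ends); the walk's endpoint *is* the species' current
  category, so recorded pairs are always valid single-category moves and
  deterioration dominance shows up as a negative global trend;
* 40 IBAs, 15 AZE sites, 120 protected areas; 40% of protected areas
  duplicate a site footprint, 30% cover site halves (so some sites are
  completed only by unions), 30% are background rectangles; establishment
  years uniform 1960–2010;
* undated fractions 14.3% terrestrial / 8.6% marine — the documented
  shares in the real protected-area database;
* assessment period 1993–2013 (20 years; real per-taxon periods are not
  printed in the source material, so a representative two-decade window
  is used).

Each component draws from its own RNG substream derived from the master
seed, so adding a component never shifts another's draws; a fixed seed
regenerates the world byte-identically. Ground truth is enumerated with
plain nested loops over the generator's own bookkeeping (true ranges,
true steps, true years) — independent of the pipeline's filtering and
aggregation code.

What the generator does **not** emulate: real biogeography and
coastlines, taxonomy, geodesic areas, curvilinear boundaries,
degazettement, site-establishment dynamics, and spatial correlation
between threat and protection. Passing tests therefore demonstrate the
correctness of the disaggregation machinery, not properties of any real
dataset.

# Test problem sizes

The suite validates: the three bound formulas on 10,000 random count
vectors plus hand-evaluated fixtures; tabulation against a nested-loop
brute-force oracle on 20 random worlds of up to 50 countries × 500
species; the RLI decomposition identity on 30 random event/fraction sets;
coverage percentages against a 1000×1000 rasterization oracle on 20
random layouts; and the imputation envelope on 50 generator seeds at 200
replicates with 15% masked years (containment of the truth series in ≥90%
of year-points), alongside exactness (zero envelope width with nothing
undated) and boundedness (every replicate between the pool-extreme
series). The end-to-end run writes all fourteen product files
byte-identically under a fixed seed.

# Known limitations

* The geometry engine is exact only on rectilinear inputs; projected
  real-world layers would need pre-processing outside this package.
* Point-only protected areas are excluded from coverage (no
  buffered-circle mode).
* The global RLI time series itself (the 0–1 index) is not computed;
  range fractions are inputs, not derived from range maps.
* IUCN management-category breakdowns, governance types and management
  effectiveness are out of scope.
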