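---
title: "Modelling chemical immunotoxicity with a desk-scale agent-based immune simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling chemical immunotoxicity with a desk-scale agent-based immune simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunotox)
```

## The model

`immunotox` simulates the humoral and cellular response of a simplified human
immune system as an agent-based model, and layers on top of it a chemical
mechanism-of-action (MoA) map describing how a circulating immunotoxicant
(the shipped map targets PFOA/PFOS) suppresses parts of that machinery. The
package exists to run *in silico* trials: cohorts of virtual patients are
vaccinated or challenged under different serum-exposure levels, and the
resulting antibody endpoints are compared across arms.

### Shape space and affinity

Receptor specificity is a fixed-length binary string (default `l = 12` bits,
a repertoire of $2^{12}$ clonotypes). Every receptor, epitope, peptide and
MHC molecule lives in this shape space. Complementarity between two strings
is their Hamming distance $d$ — differing bits are complementary — and a
specific interaction succeeds as a Bernoulli event with probability

$$p(d) = \begin{cases} 0 & d < d_{\min} \\ p_{\max}\,\alpha^{\,l-d} & d \ge d_{\min}, \end{cases}$$

a thresholded exponential chosen because it is monotone in complementarity
and has a single sharpness parameter. Defaults: $d_{\min} = 8$, $\alpha =
0.7$, $p_{\max} = 1$. With these values roughly one receptor in five can
bind a random epitope at all, which at the default pool sizes gives each
patient on the order of twenty responding B clones — enough that response
magnitudes average over clones instead of hinging on one lucky founder.
MHC–peptide binding uses the same rule with a separate, much lower threshold
(`mhcAffinity$dMin = 4`), reflecting the far lower specificity of peptide
presentation compared with receptor recognition; with the default haplotype
pool this keeps the fraction of patients who cannot present a vaccine
peptide below one percent. Memory lymphocytes bind with a one-bit-relaxed
threshold (their lower activation barrier).

Aspecific (TLR–PAMP) recognition bypasses the shape space: any
PAMP-carrying antigen is taken up by monocytes, macrophages and dendritic
cells with a fixed probability $p' = 0.4$ per encounter.

### Space, compartments, time

The secondary lymphoid organ is a 2-D hexagonal lattice (default $8 \times
8$, periodic boundaries; a 3-D cubic lattice and hard walls are available).
All interactions are strictly local to one lattice site in one time step.
Agents perform a Brownian walk — every step, each cell moves to one of its
six neighbours with equal probability. Cytokines are per-site concentration
fields: each step a site keeps $1-D$ of its mass and sends $D/6$ to each
neighbour, then decays with a fixed half-life. Antigen boluses are discrete
units that diffuse like agents and decay by binomial thinning.

Bone marrow and thymus are modelled as separate compartments without their
own interaction dynamics: haematopoiesis creates cells in the marrow, T
lineage cells pass through the thymus for selection, and matured cells
emigrate into the secondary organ. Time advances in 8-hour steps (3 steps
per day), so "day 20" is step 60.

### Homeostasis and thymic education

Each lineage's naive-cell target count follows an exact-discretization
Ornstein–Uhlenbeck process
$x' = \mu + (x-\mu)e^{-\theta} + \sigma\sqrt{(1-e^{-2\theta})/(2\theta)}\,\varepsilon$,
clamped at zero and rounded; deficits against the target are filled with
fresh naive cells (uniform new receptors), surpluses remove the oldest naive
cells first. New T cells undergo two-stage thymic education: positive
selection keeps a receptor only if its best complementarity to any MHC
string of its restricting class reaches $\theta_{pos} = 4$; negative
selection deletes it if its complementarity to any MHC–self-peptide complex
reaches $\theta_{neg} = 10$. Complexes are the bitwise XOR of the MHC and
peptide strings — a fixed, length-preserving combiner. Survivors emigrate at
rate 0.5 per step.

### The response machinery

The per-step interaction phase visits every active site and runs a
randomized schedule: interaction rules are permuted, the actor list within
each rule is permuted, each actor is compared against the rule's partners
until its first success, and consumed partners are gone for all later
attempts. The engine's rule set covers: aspecific APC uptake with endocytic
(class II) and, on failure, cytosolic (class I) processing; specific B-cell
antigen capture; T-helper priming by presenting APCs; T help to presenting B
cells; and cytotoxic T priming by cross-presenting DCs.

A helped B cell becomes a blast and divides every 8-hour step (a realistic
blast division time that also keeps clone sizes reproducible) until the
Hayflick limit of 6 divisions; each daughter independently becomes a plasma
cell (25%), a memory cell (10%) or continues dividing, and may hypermutate
by one receptor bit (30%). Plasma-cell isotype is decided at differentiation
by the local IL-4 concentration (IgM below the threshold, IgG at or above;
a slow late IgG→IgA switch adds an IgA tail). Plasma cells secrete one
titre unit per step into a serum immunoglobulin pool tracked per clonotype
(capped at 256 clonotypes; the least abundant overflow into a bulk pool that
keeps isotype but not specificity). A presenting B cell that waits more than
5 days without any co-stimulatory APC at its site becomes anergic.
Cytokine secretion is a per-(type, state) rate table; the defaults encode the
producer map used throughout the package (activated Th2 → IL-4/IL-6/IL-10,
Th1 → IL-2/IFN-γ, macrophages → IL-6/TNF-α/IL-1/IL-12, DCs →
IL-12/IL-8/IL-18, NK → IFN-γ, Tregs → IL-10/TGF-β, mast cells → IL-4).

None of the per-type half-lives, secretion rates or pool sizes are
published for this class of simulator at desk scale; the shipped values are
order-of-magnitude choices documented in `inst/extdata/default_params.yaml`
and are deliberately small (hundreds of agents) so that a full trial arm
runs in minutes on one CPU.

### The immunotoxicity layer

Serum concentration is an exogenous step-constant profile (no
pharmacokinetics — uptake, distribution and clearance are out of scope by
design). Each MoA entry suppresses one engine rate by a Hill/Emax factor
$f(C) = 1 - I_{\max} C^h / (C^h + EC_{50}^h)$. The shipped PFOA/PFOS map
suppresses secretion of IL-6, TNF-α, IL-4, IL-8, IL-18, IFN-γ and IL-10,
the B-cell homeostatic mean (spleen atrophy), thymic output (thymus
atrophy), and mast-cell growth. Because no quantitative ordering of the
seven cytokine effects is available, all entries share one $I_{\max}$; PFOS
shares the map with a single potency multiplier (1.5) on concentration.
Suppressing IL-4 lowers the IgG fraction of the response; suppressing the
B-pool mean lowers the number of responding clones; both act monotonically
on the IgG endpoint.

The shared $I_{\max}$ is the one free parameter and is calibrated: the
shipped `scripts/calibrate_defaults.R` bisects it until a paired-cohort
child diphtheria trial reproduces a −39% change in the mean anti-diphtheria
IgG endpoint per 2-fold increase in exposure (reference arm at 10 ng/ml).
$EC_{50}$ is fixed at 8 ng/ml — the same order as the 10 ng/ml serum level
of the exposure study, placing both that study and the 10→20 ng/ml
calibration contrast on the steep part of the Hill curve so the target
effect is attainable within $I_{\max} \in [0,1]$ — and $h = 1$ in the
absence of any shape information.

### Virtual patients and trials

A virtual patient is the 26-entry personalization vector (exposure, cell
pools, cytokine baselines, baseline IgG, vitamin D, age, BMI, and the
disease-model/vaccination/MoA references) plus HLA class I and II haplotype
pairs drawn uniformly from a pool of 16 synthetic bit-string haplotypes (no
real allele frequencies are claimed), and a private seed. The printed table
this vector mirrors lists IL-10 twice (rows 10 and 20); the schema keeps
both entries aliased to one value to preserve the 26-entry count, and its
first row is a single exposure field accepting either PFOA or PFOS.
Marginals are truncated normals; BMI is sampled conditionally on age, and
the adult naive T pools decline with age (waning thymic output). A child
spec (ages 4–6) scales lineage pools by 0.85. Each patient additionally
carries a lognormally distributed isotype-switch sensitivity (their own
IL-4 threshold, drawn under the patient seed and therefore shared across
paired arms): without this heterogeneity the whole cohort's class-switch
decisions flip coherently as exposure scales the IL-4 field, producing
implausible population-level jumps in the IgG endpoint. Cohort generation splits a
master seed into per-patient seeds, so cohorts are byte-reproducible and
paired arms share patients exactly.

Three study designs ship with the package: the adult exposure study (two
cohorts of 100, ages 18–60, 10 ng/ml versus unexposed, bacterial challenges
at day 20 and day 100), the child two-dose diphtheria study (doses at day 10
and 38, endpoint 60 days after the second dose) used for calibration and
the 2-fold contrast, and the influenza study (411 patients, per-patient
exposure, single vaccination, quartile analysis). Vaccines are
PAMP-positive antigen boluses (adjuvant effect); bacterial challenges are
boluses as well — pathogen replication is not modelled, which is the main
respect in which "challenge" underestimates a real infection.

### Common random numbers

All exposed-versus-unexposed contrasts use common random numbers. Beyond
sharing patient seeds, the engine keys every stochastic decision to a
persistent entity identity: each agent and antigen unit carries a uid
(daughters derive theirs from the parent's), and movement, survival,
division fates, hypermutation, emigration and decay draw from a
deterministic hash of (seed, uid, step, purpose). Newly created cells take
their receptors from a per-lineage counter-keyed sequence, so paired arms
see the same repertoire even when exposure changes how many cells are
created. Paired arms therefore share identical noise except where the
exposure genuinely flips an outcome, which reduces the variance of
between-arm effect estimates by roughly an order of magnitude and makes the
calibration objective a near-continuous function of $I_{\max}$.

### Analytics

Endpoint analytics are deliberately simple: pointwise population mean/SD
trajectories; contiguous exposure quartiles (sorted by exposure, remainder
to the lowest quartiles, ties broken by patient id); Spearman rank
correlation for exposure–response (robust to the arbitrary titre scale),
with a seeded 2000-resample percentile bootstrap CI; the fold-change effect
$100 \cdot (\bar{x}_{2C} - \bar{x}_{C}) / \bar{x}_{C}$ with the same
bootstrap; bisection calibration of the shared $I_{\max}$; and bisection
benchmark-dose search for the serum concentration producing a predetermined
percent reduction (e.g. 5% or 10%) in the mean antibody endpoint.

## What the synthetic data do and do not show

The cohort generator emulates realistic marginal spreads, a plausible
age–BMI dependency, and HLA diversity, but not real allele frequencies, real
PFAS exposure distributions, co-morbidities, or assay noise. The engine
reproduces the qualitative signatures the package is tested on — primary
versus secondary (memory) response, dose-monotone suppression, exposed
versus unexposed separation — at desk scale (hundreds of agents, a $2^{12}$
shape space). Passing tests therefore demonstrate internal consistency of
the mechanism and calibration machinery, not predictive accuracy for any
real population; the calibrated map reproduces one published effect size by
construction, and everything downstream of it (e.g. benchmark doses) is
conditional on that anchor.

## Numerical and design choices

* **Time step** 8 hours, 3 per day; "day 20" = step 60.
* **Lattice** $8 \times 8$ hexagonal periodic for the engine default —
  large enough that local crowding matters, small enough for minute-scale
  trial arms. The lattice constructor's own default is $16 \times 16$.
  Periodic hexagonal lattices require an even side (odd-r offset stencil
  parity); the constructor enforces this.
* **Geometric survival** parameterized by half-life (removal probability
  $1 - 2^{-1/t_{1/2}}$): memoryless, so no per-agent age bookkeeping is
  needed for death.
* **Complex combiner** XOR, fixed; any deterministic length-preserving
  combiner would do, but it must be frozen for thymic education and T help
  to agree.
* **Hard-wall diffusion** redistributes the outgoing fraction among the
  existing neighbours (no mass loss at walls); hard-wall agent moves re-draw
  among valid directions (no sticking bias).
* **Phase order** (frozen): exposure update → haematopoiesis → thymic
  education/emigration → per-site interactions → maturation and clonal
  expansion → secretion → field diffusion/decay → agent diffusion →
  lifecycle. The clock advances once per cycle.
* **Degenerate inputs**: empty repertoires, empty schedules, zero doses and
  zero-concentration exposures are all identities; a zero-concentration
  exposure is bit-identical to no exposure.
* **Problem sizes in the test-suite** were chosen to keep the full suite in
  the tens of minutes on one CPU: paired-seed property checks use 16–20
  seeds, the 2-fold contrast uses 50 patients per arm, and calibration
  recovery uses 12 per arm with a shortened sampling tail.

## Known limitations

* The desk-scale endpoint is stochastic: even under common random numbers a
  per-2-fold effect estimated from 50-patient arms carries a few percentage
  points of Monte-Carlo uncertainty, and the effect-versus-$I_{\max}$ curve
  is a dense staircase rather than a smooth function. Inverting it much
  below $\pm 0.05$ in $I_{\max}$ requires cohort sizes that defeat the
  purpose of a desk-scale tool.
* At high $I_{\max}$ the relative 2-fold effect is non-monotone (both arms'
  responses collapse and the ratio compresses), so calibration targets
  should sit on the monotone branch; `calibrateMoa` accepts an upper search
  bound for this reason.
* Antibodies are tracked as a well-mixed serum pool, not a spatial field:
  they are read out as titres and play no spatial role in any implemented
  interaction.
* No pharmacokinetics, no pathogen replication, no germinal-centre anatomy,
  no intracellular signalling; "stimulation" of macrophages by IL-10 loss
  is represented only as removal of inhibition.
* Whether cells may also stay in place during a movement step is not
  specified by the modelling tradition this follows; here every cell moves
  every step.

## A worked run

```{r, eval = FALSE}
design <- studyDesign("diphtheria_child")
cohort <- generateCohort(50, design$spec, masterSeed = 1)
moa <- defaultMoAMap()

ref <- runTrial(cohort, design$schedule, constantExposure(10),
                moa = moa, poolScale = design$spec@poolScale)
x2  <- runTrial(cohort, design$schedule, constantExposure(20),
                moa = moa, poolScale = design$spec@poolScale)
foldChangeEffect(ref@endpoints$endpoint_IgG, x2@endpoints$endpoint_IgG)
```

See the README for the command-line entry points and for reproducing the
headline numbers with `scripts/acceptance.R`.
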