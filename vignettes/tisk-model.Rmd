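---
title: "The TISK model: diphone string kernels, interactive activation, and lexical feedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The TISK model: diphone string kernels, interactive activation, and lexical feedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

```{r}
library(tisk)
```

## The problem: recognizing words in a phoneme stream

Spoken words unfold in time. A recognizer that simply pools evidence for
phonemes cannot work: /kat/, /tak/ and /akt/ (CAT, TACK, ACT) contain the
same phonemes, and /sol/ vs /solo/ (SOUL, SOLO) differ only in a repeated
element. Classic interactive-activation accounts solve this by duplicating
every phoneme and word node at every time step, which works but requires
enormous numbers of nodes and connections at realistic scale.

TISK (the time-invariant string kernel model) takes a different route. Each
word is coded by its **ordered open diphones**: every pair of phonemes
(x, y) such that some occurrence of x precedes some occurrence of y,
adjacent or not. For a word of n phonemes there are n(n-1)/2 such pairs,
counted with multiplicity:

```{r}
open_diphones("solo")
#> so sl ol oo lo  (with so = 2)
```

The diphone count matrix is a **string kernel**: a fixed-dimension
representation (phoneme x phoneme) in which words of any length can be
compared by ordinary vector operations. Open-diphone codes are
order-sensitive and repetition-sensitive, which is exactly what the phoneme
pool lacked. (Note one bookkeeping subtlety: the code of SOLO contains
*six* pairs — so, so, sl, ol, oo and lo — since every ordered index pair
counts.)

The mapping from time-specific inputs to time-invariant diphones is graded
rather than flat. An ordered pair at gap g (g = 0 for adjacent) contributes
`gamma^g`, and the reversed pair contributes the same amount scaled by
`rho < 1`:

```{r}
graded_weights("ba", gamma = 0.5, rho = 0.1)
#> ba = 1.0, ab = 0.1
```

So /st/ is activated more by STOP than by SPOT, and /sa/ more by *sock*
than *stock* than *strong*. The published account of this "symmetry
network" defers its exact functional form to earlier work; the
`gamma^gap`/`rho` parameterization used here is this package's stand-in for
it, chosen to satisfy the ordinal contract (ordered >> reversed, weight
strictly decreasing in gap, adjacent pair = 1). Both constants are exposed
in `tisk_params()` (defaults `gamma = 0.5`, `rho = 0.1`).

## Architecture and dynamics

`build_network()` wires three layers over a phoneme inventory (default: 14
symbols plus silence):

1. **Time-specific input layer** — one node per (phoneme, slot); 10 slots,
   with each successive phoneme arriving every `cycles_per_phoneme = 10`
   cycles.
2. **Time-invariant N-phone layer** — P single-phone nodes plus P x P
   diphone nodes (14 + 196 = 210 by default).
3. **Word layer** — one node per lexicon entry, with all-pairs lateral
   inhibition, and (optionally) positive feedback to its constituent
   N-phones and weak negative feedback to all other N-phones.

Updates are synchronous from a pre-update snapshot, so trials are
deterministic and order-independent; all stochasticity lives in schedule
construction (`degrade_schedule()`, `add_global_noise()` take explicit
seeds).

Three dynamical choices deserve explanation, because each was forced by a
failure mode we observed with the simpler alternative:

**External input clamps.** During its scheduled block, an input node's
activation is the larger of its decayed previous value and the stimulus
amplitude. If the stimulus were instead *added* every cycle, any sub-unit
amplitude (a 1/6 continuum step, weak noise) would integrate to ceiling
within a few cycles, flattening every identification continuum; clamping
preserves graded stimulus strength, which the Ganong and restoration
paradigms require.

**Shunting integration with a sub-rest floor.** The N-phone and word layers
follow the classic interactive-activation update

    a' = a (1 - decay) + exc (act_max - a) - inh (a - act_min)

clipped to `[act_min, act_max]`, with `act_min = -0.2` below the resting
level 0, and only supra-rest activation transmitted. With simple additive
clipping instead, every word whose net input exceeds its decay saturates at
the ceiling: a fully supported embedded word (/diu/ inside /dius/) then
*ties* its carrier forever, and the recognition margin criterion fails for
much of the lexicon. Shunting keeps equilibria proportional to evidence, so
evidence differences become activation differences. The sub-rest floor
gives inhibition holding power: a suppressed node transmits nothing until
it has climbed back above rest.

**Transmission thresholds.** A node influences the next layer only by its
surplus above a layer threshold (`nphone_threshold = 0.2`,
`word_threshold = 0.2`; the word threshold gates both lateral inhibition
and feedback). Without thresholds, positive feedback manufactures N-phone
activity with zero bottom-up support, and cliques of similar words
resonate with each other strongly enough to out-compete the actual target.
Thresholds mean feedback can only amplify what the input at least weakly
supports. They also produce the characteristic delayed activation of
ambiguous (half-amplitude) inputs: a 0.5 stimulus needs top-down or later
bottom-up support before its phoneme crosses threshold.

Two further wiring choices: bottom-up word weights use each word's graded
kernel divided by the kernel mass raised to `kernel_norm_power = 0.5`.
The unnormalized kernel (power 0) lets long words dominate on partial
matches; full normalization (power 1) makes a perfectly matched embedded
word indistinguishable from its carrier. The square-root compromise —
cosine normalization, the standard choice for string kernels — keeps
matched evidence growing with word length while shrinking spurious partial
matches. Positive feedback is likewise a per-word budget (`fb_positive`
spread over the word's constituents with the same exponent), so words with
many constituents cannot inject unboundedly more top-down excitation;
negative feedback stays uniform per non-constituent, as described for the
model, acting as a global brake. Word-word inhibition is not normalized by
the number of competitors.

## Parameters

`tisk_params()` ships the three published presets; the nine core rates are
carried verbatim:

| parameter | ORIGINAL | OPT_NOFB | OPT_FB |
|---|---|---|---|
| input phoneme decay | 0.010 | 0.001 | 0.001 |
| N-phone decay | 0.001 | 0.001 | 0.100 |
| word decay | 0.010 | 0.050 | 0.050 |
| phoneme-to-N-phone | 1.000 | 0.100 | 0.100 |
| diphone-to-word | 0.050 | 0.050 | 0.050 |
| single-phone-to-word | 0.010 | 0.010 | 0.010 |
| word-word inhibition | -0.005 | -0.005 | -0.010 |
| positive feedback | — | — | 0.150 |
| negative feedback | — | — | -0.050 |

All decays are per-cycle proportions; weights are per-cycle gains on
transmitted (supra-threshold) activation. The architecture constants —
`gamma`, `rho`, `kernel_norm_power`, the two transmission thresholds,
`act_min`, `cycles_per_phoneme = 10`, `n_slots = 10`, `total_cycles = 100`
— are this package's design, fixed once by calibrating noise-free
full-lexicon recognition accuracy of all four model variants into the
published regime (high accuracy, with the feedback model slightly below
the optimized feedforward model) *before* any top-down or noise experiment
was examined, and they are identical across all experiments. Presets are
also shipped as YAML under `inst/extdata/presets/`.

## Recognition criterion

`recognition_time()` implements the margin criterion: a word is recognized
at the first cycle where its activation exceeds *every* other word's by at
least 0.05, keeps that margin for 10 consecutive cycles (the window
includes the onset cycle), and remains the strict argmax until the end of
the trial. Ties count against recognition. An exhaustive brute-force
scanner validates the implementation in the test suite.

## The synthetic lexicon generator

The experiments were designed around a small historical 211-word lexicon
that is not redistributed here. `generate_synthetic_lexicon()` emulates its
structure so that everything runs self-contained: 2–9 phoneme words over
the 14-symbol inventory, with controllable densities of onset cohorts,
same-length rhymes, and embeddings (density = proportion of words with at
least one competitor of that class; defaults 0.5 / 0.3 / 0.3). Two realism
constraints matter for the dynamics and are deliberate: rhyme and
embedding derivations use bases of at most 3 phonemes (real rhyme and
embedding families — *cat/bat/scat/cats* — share short cores, and deriving
near-duplicates of 8-phoneme words would create implausibly dense long-word
neighborhoods), and adjacent identical phonemes (geminates) are excluded.
`bundled_lexicon()` returns the frozen 211-word stand-in used by the
simulation defaults: the ten 4-phoneme item words plus *plug* and *blush*,
filled with 199 generated entries under a fixed seed, with *blug*, *plush*
and all Ganong replacement nonwords excluded.

What the generator does **not** emulate: English phonotactics beyond the
geminate ban, word frequency, and the actual transcriptions of the
historical lexicon. Consequently, passing the bundled simulations shows
that the mechanisms produce the qualitative phenomena under realistic
competitor densities — not that quantitative accuracy or RT values match
any particular natural lexicon. When a real lexicon file is available it
can be supplied to every harness (`load_lexicon()`), and `sim1_timecourse()`
will score it directly.

## The five simulation harnesses

* `sim1_timecourse()` — one noise-free trial per word; class time courses
  (target / cohort / same-length rhyme / all-word baseline), accuracy,
  per-item RTs, six lexical dimensions (length, embeddings, cohorts,
  ex-embeddings, DAS neighbors, first-position rhymes) and their RT
  correlations. Note the two rhyme predicates: the time-course class uses
  same-length first-phoneme substitution; the dimension additionally admits
  first-position deletion/addition.
* `sim2_ganong()` — 7-step identification continua (alpha = 0, 1/6, …, 1)
  from each item phoneme to a nonword replacement, at all four positions,
  with and without feedback; choice proportion = peak(lexical) /
  (peak(lexical) + peak(replacement)) over the two single-phone nodes.
* `sim3_right_context()` — /#l^g/ and /#l^S/ with the ambiguous /#/ onset
  (0.5 input to both /p/ and /b/), disambiguated only by the final phoneme.
* `sim4_restoration()` — each item phoneme presented intact, silenced, or
  replaced by truncated Gaussian noise (SD 0.2–0.8); the measure is the
  expected phoneme's peak activation. 480 simulations at the default
  configuration.
* `sim5_noise_sweep()` — full-lexicon runs under global input noise for
  four variants (feedback; optimized feedforward; original feedforward;
  feedback parameters with feedback off), with matched-item RT analysis
  over the words recognized by both models of a pair, with noise samples
  shared across variants.

Problem sizes in the shipped tests are the package's scaled study
conditions: the noise sweep uses a 50-word synthetic lexicon, 5 runs per
level, and SD in {0, 0.05, 0.10, 0.15}; the paper-scale grid (15 levels x
15 runs x 211 words) runs unchanged by passing those arguments.

## Numerical and procedural details

* Noise is applied to external inputs (nonnegative evidence): Gaussian
  draws are truncated at zero, one draw per (phoneme, slot) held over the
  slot's active block by default (`resample = "cycle"` redraws each cycle).
  Schedule values above 1 are not clipped at the schedule level; node
  activations are bounded by the network.
* Input slots beyond the word's end are held at rest, and silence is
  simply absent input (the input floor is rest).
* Per-run and per-word seeds derive from a master seed via a fixed
  splittable counter (`--seed` in the CLI and the experiment functions);
  all derived seeds stay within 32-bit range, and every harness is
  bit-reproducible given its configuration and seed.
* Degenerate inputs: an empty schedule leaves the network at rest forever
  (a fixed point); a single-phoneme word has an empty diphone code;
  lexicons validate symbols and reject duplicate labels at load time.

## Known limitations

* The symmetry-network stand-in is ordinal, not a reimplementation of the
  published gating network; absolute diphone activation levels (and thus
  absolute RTs) are not comparable to the original implementation.
* The feedback model's accuracy is mildly below the feedforward optimum on
  dense synthetic lexicons (as in the published comparison), and the
  restoration effect sizes are modest; both are activation-scale dependent.
* No attempt is made to model phoneme similarity structure (all phonemes
  are equally confusable under noise) or word frequency.
* The full parameter-space search used to find the optimized presets is
  out of scope; `param_grid_search()` is a minimal utility for local
  exploration.
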