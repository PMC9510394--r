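---
title: "Methods: network propagation and the transcriptional reversal screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network propagation and the transcriptional reversal screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `netrepurpose`, the
parameters that matter, the numerical choices behind them, and what the
synthetic validation data can and cannot show about real-data behaviour.

## The propagation model

The interactome is an undirected simple graph of gene symbols: self-loops
removed, reversed duplicates collapsed, edge weights and evidence types
ignored. We deliberately keep the full graph rather than its largest
connected component; diffusion is component-local, so seeds in a small
component retain their heat there, which is the physically meaningful
behaviour and avoids silently discarding genes.

Seed relatedness is scored by the heat kernel of the combinatorial graph
Laplacian $L = D - A$:

$$ h(t) = e^{-tL}\,h_0, \qquad h_0 = \mathbf{1}_{\text{seeds}} . $$

Because the columns of $L$ sum to zero, $\sum_i h_i(t)$ equals the number
of mapped seeds for every $t$ (conservation), and $e^{-tL}$ has
non-negative entries (heat never goes negative). Both properties are
asserted in the test suite. A symmetric-normalized Laplacian
$I - D^{-1/2} A D^{-1/2}$ is available behind the `laplacian` switch for
sensitivity analysis; conservation does not hold for it, which is why it
is not the default.

**Diffusion time `t`.** Default `0.1`, the documented default of the
Cytoscape Diffusion service this stage models. Larger `t` flattens the
heat toward the per-component equilibrium $k/n$; smaller `t` approaches
the seed indicator. Because downstream selection uses only the heat
*ranking*, results are fairly robust over an order of magnitude in `t`,
but the parameter is surfaced in every interface.

**Numerics.** `exp(-tL) h_0` is computed by uniformization: with
$c = \max_i L_{ii}$ and $M = cI - L$ (entrywise non-negative),
$e^{-tL} = e^{-tc} e^{tM}$, and the Taylor series of $e^{tM} h_0$ has
non-negative terms, so the method cannot produce negative heat beyond
rounding. Times with $tc > 8$ are split into sub-steps; the series is
truncated when a term falls below $10^{-14}$ of the accumulated sum
(after at least $tc$ terms, where the Poisson weights peak). The contract
— agreement with a dense eigendecomposition oracle to better than
$10^{-8}$ on graphs up to 200 nodes — is enforced in the acceptance
tests; observed deviations are near $10^{-13}$.

## Disease-network selection

Non-seed nodes are ranked by heat and the top fraction (default 1%) joins
the mapped seeds. Two conventions are deliberate:

* **Seeds are excluded from the ranked pool** and retained
  unconditionally. At genome scale (17,706 nodes, 147 mapped seeds) this
  gives $\lceil 0.01 \times 17{,}559\rceil = 176$ related genes and a
  323-gene network; ranking over all nodes would give 178 and not
  reproduce that arithmetic.
* **Ceiling, not floor or round**, for the selection count: "top 1%" is
  read as at-least coverage (round gives the same 176 here; floor gives
  175; ceiling is the documented choice).

Ties at the cutoff are broken lexicographically so the selection is a
deterministic function of the input.

## Drug–target and signature handling

Approved drugs are kept by a permissive approval-flag match
(`approved/true/yes/1`, case-insensitive); interaction type and direction
are ignored — any interaction row qualifies. Drug names are matched
between the interaction table and the signature compendium exactly after
lower-casing and trimming; synonym resolution across vocabularies is an
external-data curation task out of the package's scope, and unmatched
drugs simply drop out at the `restrict_to_signatures()` step with counts
logged.

Replicate signatures of one drug (cell lines, doses, times) collapse to a
single profile by unweighted mean (default) or by the signed value of
largest magnitude (`max_abs`). Mean is the least-assumption choice; both
are exposed because the aggregation rule is genuinely open. The same
applies to the tissue dimension of the disease profile: unweighted mean
across tissues with a model (default), `max_abs`, or a `single_tissue`
pick. Genes with no model in any tissue are absent from the profile and
silently shrink the correlation gene set.

## The TWAS stage

When the disease profile is not supplied directly it is imputed from GWAS
summary statistics by the S-PrediXcan statistic
$Z_g = \sum_l w_{lg} \sigma_l Z_l / \sigma_g$ with
$\sigma_g = \sqrt{w^\top \Gamma w}$. Implementation choices:

* variants missing from the GWAS are dropped from both $w$ and $\Gamma$
  and $\sigma_g$ recomputed (the standard behaviour of summary-statistic
  imputation tools);
* degenerate models ($\sigma_g = 0$, e.g. weights in the null space of a
  singular LD block) return no value with a recorded reason rather than
  an error, so one bad model cannot abort a transcriptome-wide run;
* allele harmonization is assumed done upstream — inputs carry signed
  z-scores on a consistent effect-allele convention.

The statistic is scale-invariant in the weights and reduces to
$\sum_l Z_l/\sqrt{n}$ for equal weights under identity LD; both closed
forms are asserted in tests.

## The reversal screen

Each drug is scored by the Spearman correlation (Pearson of mid-ranks,
two-sided p from the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$) between its profile and the disease
profile. Decisions worth stating:

* **Gene scope.** Default `network_all`: correlate over all
  disease-network genes present in both profiles. The alternative
  `drug_targets` mode restricts to the drug's own interaction partners in
  the network. The field's phrasing is ambiguous between the two; both
  are implemented and the scope is a visible parameter rather than a
  hidden assumption.
* **Sidedness.** p-values are two-sided; candidacy additionally requires
  $\rho < 0$, and significant positive correlations are flagged as
  potential risk drugs rather than discarded.
* **Multiplicity.** No correction is applied to the candidate flags
  (screens of this kind conventionally report uncorrected p), but a
  Benjamini–Hochberg FDR column is always emitted alongside.
* Drugs sharing fewer than 3 genes with the disease profile are skipped
  with a warning; a permutation p-value (`permutation_p()`) is available
  as a small-n alternative to the t approximation.

## What the synthetic data emulates

`generate_interactome()` draws a preferential-attachment graph (heavy-
tailed degrees, as in real interactomes) and plants a dense module —
extra edges at probability 0.3 among 30 genes — containing the 20 seed
genes, emulating the clustering of disease genes in network
neighbourhoods. `generate_expression_data()` gives every network gene a
true disease effect $\beta \sim N(0,1)$; tissue z-scores are $\beta$ plus
$N(0, 0.5^2)$ noise across 13 tissues, with 35% of genes lacking a model
in every tissue (matching the roughly two-thirds imputation coverage seen
on real brain-tissue panels). Reverser drugs are built by a Gaussian
copula against the realized mean-aggregated disease profile with latent
Pearson correlation $2\sin(\pi\rho_s/6)$, so the planted quantity is
exactly the population Spearman correlation being estimated; replicate
columns add row-centred noise, making mean aggregation recover the
planted vector exactly. Null drugs are independent noise.
`generate_twas_inputs()` builds per-gene random-correlation LD
(`cov2cor(AᵀA)`, unit diagonal, PSD by construction), tissue-jittered
weights around a shared base vector, and GWAS z-scores
$Z_l = 3\,\beta_g w_l + N(0,1)$ so large true effects yield large imputed
$|Z_g|$ of matching sign.

The default `simulate_study()` scenario uses a 500-node interactome and a
top fraction of 0.2 instead of the genome-scale 1%: one percent of a
500-node graph would select ~5 genes, far too few for a stable rank
correlation, whereas 0.2 yields a network of ~115 genes (~75 with tissue
models), the absolute-size regime the screen operates in at genome scale.
Problem sizes used throughout the validation suite (100 oracle graphs of
20–80 nodes, 2,000 null drugs, 100 recovery replicates at 60 genes, 200
TWAS genes) were chosen as the smallest sizes at which the quantities
being checked are statistically stable.

**What passing tests do not show.** The synthetic data have no CMAP-style
batch effects or cell-line heterogeneity, no realistic LD block
structure, no gene-symbol vocabulary mismatches between sources, and
tissue noise is homoscedastic and independent across tissues. Recovery of
planted reversers therefore demonstrates correctness of the machinery,
not expected sensitivity on real compendia, where signature quality and
name reconciliation dominate.

## Known limitations

* Exact symbol matching only; no HGNC alias/history resolution, no
  Entrez/Ensembl conversion.
* The screen's p-values are conditional on the selected network; network
  selection uncertainty is not propagated.
* Connectivity-score (weighted KS) alternatives and drug–disease network
  proximity z-scores are out of scope; the pipeline is diffusion
  membership plus Spearman reversal only.
* GCTX/HDF5 signature files are not read; convert to GCT v1.3 text or
  the TSV dialect first.
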