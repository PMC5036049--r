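# crhunter

Catalytic residue prediction from protein structure and sequence.

`crhunter` scores every residue of an enzyme chain for catalytic function
by fusing four per-residue predictors across two information channels:

- **Structural feature predictor** — an RBF SVM over descriptors of the
  residue's 3D context: a microenvironment score on the Delaunay
  tessellation of heavy atoms (residue contacts weighted by shared
  Voronoi facet counts), residue interaction network centralities
  (degree, closeness, betweenness, clustering), multi-scale Laplacian
  norms (a concavity measure that is small at pocket bottoms), and
  evolutionary profile columns.
- **Sequence feature predictor** — an RBF SVM over a 19-position sliding
  window of PSSM log-odds, conservation entropies, residue type and
  physicochemical scales.
- **Two template predictors** — direct transfer of known catalytic
  annotations from the most similar reference protein found by structure
  alignment or by profile alignment.

Within each channel, the feature and template scores are blended by a
convex combination only when the template similarity clears a reliability
cutoff; otherwise the feature score passes through unchanged. The two
channels are then averaged into the final score.

Because real benchmarks require curated catalytic-site databases and
large-scale alignment searches, the package ships a deterministic
synthetic benchmark generator (`make_benchmark()`) that plants geometric
(surface pocket), compositional (biased alphabet) and evolutionary
(conservation) signal into protein-like chains, plus perturbed-copy
template libraries — enough to exercise and validate the entire pipeline
offline. See the vignette (`vignettes/catalytic-residue-prediction.Rmd`)
for the methods in full.

## Worked example

```r
library(crhunter)

# a self-contained synthetic benchmark: 12 chains with planted catalytic sites
benchmark <- make_benchmark(fixture_spec(n_structures = 12, seed = 7))

# fit on ten chains
model <- crhunter(benchmark$structures[1:10], benchmark$annotations[1:10],
                  benchmark$pssms[1:10], benchmark$msas[1:10])
print(model)
#> <crhunter> fitted on 10 structures (587 residues, 35 catalytic)
#>   facet cutoff 9; SVM C=2 gamma=0.03125 ratio 1:6
#>   fusion alpha=0.55 (SP>=0.60), beta=0.57 (HH>=0.87), gamma=0.50

# score a held-out chain, using its template hits
query <- benchmark$structures[[11]]
id <- query$id
scores <- predict(model, query, benchmark$pssms[[11]], benchmark$msas[[11]],
                  hits_str = benchmark$hits_str[[id]],
                  hits_seq = benchmark$hits_seq[[id]],
                  template_annotations = benchmark$template_annotations)
head(scores[order(-scores$crhunter), ], 5)
#>    index aa fscore_str tscore_str fscore_seq tscore_seq strhunter seqhunter crhunter
#> 27    27  D   1.00e+00          1      0.998          1  1.00e+00     0.999   0.9995
#> 26    26  H   1.00e+00          1      0.998          1  1.00e+00     0.999   0.9993
#> 25    25  D   1.00e+00          1      0.969          1  1.00e+00     0.982   0.9911
#> 28    28  R  4.78e-139          0      0.695          0 2.63e-139     0.396   0.1981
#> 42    42  I  8.65e-237          0      0.180          0 4.76e-237     0.103   0.0513

benchmark$annotations[[11]]$catalytic_indices
#> [1] 25 26 27
```

The three planted catalytic residues are ranked top-3, well separated
from the rest of the chain.

```r
# structure-grouped cross-validation of the whole benchmark
evaluation <- cross_validate(benchmark, k = 3, seed = 7)
print(evaluation)
#> <cr_evaluation> 3-fold CV, 694 residues
#>   fscore_str  AUC 0.983 (fold SE 0.001)
#>   tscore_str  AUC 0.988 (fold SE 0.011)
#>   fscore_seq  AUC 0.995 (fold SE 0.004)
#>   tscore_seq  AUC 0.976 (fold SE 0.013)
#>   strhunter   AUC 1.000 (fold SE 0.000)
#>   seqhunter   AUC 0.999 (fold SE 0.001)
#>   crhunter    AUC 1.000 (fold SE 0.000)
```

Real protein chains enter the same way: `read_structure()` parses a PDB
chain, `read_pssm()` a PSI-BLAST ASCII profile, `read_msa()` an aligned
FASTA, and `read_template_hits()` ranked alignment hits.

## Command line

A thin CLI over the same functions lives in `inst/cli/crhunter.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","crhunter.R",package="crhunter"))')" \
    simulate --out bench/ --n 40 --seed 1
Rscript .../crhunter.R evaluate --benchmark bench/ --k 5 --out report.json
Rscript .../crhunter.R predict  --benchmark bench/ --query syn003 --out scores.tsv
```

## Tests and reproduction

The test suite (testthat, 3rd edition) includes per-module unit tests and
an acceptance suite (`tests/testthat/test-acceptance.R`) that verifies,
among others: facet counts from the Delaunay dual against an explicit
brute-force Voronoi ridge construction (`inst/oracle/voronoi_pairs.py`),
network centralities against Floyd–Warshall + triangle enumeration,
Laplacian-norm closed forms, signal recovery on the 40-structure
benchmark over three seeds, and byte-level determinism of the full
pipeline.

```r
testthat::test_dir("tests/testthat", package = "crhunter",
                   load_package = "installed")
```

To reproduce the headline numbers end to end (40 structures, 5-fold
grouped cross-validation, ~2 minutes on one CPU):

```sh
Rscript scripts/acceptance.R --seed 1 --out report.json
```

which writes pooled AUCs for all seven scores and threshold metrics of
the fused score as a flat JSON report. Every random choice in the
package flows from explicit seeds, so repeated runs are byte-identical.
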