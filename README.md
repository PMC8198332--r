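# thyromorph

Automated morphometry of thyroid follicles from multichannel fluorescence
micrographs, for researchers quantifying thyroid gland architecture and
thyrocyte turnover in histological sections.

Thyroid tissue is organized into follicles: a central lumen storing
thyroglobulin, enclosed by a single-layered thyrocyte epithelium whose outer
edge is marked by a basal lamina. Sections are typically stained with three
fluorescent channels — a *marker* channel (basal lamina such as collagen
IV/laminin, or cathepsins), a whole-*cytoplasm* stain (e.g. CellMask Orange)
and a *nuclei* stain (e.g. Draq5). From such images, `thyromorph`:

- **segments** follicle lumina (primary objects in the inverted all-tissue
  mask, filtered by roundness), follicles (seeded region growing from each
  lumen, bounded by the skeletonized basal lamina and a 30 px expansion cap)
  and epithelia (follicle minus lumen);
- **measures** per-follicle morphometrics: lumen, follicle and epithelium
  areas (µm²); the epithelial extension
  `EExt = sqrt(A_follicle / pi) − sqrt(A_lumen / pi)` (µm), a proxy for
  epithelial height; cells per follicle; the thyrocyte area
  `A_epithelium / n_cells`; and intraluminal dead-cell remnants;
- **compartmentalizes** marker fluorescence into intracellular
  (epithelium-masked) versus extracellular (luminal + pericellular,
  obtained by subtraction) fractions, normalized per cell, with the
  roundness statistic `FormFactor = 4π·area / perimeter²` used to filter
  objects (1.0 = perfect circle, filter threshold 0.3);
- **summarizes** sections (cells per 1000 µm² follicle area, dead-cell
  percentage) and renders standardized lumen-area heat maps;
- **compares** genotype cohorts as fold changes over the wild-type controls
  of each cohort, with one-way ANOVA and Dunnett many-to-one adjustment;
- **generates** synthetic follicular-tissue phantoms with exact ground truth
  (geometry, nucleus counts, marker-signal budget) for validating every step.

## Worked example

```r
library(thyromorph)

# a 2048 x 2048 px synthetic section: 30 follicles with known geometry
ph  <- generate_phantom(phantom_spec(seed = 42, noise_sd = 0))
sec <- analyze_section(ph$channels)

sec
#> <thyro_section> 30 follicles, 475 nuclei (19 intraluminal)
#> # A tibble: 1 × 7
#>   n_follicles mean_lumen_area mean_follicle_area mean_thyrocyte_area mean_eext
#>         <int>           <dbl>              <dbl>               <dbl>     <dbl>
#> 1          30           3754.              6335.                189.      10.5
#> # ℹ 2 more variables: cells_per_1000um2 <dbl>, dead_cell_pct <dbl>

tidy(sec)      # one row per follicle: areas, EExt, n_cells, thyrocyte area, dead cells
glance(sec)    # the one-row section summary shown above

sec$intensity$intra_pct
#> [1] 69
```

The phantom places 31% of the marker signal in the lumina, and the
compartmentalization recovers the intracellular share as exactly 69% of the
total. `mean_eext` of 10.5 µm is the mean equivalent-disc radius difference
across the 30 follicles; every recovered per-follicle value lies within 3%
of the generator's ground truth (`ph$truth`). The 19 intraluminal nuclei
are the rendered dead-cell remnants (4% of all 475 nuclei), recovered
exactly, and the cell density is 2.5 cells per 1000 µm² follicle area.

Cohort comparison:

```r
cmp <- many_to_one_compare(cohort_table)   # columns: animal_id, genotype,
tidy(cmp)                                  #   cohort, metric_name, value
autoplot(cmp)
```

A command-line front end over the same functions is installed at
`inst/cli/thyromorph.R` with subcommands `phantom`, `segment`, `intensity`,
`summarize` and `compare`.

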