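# spikeprop

Spatiotemporal mapping of interictal spike propagation in intracranial EEG.

Interictal spikes — brief high-amplitude discharges recorded between
seizures — often appear on several subdural electrodes with millisecond
latencies, reflecting propagation across the cortical surface. `spikeprop`
turns automated spike-detector output (a stream of `(channel, peak time)`
events) into quantitative maps of that propagation and asks whether their
spatial organisation differs between surgical-outcome groups. It is aimed at
epilepsy researchers analysing presurgical subdural grid/strip recordings.

## The method

Starting from detector output on a 2D electrode map (10 mm grid spacing):

1. **Segmentation** — the event stream is cut into non-overlapping segments
   of 10,000 spikes; 10 segments are sampled at random and concatenated
   (100,000 spikes per recording when available).
2. **Spike frequency maps** — per-channel spikes/min, with the concentration
   of spiking summarised by the Lorenz curve and Gini coefficient
   *G* = Σᵢⱼ|Fᵢ−Fⱼ| / (2N²F̄).
3. **Sequence extraction** — a greedy pass chains spikes into multichannel
   sequences: a spike joins the open candidate if it peaks within 50 ms of
   the sequence *leader* or within 15 ms of the previous spike; a spike
   violating both rules terminates the candidate and leads the next one.
   Only sequences with ≥ 5 spikes are kept. Acquisition ties (equal 5 ms
   frames at 200 Hz) are re-ordered by spatial proximity to the nearest
   non-tied event.
4. **Constraints** — successive spikes must stay within the same or an
   adjacent electrode partition (4–8 neighbouring contacts), unless the
   channel-to-channel connection is *frequent*: C(i,j)/ΣⱼC(i,j) > 0.05,
   where C counts direct i→j propagation across all sequences.
5. **Trajectory cleaning** — every ordered pair of sequences gets a
   similarity score from matched `(x, y, latency)` points
   (sim = 1 − d_match/15 mm within 15 mm and 15 ms); k-means (k = 3) on the
   degree centrality of the non-symmetric similarity matrix removes the
   Low-Degree cluster as artifact-driven outliers.
6. **Recruitment latency maps** — each channel's mean latency from the
   sequence leader, the propagation "source/sink" picture.
7. **Spatial statistics** — the Moran Index
   I = (N/Σwᵢⱼ) · Σwᵢⱼ(Fᵢ−F̄)(Fⱼ−F̄) / Σ(Fᵢ−F̄)², with inverse-distance
   weights wᵢⱼ = 1/dᵢⱼ for dᵢⱼ ≤ 1.5 cm, quantifies the spatial
   organisation of both maps; outcome groups are compared with exact
   Wilcoxon rank-sum tests (midranks, Bonferroni 0.05/2).

A seeded simulator (`simulate_recording()`) generates detector-style event
streams with planted propagating wavefronts, Poisson background spikes, and
single-frame artifact bursts, so every stage can be validated against known
ground truth.

## Worked example

```r
library(spikeprop)

map <- grid_electrode_map(6, 8)                      # 48 contacts, 10 mm
cfg <- simulation_config(map = map,
                         sources = rbind(c(0, 0), c(70, 50)),
                         discharge_rate = 8, duration_min = 5,
                         background_rate = 0.2, detection_miss_rate = 0,
                         artifact_burst_rate = 12, latency_jitter_sd = 1,
                         seed = 91)
sim <- simulate_recording(cfg)
rep <- run_pipeline(sim$dataset, map, spikes_per_segment = NULL, seed = 7)
rep
#> Spike-propagation run:
#>             spikes_in           spikes_used         segments_used
#>                  1149                  1149                    NA
#>         raw_sequences constrained_sequences     cleaned_sequences
#>                    43                    54                    40
#> gini 0.152 | seq freq 8.0000 /min | Moran (freq) 0.307 | Moran (latency) 0.614
```

The planted wavefronts are recovered as multichannel sequences (the
constrained count can exceed the raw count because a constraint-violating
spike splits off a new, temporally overlapping candidate). The
recruitment-latency map is strongly spatially organised (Moran I ≈ 0.61:
the two simulated lead regions cluster early latencies around themselves),
and the frequency map inherits milder structure from the wavefronts
themselves (I ≈ 0.31). The low Gini (≈ 0.15) says spikes are spread fairly
evenly across channels in this simulation.

Group statistics of the packaged 18-patient cohort:

```r
rep <- reproduce_cohort_stats()
subset(rep$summary, variable %in% c("freq_moran", "latency_moran"))
#>        variable mean_all sd_all mean_szfree sd_szfree mean_szpersist sd_szpersist        p
#> 6    freq_moran   0.3978 0.1450      0.4068    0.1614         0.3888      0.13595 0.863307
#> 9 latency_moran   0.3608 0.1534      0.4471    0.1594         0.2744      0.08836 0.002962
```

Recruitment-latency organisation separates seizure-free from
seizure-persistent patients (p = 0.003, below the Bonferroni threshold
0.025); spike-frequency organisation does not (p = 0.863).

## Command line

A thin CLI over the same functions ships in `inst/cli/spikeprop.R`:

```sh
Rscript inst/cli/spikeprop.R simulate --config sim.yaml --out-dir sim/
Rscript inst/cli/spikeprop.R run --detections sim/detections.csv \
    --map sim/electrode_map.csv --minutes 5 --out-dir run/
Rscript inst/cli/spikeprop.R stats
```

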