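# activeload

Single-cell microfluidic instruments that make slow biophysical
measurements — serial suspended microchannel resonators (sSMR) weighing
cells to picogram precision among them — face a hard trade-off: the
measurement channel's flow rate is fixed by the required measurement
bandwidth, so cells enter at a rate governed purely by Poisson statistics
at the sample concentration. Dilute or debris-laden clinical samples then
take hours to days to measure, and debris clogs the channel.

**Active loading** breaks that trade-off with an optically triggered
fluidic state machine. Four image regions of interest (ROIs) drive four
fluidic states: a fast **seek** scan of the sampling channel finds the next
particle without touching the measurement flow; **load** captures it;
**queue** bumps it upstream until the loading duty cycle has elapsed, so
cells arrive evenly spaced; and **reject** briefly reverses the measurement
flow to expel debris and doublets identified by real-time geometry
(cross-sectional area and x–y ratio) at the channel entrance.

`activeload` is a complete in-silico implementation for studying and
validating this scheme:

* the pure four-state controller (`onRoiEvent`, `verdict`,
  `transitionTable`), replayable event log included;
* an event-driven stochastic simulator of the two-channel device
  (`runPassive`, `runActive`) with Poisson particle arrivals,
  camera-frame-quantized detection, pneumatic-latency overshoot, and
  geometric debris rejection;
* closed-form throughput theory (`passiveThroughput`, `activeThroughput`,
  `speedup`): passive loading measures cells at rate
  `λ·exp(−λ·t_match)` with `λ = c·Q_m` (unimodal in concentration, peak
  `3600/(e·t_match)` cells/h at `λ = 1/t_match`), while active loading is a
  renewal process with mean cycle `E[max(t_duty, W)]`, `W` the seek delay,
  saturating at `3600/t_duty` and approaching `Q_s/Q_m` times the passive
  rate for dilute samples;
* synthetic bright-field imaging with detection and classification
  (`renderFrame`, `detectParticles`, `classifyStream`);
* the SMR signal chain (`synthTrace`, `occupancy`, `transitTimes`,
  `peakMass`, `matchCells`, `mar`): Savitzky–Golay smoothing, running-median
  baseline subtraction, threshold plus length-49 median filtering into
  binary occupancy, transit times as runs of occupied samples, buoyant
  masses from depression depths, and mass accumulation rate (MAR, pg/h) as
  the least-squares slope of a cell's mass trajectory;
* group statistics for drug-vs-control panels (`tukeySummary`,
  `compareGroups`, `conditionTable`).

## Worked example

```r
library(activeload)

cfg <- SimulationConfig(concentration = 10, dutyCycle = 15,
                        duration = 3600, seed = 1)
runPassive(cfg)
#> SimResult (passive loading)
#>   loaded   : 1 events (1 per h)
#>   rejected : 0, overshoots: 0, still in channel: 0
#>   duration : 3600 s
runActive(cfg)
#> SimResult (active loading)
#>   loaded   : 33 events (33 per h)
#>   rejected : 0, overshoots: 33, still in channel: 0
#>   duration : 3600 s

p <- ThroughputParams()   # Q_m = 5e-5 uL/s, t_match = 0.8 s, t_duty = 15 s
round(c(passive = passiveThroughput(10, p),
        active  = activeThroughput(10, p),
        speedup = speedup(10, p)), 2)
#> passive  active speedup
#>    1.80   35.59   19.78
```

At 10 particles/µL the passive detector sees ~2 cells per hour (one in this
particular simulated hour); the seek/queue cycle delivers ~35 — the
simulated counts straddle their closed-form expectations. The dilute-limit
speedup approaches the seek flow multiplier (20×).

The signal chain recovers the 800 ms detector transit time from a noisy
synthetic resonance trace:

```r
tr <- synthTrace(data.frame(start = 4.605, duration = 0.8, depth = 10),
                 sampleRate = 100, noiseSd = 1, duration = 12, seed = 1)
transitTimes(occupancy(tr, FilterSettings(threshold = 1)), 100)
#> [1] 0.8
```

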