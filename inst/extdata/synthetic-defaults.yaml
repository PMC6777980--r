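# Default study conditions for the synthetic paired tracer/tractography
# generator. Units: distances in mm, rates per mm.
nRegions: 8            # ferret-like edge-complete subnetwork size
edgeDensity: 0.85      # inter-areal visual cortex is densely connected
reciprocity: 0.8       # cortico-cortical projections are highly reciprocal
mu: 0.0                # lognormal log-mean of true weights
sigma: 1.5             # lognormal log-sd: ~3 orders of magnitude of weights
lambda: 0.2            # exponential distance decay of true weights (per mm)
boxSize: 20.0          # centroid sampling box edge (mm)
neuronsPerInjection: 10000   # labeled neurons counted per injection site
totalStreamlines: 1000000    # streamlines tracked over the whole brain
gamma: 0.05            # tractography distance-dependent dropout (per mm)
epsilon: 0.002         # false-positive floor, relative to the mean weight
allocation: multinomial      # streamline budget: multinomial | poisson
seed: 20260101
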