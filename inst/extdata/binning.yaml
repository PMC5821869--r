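# Surrogate-measure binning: thresholds strictly increasing; ordinal =
# number of thresholds strictly below the measure. Ranges follow the Ishak
# grading scheme (0-4, 0-6, 0-4, 0-4; composite 0-18). Boundary values
# calibrated once on the synthetic severity-ladder design (CD45 densities
# in cells/mm^2, necrotic fraction of tissue, foci/mm^2 of lobule).
piecemeal: [100, 300, 500, 800]
confluent: [0.01, 0.05, 0.10, 0.15, 0.20, 0.25]
lobular: [1, 4, 8, 14]
portal: [100, 300, 500, 800]
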