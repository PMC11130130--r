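# Climate-zone scheme: class edges for annual growing-degree days (C-days,
# base 0), aridity index (precipitation / PET) and temperature seasonality
# (bio4 convention, SD of monthly means x 100). Bins are half-open [lo, hi);
# codes concatenate the three class indices as "gdd-ai-ts". The edges
# approximate the global yield-gap atlas zonation (GDD classes of 1000
# C-days, aridity classes densified in the semi-arid range); the scheme is
# configuration, not code, and analyses should be reported alongside the
# scheme used.
gdd_edges: [0, 1000, 2000, 3000, 4000, 5000, 6000, 7000, 8000, 9000, 10000, 11000, 12000]
ai_edges: [0, 0.05, 0.1, 0.15, 0.2, 0.3, 0.5, 0.7, 1.0, 1.5, 100]
ts_edges: [0, 250, 500, 750, 1000, 1500, 2500, 20000]
two_season_zones: []
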