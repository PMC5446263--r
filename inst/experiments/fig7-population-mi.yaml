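# Single-cell variability and mutual information: 8 stimulus levels (3-bit
# input), log-normal cell-to-cell scaling (CV 0.3) of receptor and ERK totals.
# Run: Rscript gnrhpulse.R mi simulate --config fig7-population-mi.yaml --seed 1 --out cells.csv
#      Rscript gnrhpulse.R mi estimate --in cells.csv --bins 16 --boot 200
model: network
population:
  stimulus_levels: [1.0e-11, 1.0e-10, 3.0e-10, 1.0e-9, 3.0e-9, 1.0e-8, 1.0e-7, 1.0e-6]
  n_cells: 30
  cv: 0.3
  noise_sd: 0.0
  seed: 1
seed: 1
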