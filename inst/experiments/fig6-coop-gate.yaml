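# Co-operative gate: bell-shaped frequency response (and non-monotonic dose
# response at reduced internalization), vs monotonic single-TF/AND/OR gates.
# Frequency: Rscript gnrhpulse.R scan-frequency --config fig6-coop-gate.yaml \
#              --periods 5,15,30,60,120,240,480 --out freq.csv
# Dose:      Rscript gnrhpulse.R scan-dose --config fig6-coop-gate.yaml \
#              --doses 1e-11,1e-10,1e-9,1e-8,1e-7,1e-6 --out dose.csv
model: network
params:
  int_mult: 0.5
protocol:
  amplitude_M: 1.0e-7
  width_min: 5
  period_min: 60
  horizon_min: 960
gate:
  mode: COOP
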