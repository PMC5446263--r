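# Pulsatility mitigates receptor internalization: compare PLC/Egr1 AUCs at
# int_mult 1 vs 0.001 across constant (period 5 = width) and periods 30, 120.
# Run once per int_mult (edit params.int_mult to 0.001 for the reference):
#   Rscript gnrhpulse.R scan-frequency --config fig4-internalization-mitigation.yaml \
#     --periods 5,30,120 --out scan_int1.csv
model: network
params:
  int_mult: 1
protocol:
  amplitude_M: 1.0e-7
  width_min: 5
  period_min: 60
  horizon_min: 960
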