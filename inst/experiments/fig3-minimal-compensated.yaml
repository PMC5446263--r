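# Minimal cascade, compensated family (duty fraction 1/12, equal input
# integral): E1*/E3* AUCs flat, E2* AUC increasing with frequency.
# Run: Rscript gnrhpulse.R scan-frequency --config fig3-minimal-compensated.yaml \
#        --periods 12,24,48,96,192,384 --compensated --duty 0.0833333333 --out scan.csv
model: minimal
protocol:
  amplitude_M: 1
  width_min: 2
  period_min: 24
  horizon_min: 768
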