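# Minimal cascade, fixed 4-min pulse width, varied period: E1*/E3* AUC
# proportional to frequency, E2* AUC non-linear.
# Run: Rscript gnrhpulse.R scan-frequency --config fig3-minimal-noncompensated.yaml \
#        --periods 4,8,16,32,64,128,256 --width 4 --out scan.csv
model: minimal
protocol:
  amplitude_M: 1
  width_min: 4
  period_min: 32
  horizon_min: 1024
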