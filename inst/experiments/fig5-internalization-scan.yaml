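# Ca2+ frequency-response shape across internalization multipliers: bell
# shape emerges at 4x and above; PLC stays monotonic at every multiplier.
# Run: Rscript gnrhpulse.R scan-internalization --config fig5-internalization-scan.yaml \
#        --int-mults 0.03125,0.0625,0.125,0.25,0.5,1,2,4,8,16,32 --out shapes.csv
model: network
protocol:
  amplitude_M: 1.0e-7
  width_min: 5
  period_min: 60
  horizon_min: 960
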