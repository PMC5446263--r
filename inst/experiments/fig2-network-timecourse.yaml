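# Network time course under 5-min pulses of 1e-7 M GnRH at 60-min period:
# fast HR/PLC/Ca2+/ppERK transients, slow NFAT and Egr1 accumulation.
# Run: Rscript gnrhpulse.R simulate --config fig2-network-timecourse.yaml --out tc.csv
model: network
protocol:
  amplitude_M: 1.0e-7
  width_min: 5
  period_min: 60
  horizon_min: 960
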