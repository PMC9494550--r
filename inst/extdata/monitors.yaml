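# Registry of bundled SYNTHETIC monitor response functions.
# valid_range is the energy interval (MeV) over which the curve may be
# evaluated; non-zero fluence outside it is an error, never a silent zero.
wendi2:
  file: response_wendi2_synthetic.csv
  valid_range: [1.0e-9, 5000.0]
lb6411:
  file: response_lb6411_synthetic.csv
  valid_range: [1.0e-9, 240.0]
nm2b458:
  file: response_nm2b458_synthetic.csv
  valid_range: [1.0e-9, 240.0]
nm2b495pb:
  file: response_nm2b495pb_synthetic.csv
  valid_range: [1.0e-9, 240.0]
sievert:
  file: response_sievert_synthetic.csv
  valid_range: [1.0e-9, 240.0]
hawk:
  file: response_hawk_synthetic.csv
  valid_range: [0.5, 60.0]
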