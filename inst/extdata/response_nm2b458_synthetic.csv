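# SYNTHETIC stylized H*(10) energy response of a conventional
# Andersson-Braun BF3 counter (NM2B-458 type): response drops rapidly above
# about 10 MeV. Test/demo fixture, not metrological data.
energy_MeV,response
1.0e-9,0.35
1.0e-8,0.45
1.0e-7,0.75
1.0e-6,1.55
1.0e-5,1.75
1.0e-4,1.70
1.0e-3,1.50
1.0e-2,1.25
1.0e-1,1.05
5.0e-1,1.00
1.0,1.00
5.0,0.95
10.0,0.80
20.0,0.30
50.0,0.03
100.0,0.006
240.0,0.002
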