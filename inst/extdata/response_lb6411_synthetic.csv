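# SYNTHETIC stylized H*(10) energy response of a conventional moderated
# 3He counter (LB 6411 type): thermal under-response, strong epithermal
# over-response, near-unity around evaporation energies and a steep cutoff
# above about 20 MeV. Test/demo fixture, not metrological data.
energy_MeV,response
1.0e-9,0.35
1.0e-8,0.45
1.0e-7,0.75
1.0e-6,1.60
1.0e-5,1.85
1.0e-4,1.80
1.0e-3,1.55
1.0e-2,1.30
1.0e-1,1.05
5.0e-1,1.00
1.0,1.00
5.0,1.00
10.0,0.90
15.0,0.65
20.0,0.40
30.0,0.10
50.0,0.02
100.0,0.005
240.0,0.002
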