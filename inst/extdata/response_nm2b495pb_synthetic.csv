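# SYNTHETIC stylized H*(10) energy response of an extended-range
# Andersson-Braun counter with lead shell (NM2B-495Pb type): near-unity
# response kept up to high energies. Test/demo fixture, not metrological
# data.
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
5.0,1.00
10.0,1.00
20.0,1.00
50.0,0.95
100.0,0.90
240.0,0.85
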