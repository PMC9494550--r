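# SYNTHETIC stylized H*(10) energy response of a variance-method TEPC
# (Sievert type): epithermal under-response (less backscatter than the ICRU
# sphere), near-unity at evaporation energies, slight high-energy
# over-response. Test/demo fixture, not metrological data.
energy_MeV,response
1.0e-9,0.40
1.0e-8,0.45
1.0e-7,0.50
1.0e-6,0.50
1.0e-5,0.55
1.0e-4,0.60
1.0e-3,0.65
1.0e-2,0.75
1.0e-1,0.90
5.0e-1,0.98
1.0,1.00
5.0,1.00
10.0,1.05
20.0,1.10
50.0,1.15
100.0,1.25
240.0,1.30
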