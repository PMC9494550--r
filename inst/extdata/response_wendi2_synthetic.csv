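# SYNTHETIC stylized H*(10) energy response of an extended-range moderated
# neutron monitor (Wendi-II type): thermal under-response, epithermal
# over-response, near-unity around evaporation energies, mild high-energy
# under-response thanks to the tungsten shell. Test/demo fixture, not
# metrological data.
energy_MeV,response
1.0e-9,0.30
1.0e-8,0.40
1.0e-7,0.70
1.0e-6,1.40
1.0e-5,1.60
1.0e-4,1.60
1.0e-3,1.40
1.0e-2,1.20
1.0e-1,1.05
5.0e-1,1.00
1.0,1.00
5.0,1.00
10.0,0.98
20.0,0.95
50.0,0.85
100.0,0.80
240.0,0.75
5000.0,0.70
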