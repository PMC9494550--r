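# SYNTHETIC stylized H*(10) energy response of a single-event TEPC (HAWK
# type); data points only exist between 0.5 and 60 MeV, reflected in the
# valid range of the registry entry. Test/demo fixture, not metrological
# data.
energy_MeV,response
0.5,0.95
1.0,1.00
5.0,1.00
20.0,1.00
60.0,1.05
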