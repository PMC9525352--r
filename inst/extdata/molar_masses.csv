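compound,molar_mass_g_mol
TBBPA,543.87
BDE-47,485.79
BDE-99,564.69
TPHP,326.28
TBOEP,398.47
BBOEP,298.31
IDDPHP,390.46
IPPHP,368.37
TCP,368.37
TDCIPP,430.90
t-BPDPHP,382.39
TOCP,368.37
EHDPHP,362.41
TCIPP,327.57
TCEP,285.49
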