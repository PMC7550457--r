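# Molar extinction coefficients of human hemoglobin (Gratzer/Prahl compilation,
# as distributed with the Homer processing ecosystem).
# Units: cm^-1 (mole/liter)^-1, base-10 (decadic) absorbance convention,
# i.e. OD = eps * C * L with OD = -log10(I/I0).
# Columns: wavelength_nm, eps_hbo2 (oxyhemoglobin), eps_hbr (deoxyhemoglobin).
wavelength_nm,eps_hbo2,eps_hbr
660,319.6,3226.56
690,276.0,2051.96
700,290.0,1794.28
750,518.0,1405.24
760,586.0,1548.52
780,710.0,1075.44
800,816.0,761.72
830,974.0,693.04
850,1058.0,691.32
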