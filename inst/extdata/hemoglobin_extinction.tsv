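# Decadic molar extinction coefficients of human hemoglobin.
# Units: cm^-1 mM^-1 (base-10 absorbance convention).
# Source: standard compiled Hb/HbO2 absorption spectra (Prahl/OMLC
# compilation), linearly interpolated to the device wavelengths.
wavelength_nm	eps_hb	eps_hbo2
735	1.1050	0.4100
805	0.7617	0.8303
850	0.6913	1.0580
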