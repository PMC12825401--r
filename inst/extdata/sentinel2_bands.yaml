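# Default band definitions for the chlorophyll band-depth index:
# Sentinel-2A Bands 3/4/5 with nominal centres and bandwidths, boxcar
# spectral response functions. Readable with readBandConfig(); replace
# `shape` with `gaussian`, or add an `srf_table` CSV path
# (wavelength_nm, weight) for tabulated response functions.
- name: B3
  center_nm: 560
  fwhm_nm: 36
  shape: boxcar
- name: B4
  center_nm: 665
  fwhm_nm: 31
  shape: boxcar
- name: B5
  center_nm: 705
  fwhm_nm: 15
  shape: boxcar
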