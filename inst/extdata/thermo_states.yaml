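# Thermodynamic states of the aqueous systems: temperature (K), mass density
# (kg/L) and number of configurations analyzed per state.
states:
  - {temperature_K: 298, density_kgL: 0.997, n_probes: 24996}
  - {temperature_K: 310, density_kgL: 0.994, n_probes: 25000}
  - {temperature_K: 373, density_kgL: 0.969, n_probes: 24999}
  - {temperature_K: 473, density_kgL: 0.881, n_probes: 21036}
  - {temperature_K: 573, density_kgL: 0.740, n_probes: 24493}
  - {temperature_K: 573, density_kgL: 0.720, n_probes: 24843}
  - {temperature_K: 623, density_kgL: 0.610, n_probes: 24577}
  - {temperature_K: 673, density_kgL: 0.660, n_probes: 24376}
  - {temperature_K: 673, density_kgL: 0.550, n_probes: 24353}
  - {temperature_K: 653, density_kgL: 0.451, n_probes: 22613}
  - {temperature_K: 673, density_kgL: 0.420, n_probes: 23020}
  - {temperature_K: 673, density_kgL: 0.375, n_probes: 19929}
  - {temperature_K: 673, density_kgL: 0.310, n_probes: 19358}
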