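# Demo run configuration: Portugal-like synthetic domain, two mock
# GCM-RCM model pairs with a known warm bias, moderate and strong
# warming scenarios (degC per year), eight synthetic fruit regions.
weather:
  grid: {lat: [36.5, 42.5, 10], lon: [-9.5, -6.0, 10]}
  year_start: 1989
  year_end: 2005
  mean_annual_T: 15
  lat_ref: 40
  lat_gradient: -0.7
  seasonal_amplitude: 6.5
  diurnal_range: 10
  ar1_coef: 0.7
  noise_sd: 2
  bias_offset: 1.5
  bias_scale: 1.02
scenario_grid: {lat: [36.5, 42.5, 8], lon: [-9.5, -6.0, 8]}
n_models: 2
scenarios: {rcp45: 0.02, rcp85: 0.045}
future_end: 2080
regions: demo_regions.geojson
n_quantiles: 99
level: 0.1
seed: 1
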