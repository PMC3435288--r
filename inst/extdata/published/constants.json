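{
  "mean_phi": {
    "country_table": 0.0706,
    "domestic_port_table": 0.0613,
    "port_by_port_table": 0.00259
  },
  "degree_centrality": {
    "Busan": 3086,
    "Kaohsiung": 2979,
    "Keelung": 758,
    "Yemen": 57,
    "Turkey": 113,
    "Pakistan": 125
  },
  "mean_leg_days": 7.9,
  "window_prior_ports": 10,
  "window_journey_days": 71,
  "simulations_per_origin": 2000000,
  "network_scale": {
    "foreign_ports": 553,
    "countries": 126,
    "domestic_ports": 30,
    "ships": 557,
    "call_events": 25507,
    "range_countries": 36,
    "range_countries_on_network": 24,
    "range_ports_on_network": 87
  }
}
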