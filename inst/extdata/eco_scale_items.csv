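method,label,category,points
proposed,distilled water,reagent,0
proposed,instrument energy (< 1.5 kWh per sample),instrument_energy,1
proposed,occupational hazard,occupational_hazard,0
proposed,waste,waste,3
reported_ANT,ethanol,reagent,4
reported_ANT,0.1 N HCl,reagent,4
reported_ANT,instrument energy (< 1.5 kWh per sample),instrument_energy,1
reported_ANT,occupational hazard,occupational_hazard,0
reported_ANT,waste,waste,3
reported_BEN,0.01 N HCl,reagent,4
reported_BEN,instrument energy (< 1.5 kWh per sample),instrument_energy,1
reported_BEN,occupational hazard,occupational_hazard,0
reported_BEN,waste,waste,3
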