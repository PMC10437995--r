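label,category,unit_cost,quantity,amount,attributable_fraction
"Personnel: field staff, supervision and management",personnel,,,46485,1
"Materials and other variable costs",materials_other,,,11496,1
"Capacity building: recruitment and training of health workers",capacity_building,,,1822,1
"Capital: facilities, mobile tent, phones and other overheads",capital,,,533,1
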