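id: 0015
name: Rosa Moretti
description: A grandmother with reduced creatinine clearance. Her premixed regimen is simple, but renal impairment changes how high excursions resolve.
weight: 67 kg
meal: 08:00 30
meal: 10:30 15
meal: 13:00 35
meal: 16:00 15
meal: 18:30 35
meal: 22:00 10
insulin: Humulin M3 30/70
injection: 08:00 16
injection: 18:30 12
rtg: normal
ccr: low_reduced
hepatic: normal
peripheral: normal
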