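id: 0032
name: Birgit Hansen
description: A ferry steward with a high renal threshold; nothing spills into the urine until glucose is very high. Her HbA1c tells the real story.
weight: 64 kg
meal: 08:00 30
meal: 10:30 20
meal: 13:00 40
meal: 16:00 15
meal: 19:00 40
meal: 22:30 15
insulin: Actrapid
injection: 08:00 8
injection: 19:00 6
insulin: Insulatard
injection: 08:00 10
injection: 22:30 8
rtg: high_increased
ccr: normal
hepatic: normal
peripheral: normal
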