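id: 0004
name: Dikembe Okafor
description: A heavyweight rower with reduced peripheral sensitivity and a high renal threshold. Large meals and large boluses make his profile swing; smooth it out.
weight: 90 kg
meal: 07:30 45
meal: 10:30 20
meal: 13:00 55
meal: 16:30 20
meal: 19:30 50
meal: 22:30 15
insulin: Actrapid
injection: 07:30 10
injection: 13:00 12
injection: 19:30 10
insulin: Protaphane
injection: 07:30 10
injection: 22:30 14
rtg: high_increased
ccr: normal
hepatic: normal
peripheral: low_reduced
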