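id: 0023
name: Helga Brandt
description: A baker with reduced peripheral sensitivity and an early, carbohydrate-heavy breakfast. The post-breakfast peak dominates her day.
weight: 69 kg
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
rtg: normal
ccr: normal
hepatic: normal
peripheral: low_reduced
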