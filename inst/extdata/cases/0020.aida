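id: 0020
name: Viktor Petrov
description: A night-shift security guard. His single long-acting injection anchors the day; mealtime soluble insulin does the rest.
weight: 80 kg
meal: 08:00 30
meal: 13:00 40
meal: 19:00 40
meal: 22:00 10
insulin: Actrapid
injection: 08:00 6
injection: 19:00 6
insulin: Ultratard
injection: 22:00 12
rtg: normal
ccr: normal
hepatic: normal
peripheral: normal
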