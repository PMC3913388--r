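id: 0037
name: Olusegun Bakare
description: A lecturer who wants a minimal regimen during term time. One basal injection and two boluses: find the weak point.
weight: 74 kg
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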