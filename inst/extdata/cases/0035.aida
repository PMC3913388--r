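id: 0035
name: Douglas Ferguson
description: A rugby coach with a large evening meal after training. His overnight profile depends heavily on the supper bolus.
weight: 87 kg
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
rtg: normal
ccr: normal
hepatic: normal
peripheral: normal
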