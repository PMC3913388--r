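id: 0008
name: Gordon MacLeish
description: A publican with reduced sensitivity at both liver and periphery. He needs substantial doses; explore how far insulin alone can take him before diet changes are needed.
weight: 88 kg
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
hepatic: low_reduced
peripheral: low_reduced
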