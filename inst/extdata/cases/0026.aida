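id: 0026
name: Sophie Marchand
description: This young woman is on a twice daily insulin regimen, injecting a biphasic preparation with a premixed 30% to 70% ratio of short versus intermediate acting insulin. It saves mixing insulin in the syringe at the cost of some flexibility. Use the simulator to see what would happen if you switched her onto other biphasic preparations with, say, 10/90, 20/80, 40/60 or 50/50 percent constituents.
weight: 58 kg
meal: 08:00 30
meal: 10:30 15
meal: 13:00 35
meal: 16:00 15
meal: 18:30 35
meal: 22:00 10
insulin: Mixtard 30/70
injection: 08:00 18
injection: 18:30 12
rtg: normal
ccr: normal
hepatic: normal
peripheral: normal
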