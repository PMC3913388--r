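id: 0036
name: Chantal Dubois
description: A pastry chef with increased hepatic sensitivity who samples her own work. Daytime grazing meets a responsive liver.
weight: 56 kg
meal: 08:00 35
meal: 13:00 45
meal: 16:00 15
meal: 19:00 40
meal: 22:30 10
insulin: Humulin S
injection: 08:00 7
injection: 13:00 8
injection: 19:00 7
insulin: Humulin I
injection: 22:30 12
rtg: normal
ccr: normal
hepatic: high_increased
peripheral: normal
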