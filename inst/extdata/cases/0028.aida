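id: 0028
name: Aisha Khan
description: A pharmacist with increased peripheral sensitivity who snacks to protect against lows. Could smaller boluses remove the need?
weight: 51 kg
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
hepatic: normal
peripheral: high_increased
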