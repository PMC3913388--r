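id: 0038
name: Hannah Goldstein
description: A journalist with erratic meal times held together by a twice-daily premix. Today's schedule is regular; disturb it.
weight: 60 kg
meal: 08:00 30
meal: 10:30 15
meal: 13:00 35
meal: 16:00 15
meal: 18:30 35
meal: 22:00 10
insulin: Humulin M3 30/70
injection: 08:00 16
injection: 18:30 12
rtg: normal
ccr: normal
hepatic: normal
peripheral: normal
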