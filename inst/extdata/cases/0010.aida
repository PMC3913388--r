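id: 0010
name: Hugh Allibaster
description: This gentleman runs persistently high on twice-daily soluble insulin with a single bedtime ultralente injection. His supper and bedtime snack are generous. Raise the evening doses, or trim the evening carbohydrate, and watch the predicted HbA1c respond.
weight: 70 kg
meal: 08:00 30
meal: 10:30 15
meal: 13:00 40
meal: 16:00 15
meal: 19:00 40
meal: 22:30 10
insulin: Actrapid
injection: 08:00 6
injection: 19:30 4
insulin: Ultratard
injection: 23:00 8
rtg: normal
ccr: normal
hepatic: normal
peripheral: normal
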