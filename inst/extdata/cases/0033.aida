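id: 0033
name: Ahmed Farouk
description: A surveyor resistant to insulin at both sites, on substantial doses. Explore whether redistributing carbohydrate helps more than more insulin.
weight: 79 kg
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
hepatic: low_reduced
peripheral: low_reduced
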