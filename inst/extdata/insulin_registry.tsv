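# Insulin preparation registry: one brand per line, tab-separated.
# category: short | intermediate | long | biphasic
# class: absorption class for non-biphasic brands
#        (ACTRAPID_LIKE, NPH_LIKE, LENTE_LIKE, ULTRALENTE_LIKE)
# percent_short / intermediate_class: biphasic brands only.
# The intermediate brands are split between the NPH-like and Lente-like
# absorption classes here; edit this file to re-map brands or add entries.
name	category	class	percent_short	intermediate_class
Actrapid	short	ACTRAPID_LIKE
Human Actrapid	short	ACTRAPID_LIKE
Humulin S	short	ACTRAPID_LIKE
Humulin R	short	ACTRAPID_LIKE
Velosulin	short	ACTRAPID_LIKE
Insuman Rapid	short	ACTRAPID_LIKE
Hypurin Porcine Neutral	short	ACTRAPID_LIKE
Hypurin Bovine Neutral	short	ACTRAPID_LIKE
Iletin II Regular	short	ACTRAPID_LIKE
Pur-In Neutral	short	ACTRAPID_LIKE
Insulatard	intermediate	NPH_LIKE
Human Insulatard	intermediate	NPH_LIKE
Humulin I	intermediate	NPH_LIKE
Humulin N	intermediate	NPH_LIKE
Protaphane	intermediate	NPH_LIKE
Insuman Basal	intermediate	NPH_LIKE
Hypurin Porcine Isophane	intermediate	NPH_LIKE
Hypurin Bovine Isophane	intermediate	NPH_LIKE
Iletin II NPH	intermediate	NPH_LIKE
Pur-In Isophane	intermediate	NPH_LIKE
Monotard	intermediate	LENTE_LIKE
Human Monotard	intermediate	LENTE_LIKE
Humulin L	intermediate	LENTE_LIKE
Lentard MC	intermediate	LENTE_LIKE
Hypurin Bovine Lente	intermediate	LENTE_LIKE
Semitard MC	intermediate	LENTE_LIKE
Semilente MC	intermediate	LENTE_LIKE
Iletin II Lente	intermediate	LENTE_LIKE
Tempulin	intermediate	LENTE_LIKE
Ultratard	long	ULTRALENTE_LIKE
Human Ultratard	long	ULTRALENTE_LIKE
Humulin Zn	long	ULTRALENTE_LIKE
Hypurin Bovine PZI	long	ULTRALENTE_LIKE
Mixtard 10/90	biphasic		10	NPH_LIKE
Mixtard 20/80	biphasic		20	NPH_LIKE
Mixtard 30/70	biphasic		30	NPH_LIKE
Mixtard 40/60	biphasic		40	NPH_LIKE
Mixtard 50/50	biphasic		50	NPH_LIKE
Humulin M1 10/90	biphasic		10	NPH_LIKE
Humulin M2 20/80	biphasic		20	NPH_LIKE
Humulin M3 30/70	biphasic		30	NPH_LIKE
Humulin M4 40/60	biphasic		40	NPH_LIKE
Humulin 50/50	biphasic		50	NPH_LIKE
PenMix 10/90	biphasic		10	NPH_LIKE
PenMix 20/80	biphasic		20	NPH_LIKE
PenMix 30/70	biphasic		30	NPH_LIKE
PenMix 40/60	biphasic		40	NPH_LIKE
PenMix 50/50	biphasic		50	NPH_LIKE
Insuman Comb 15/85	biphasic		15	NPH_LIKE
Insuman Comb 25/75	biphasic		25	NPH_LIKE
Insuman Comb 50/50	biphasic		50	NPH_LIKE
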