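pod	domain	score	note
2	linguistic	1	mutism
28	linguistic	2	speaks single words
60	linguistic	3	speaks sentences
2	motoric	1	general atonia
12	motoric	2	limb movements return
26	motoric	3	truncal stability
36	motoric	4	walks short distance
2	neurobehavioral	1	minimal response
13	neurobehavioral	2	emotional lability
26	neurobehavioral	3	consolable lability
90	neurobehavioral	4	irritable but interactive
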