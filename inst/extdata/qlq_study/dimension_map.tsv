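instrument	scale	items	forum_matched	facebook_matched
EORTC QLQ-C30	Physical functioning	1-5	1	1
EORTC QLQ-C30	Role functioning	6-7	1	0
EORTC QLQ-C30	Emotional functioning	21-24	1	1
EORTC QLQ-C30	Cognitive functioning	20,25	1	0
EORTC QLQ-C30	Social functioning	26-27	1	1
EORTC QLQ-C30	Fatigue	10,12,18	1	1
EORTC QLQ-C30	Nausea and vomiting	14-15	1	1
EORTC QLQ-C30	Pain	9,19	1	1
EORTC QLQ-C30	Dyspnea	8	1	1
EORTC QLQ-C30	Insomnia	11	1	1
EORTC QLQ-C30	Appetite loss	13	1	1
EORTC QLQ-C30	Constipation	16	1	1
EORTC QLQ-C30	Diarrhea	17	1	1
EORTC QLQ-C30	Financial difficulties	28	1	1
EORTC QLQ-C30	Global health status and quality of life	29-30	0	0
EORTC QLQ-BR23	Body image	39-42	1	1
EORTC QLQ-BR23	Sexual functioning	44-45	1	1
EORTC QLQ-BR23	Sexual enjoyment	46	1	1
EORTC QLQ-BR23	Future perspectives	43	1	1
EORTC QLQ-BR23	Systemic therapy side effects	31-34,36-38	1	1
EORTC QLQ-BR23	Breast symptoms	50-53	1	1
EORTC QLQ-BR23	Arm symptoms	47-49	1	1
EORTC QLQ-BR23	Hair loss	35	1	1
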