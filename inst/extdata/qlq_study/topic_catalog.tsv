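label	forum_topic	facebook_topic	questionnaire_match
Hair loss	1	4	Yes
Work life during cancer and financial aspects	2	8	Yes
Chemotherapy and its secondary effects	3	2	Yes
Breast reconstruction	5	9	Yes
Support from patient's family and friends	6	10	Yes
Support from patient's family and friends	NA	19	Yes
Family members with breast cancer	10	17	No
Treatment period	11	20	Yes
Healing	13	18	Yes
Diagnosis	16	1	Yes
Breast cancer as a daily battle	17	3	Yes
Body care and body image during cancer, and sexuality	18	6	Yes
Body care and body image during cancer, and sexuality	NA	15	Yes
Body care and body image during cancer, and sexuality	NA	16	Yes
Hormone therapy and its secondary effects	4	NA	Yes
Radiotherapy and its secondary effects	7	NA	Yes
Complementary and alternative medicine	8	NA	No
Media and forum information exchange	9	NA	Yes
Everyday life during cancer	12	NA	Yes
Search for medical information	14	NA	Yes
Mourning	15	NA	No
Surgery	19	NA	Yes
Waiting for results of analysis, concerns	20	NA	Yes
Secondary effects of treatments	NA	5	Yes
Family background and breast cancer	NA	7	No
Interaction with nurses and doctors	NA	11	Yes
Anxiety and fatigue	NA	12	Yes
Healing of family member	NA	13	No
Relapse	NA	14	Yes
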