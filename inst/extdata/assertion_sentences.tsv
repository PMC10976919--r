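sentence	category	expected
There are no pathologically enlarged lymph nodes.	lymph_node	negated
No suspicious lymph nodes are seen.	lymph_node	negated
The mass is not seen on the current examination.	tumor	negated
There is no evidence of lymphadenopathy.	lymph_node	negated
Without evidence of a primary tumour.	tumor	negated
Absence of mediastinal lymphadenopathy.	lymph_node	negated
The examination is negative for malignancy.	tumor	negated
The lungs are free of masses.	tumor	negated
Lymphadenopathy is excluded.	lymph_node	negated
A spiculated mass is absent.	tumor	negated
No enlarged lymph nodes at station 4R.	lymph_node	negated
Enlarged lymph nodes are not identified.	lymph_node	negated
Negative for nodal metastasis.	lymph_node	negated
A cystic lesion rather than a tumour.	tumor	negated
No FDG-avid lymph nodes.	lymph_node	negated
No FDG-avid lymph nodes.	avidity_pos	negated
An enlarged lymph node without FDG uptake.	avidity_pos	negated
An enlarged lymph node without FDG uptake.	lymph_node	affirmed
No invasion of the chest wall.	invasion_target	negated
Suspicion of lymphadenopathy.	lymph_node	uncertain
Suspected for a primary lung carcinoma.	tumor	uncertain
Possible mass in the left lower lobe.	tumor	uncertain
Probable malignancy in the right upper lobe.	tumor	uncertain
Probably a benign lymph node.	lymph_node	uncertain
The opacity may represent a carcinoma.	tumor	uncertain
Findings are suspicious for a tumour.	tumor	uncertain
Suspect of lymphadenopathy in the mediastinum.	lymph_node	uncertain
A pathologic lymph node is suspected.	lymph_node	uncertain
A second mass is possible.	tumor	uncertain
Questionable enlarged lymph node at station 7.	lymph_node	uncertain
Differential diagnosis includes carcinoma and infection.	tumor	uncertain
There is likely a malignant mass.	tumor	uncertain
being suspicious for a lung carcinoma with lymph nodes suspect of lymphadenopathy	tumor	uncertain
being suspicious for a lung carcinoma with lymph nodes suspect of lymphadenopathy	lymph_node	uncertain
a lung carcinoma with lymphadenopathy	tumor	affirmed
a lung carcinoma with lymphadenopathy	lymph_node	affirmed
Lymphadenopathy cannot be excluded.	lymph_node	affirmed
A small tumour could not be excluded.	tumor	affirmed
The mass shows no significant change.	tumor	affirmed
Malignancy is not excluded.	tumor	affirmed
No pleural masses, but there is mediastinal lymphadenopathy.	lymph_node	affirmed
No pleural masses, but there is mediastinal lymphadenopathy.	tumor	negated
There is no primary tumour, however lymphadenopathy is present.	lymph_node	affirmed
There is no primary tumour, however lymphadenopathy is present.	tumor	negated
No enlarged nodes, although a mass persists.	tumor	affirmed
No enlarged nodes, although a mass persists.	lymph_node	negated
There is a spiculated mass in the right upper lobe.	tumor	affirmed
Enlarged lymph node at station 10L measuring 12 mm.	lymph_node	affirmed
FDG-avid subcarinal lymph node.	lymph_node	affirmed
FDG-avid subcarinal lymph node.	avidity_pos	affirmed
The paratracheal node is non-avid.	avidity_neg	affirmed
There is increased FDG uptake in the right hilum.	avidity_pos	affirmed
Known lung carcinoma with invasion of the mediastinum.	invasion_target	affirmed
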