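"study","n","accuracy","year","modality","classifier"
"synthetic-001",89,78.8,2013,"brain imaging","logistic regression"
"synthetic-002",257,72.5,2017,"motion tracking","SVM"
"synthetic-003",276,76.7,2013,"brain imaging","logistic regression"
"synthetic-004",223,73.9,2009,"brain imaging","neural network"
"synthetic-005",204,85.9,2015,"brain imaging","logistic regression"
"synthetic-006",162,81.1,2015,"brain imaging","SVM"
"synthetic-007",563,69.9,2009,"motion tracking","SVM"
"synthetic-008",1501,64.4,2019,"brain imaging","neural network"
"synthetic-009",152,83.7,2019,"brain imaging","SVM"
"synthetic-010",120,88,2013,"motion tracking","SVM"
"synthetic-011",106,76.7,2007,"brain imaging","other"
"synthetic-012",278,72.3,2009,"other","logistic regression"
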