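descriptor	tree_numbers
Bacterial Infections and Mycoses	C01
Tuberculosis	C01.252.410.040.552.846
Virus Diseases	C02
HIV Infections	C02.782.815.616.400|C20.673.480
Influenza, Human	C02.782.620.365
Parasitic Diseases	C03
Malaria	C03.752.530
Neoplasms	C04
Breast Neoplasms	C04.588.180
Lung Neoplasms	C04.588.894.797.520
Colorectal Neoplasms	C04.588.274.476.411.307
Musculoskeletal Diseases	C05
Osteoporosis	C05.116.198.579
Digestive System Diseases	C06
Liver Cirrhosis	C06.552.630
Stomatognathic Diseases	C07
Periodontitis	C07.465.714.533.324
Respiratory Tract Diseases	C08
Asthma	C08.127.108
Pulmonary Disease, Chronic Obstructive	C08.381.495.389
Nervous System Diseases	C10
Stroke	C10.228.140.300.775|C14.907.253.855
Alzheimer Disease	C10.228.140.380.100
Eye Diseases	C11
Urologic and Male Genital Diseases	C12
Kidney Diseases	C12.777.419
Female Genital Diseases and Pregnancy Complications	C13
Pre-Eclampsia	C13.703.395.249
Cardiovascular Diseases	C14
Myocardial Infarction	C14.280.647.500|C14.907.585.500
Hypertension	C14.907.489
Hemic and Lymphatic Diseases	C15
Anemia	C15.378.071
Congenital, Hereditary, and Neonatal Diseases and Abnormalities	C16
Skin and Connective Tissue Diseases	C17
Psoriasis	C17.800.859.675
Nutritional and Metabolic Diseases	C18
Diabetes Mellitus, Type 2	C18.452.394.750.149|C19.246.267
Obesity	C18.654.726.500
Endocrine System Diseases	C19
Immune System Diseases	C20
Disorders of Environmental Origin	C21
Animal Diseases	C22
Pathological Conditions, Signs and Symptoms	C23
Inflammation	C23.550.470
Physical Phenomena	G01
Chemical Phenomena	G02
Metabolism	G03
Cell Physiological Phenomena	G04
Genetic Phenomena	G05
Polymorphism, Single Nucleotide	G05.365.590.175.617
Genotype	G05.380
Genetic Predisposition to Disease	G05.420
Microbiological Phenomena	G06
Drug Resistance, Microbial	G06.099.375
Physiological Phenomena	G07
Reproductive and Urinary Physiological Phenomena	G08
Circulatory and Respiratory Physiological Phenomena	G09
Digestive, Oral, and Skin Physiological Phenomena	G10
Musculoskeletal and Neural Physiological Phenomena	G11
Immune System Phenomena	G12
Biological Phenomena	G16
Mathematical Concepts	G17
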