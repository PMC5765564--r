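issn	title
0002-9343	The American Journal of Medicine
0003-4819	Annals of Internal Medicine
0098-7484	JAMA
0028-4793	The New England Journal of Medicine
0140-6736	Lancet
0959-8138	BMJ
0003-9926	Archives of Internal Medicine
0012-3692	Chest
0009-7322	Circulation
0002-8703	American Heart Journal
0735-1097	Journal of the American College of Cardiology
0002-9149	The American Journal of Cardiology
0016-5085	Gastroenterology
0002-9270	The American Journal of Gastroenterology
0022-3476	The Journal of Pediatrics
0031-4005	Pediatrics
0002-9378	American Journal of Obstetrics and Gynecology
0029-7844	Obstetrics and Gynecology
0028-3878	Neurology
0003-990X	Archives of General Psychiatry
0002-953X	The American Journal of Psychiatry
0003-4932	Annals of Surgery
0004-0010	Archives of Surgery
0022-5223	The Journal of Thoracic and Cardiovascular Surgery
0021-9355	The Journal of Bone and Joint Surgery
0301-620X	The Journal of Bone and Joint Surgery. British Volume
0023-852X	The Journal of Clinical Investigation
0022-1767	Journal of Immunology
0022-1899	The Journal of Infectious Diseases
1058-4838	Clinical Infectious Diseases
0027-8874	Journal of the National Cancer Institute
0732-183X	Journal of Clinical Oncology
0008-543X	Cancer
0003-4967	Annals of the Rheumatic Diseases
0004-3591	Arthritis and Rheumatism
0091-6749	The Journal of Allergy and Clinical Immunology
1073-449X	American Journal of Respiratory and Critical Care Medicine
0090-3493	Critical Care Medicine
0196-0644	Annals of Emergency Medicine
0017-5749	Gut
0041-1345	Transplantation
0085-2538	Kidney International
0272-6386	American Journal of Kidney Diseases
0021-972X	The Journal of Clinical Endocrinology and Metabolism
0012-1797	Diabetes
0149-5992	Diabetes Care
0002-9165	The American Journal of Clinical Nutrition
0003-9950	Archives of Neurology
0887-8994	Pediatric Neurology
0002-9394	American Journal of Ophthalmology
0003-9950	Archives of Ophthalmology
0194-5998	Otolaryngology - Head and Neck Surgery
0003-4894	The Annals of Otology, Rhinology, and Laryngology
0002-9610	American Journal of Surgery
0148-396X	Neurosurgery
0022-3085	Journal of Neurosurgery
0033-8419	Radiology
0361-803X	AJR. American Journal of Roentgenology
0002-9262	American Journal of Epidemiology
0090-0036	American Journal of Public Health
0025-7974	Medicine
0954-6820	Journal of Internal Medicine
0007-0963	The British Journal of Dermatology
0003-987X	Archives of Dermatology
0022-202X	The Journal of Investigative Dermatology
0012-3706	Diseases of the Colon and Rectum
0002-9629	The American Journal of the Medical Sciences
0025-6196	Mayo Clinic Proceedings
0041-4131	Urology
0022-5347	The Journal of Urology
0002-9580	Anesthesiology
0003-2999	Anesthesia and Analgesia
0007-0912	British Journal of Anaesthesia
0304-3959	Pain
0003-4819	Annals of Internal Medicine
1538-3598	JAMA
9000-0003	Synthetic Core Clinical Journal of Medicine
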