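issn	title
1932-6203	PLoS ONE
1549-1676	PLoS Medicine
2044-6055	BMJ Open
1471-2458	BMC Public Health
1471-2288	BMC Medical Research Methodology
2045-2322	Scientific Reports
9000-0002	Synthetic Open Access Journal of Epidemiology
9000-0005	Synthetic Open Access Clinical Reports
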