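family	domain_acc	domain_name
GH1	IPR001360	Glycoside hydrolase family 1
GH5	IPR001547	Glycoside hydrolase family 5 (cellulase family A)
GH28	IPR000743	Glycoside hydrolase family 28 (polygalacturonase)
GH45	IPR000334	Glycoside hydrolase family 45 (cellulase family K)
GH9	IPR001701	Glycoside hydrolase family 9
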