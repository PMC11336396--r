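name	sequence	orientation	target_region	note
LF350End	ccgatagcgaacaagtac	forward	LSU	published with this marker system; also amplifies many other fungi
LR3-End2	aycattahgycagcgacc	reverse	LSU	published with this marker system; >99% of Endogonomycetes
LR3-End2a	aycattahgycagccgtta	reverse	LSU	published with this marker system; Unemaeeaceae
AMV4.5NF		forward	SSU	placeholder; supply sequence from the cited literature
AMDGR		reverse	SSU	placeholder; supply sequence from the cited literature
AM-Sal-F		forward	SSU	placeholder; supply sequence from the cited literature
FRE-F		forward	SSU	placeholder; supply sequence from the cited literature
FRE-R		reverse	SSU	placeholder; supply sequence from the cited literature
wSSUmcf		forward	SSU	placeholder; supply sequence from the cited literature
ITS1F		forward	ITS	placeholder; supply sequence from the cited literature
ITS1		forward	ITS	placeholder; supply sequence from the cited literature
gITS7ngs		forward	ITS	placeholder; supply sequence from the cited literature
ITS4ngsUni		reverse	ITS	placeholder; supply sequence from the cited literature
ITS9munngs		forward	ITS	placeholder; supply sequence from the cited literature
ITS1catta		forward	ITS	placeholder; supply sequence from the cited literature
wLSUmbr		reverse	LSU	placeholder; supply sequence from the cited literature
LROR		forward	LSU	placeholder; supply sequence from the cited literature
TW13		reverse	LSU	placeholder; supply sequence from the cited literature
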