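# Curated catalog of literature-reported miRNAs associated with response of
# colorectal cancer to preoperative (neoadjuvant) chemoradiotherapy, with the
# NOD value each miRNA attains in an integrated human miRNA-mRNA regulatory
# network. reported_id is the name used in the source study; official_id the
# reconciled (miRBase) name.
reported_id	official_id	year	expression_level	sample_type	nod
miR-630	miR-630	2011	up	tissue	5
miR-622	miR-622	2011	up	tissue	1
miR-483-5p	miR-483-5p	2011	up	tissue	4
miR-125a-3p	miR-125a-3p	2011	up	tissue	2
miR-188-5p	miR-188-5p	2011	up	tissue	1
miR-671-5p	miR-671-5p	2011	up	tissue	10
miR-765	miR-765	2011	up	tissue	10
miR-196b	miR-196b-5p	2012	up	tissue	12
let-7e	let-7e-5p	2012	up	tissue	2
miR-223	miR-223-3p	2012	up	tissue	9
let-7a	let-7a-5p	2013	up	cell lines	5
miR-21	miR-21-5p	2013	up	cell lines	38
miR-221	miR-221-3p	2013	up	cell lines	11
miR-132	miR-132-3p	2013	up	cell lines and tissue	8
miR-224	miR-224-5p	2013	up	cell lines and tissue	13
let-7g	let-7g-5p	2013	up	cell lines and tissue	17
miR-125b	miR-125b-5p	2008	down	tissue	33
miR-137	miR-137	2008	down	tissue	17
miR-451	miR-451a	2009	down	cell lines and tissue	4
miR-143	miR-143-3p	2011	down	tissue	15
miR-145	miR-145-5p	2011	down	tissue	36
miR-215	miR-215	2012	down	tissue	1
miR-200c	miR-200c-3p	2013	down	tissue	13
miR-320a	miR-320a	2013	down	cell lines and tissue	15
miR-124	miR-124-3p	2014	down	cell lines and tissue	51
miR-16	miR-16-5p	2012	NA	tissue	7
miR-590-5p	miR-590-5p	2012	NA	tissue	14
miR-153	miR-153	2012	NA	tissue	1
miR-519c-3p	miR-519c-3p	2012	NA	tissue	1
miR-561	miR-561-3p	2012	NA	tissue	15
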