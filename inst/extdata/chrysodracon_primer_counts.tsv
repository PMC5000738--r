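species	level	primer	marker_system	n_scored	n_polymorphic	pct_printed
C_hawaiiensis	primer	OPA-02	RAPD	14	13	93
C_hawaiiensis	primer	OPA-09	RAPD	13	13	100
C_hawaiiensis	primer	OPB-04	RAPD	19	18	95
C_hawaiiensis	primer	OPB-07	RAPD	23	23	100
C_hawaiiensis	primer	OPB-08	RAPD	20	20	100
C_hawaiiensis	primer	OPB-14	RAPD	19	19	100
C_hawaiiensis	primer	OPC-07	RAPD	10	9	90
C_hawaiiensis	primer	OPD-02	RAPD	16	14	88
C_hawaiiensis	primer	OPD-05	RAPD	16	15	94
C_hawaiiensis	primer	OPD-12	RAPD	11	11	100
C_hawaiiensis	primer	OPD-15	RAPD	19	18	95
C_hawaiiensis	subtotal	NA	RAPD	180	173	96
C_hawaiiensis	primer	ISSR-5007	ISSR	22	21	95
C_hawaiiensis	primer	ISSR-5009	ISSR	13	12	92
C_hawaiiensis	primer	ISSR-5028	ISSR	14	12	86
C_hawaiiensis	subtotal	NA	ISSR	49	45	92
C_hawaiiensis	total	NA	NA	229	218	95
C_auwahiensis	primer	OPA-02	RAPD	21	20	95
C_auwahiensis	primer	OPA-09	RAPD	18	18	100
C_auwahiensis	primer	OPB-04	RAPD	12	12	100
C_auwahiensis	primer	OPB-07	RAPD	19	19	100
C_auwahiensis	primer	OPB-08	RAPD	20	20	100
C_auwahiensis	primer	OPB-14	RAPD	20	20	100
C_auwahiensis	primer	OPC-07	RAPD	14	14	100
C_auwahiensis	primer	OPD-02	RAPD	16	16	100
C_auwahiensis	primer	OPD-05	RAPD	21	21	100
C_auwahiensis	primer	OPD-12	RAPD	14	14	100
C_auwahiensis	primer	OPD-15	RAPD	23	21	91
C_auwahiensis	subtotal	NA	RAPD	198	195	98
C_auwahiensis	primer	ISSR-5007	ISSR	15	13	87
C_auwahiensis	primer	ISSR-5009	ISSR	12	9	75
C_auwahiensis	primer	ISSR-5028	ISSR	13	13	100
C_auwahiensis	subtotal	NA	ISSR	40	35	88
C_auwahiensis	total	NA	NA	238	230	97
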