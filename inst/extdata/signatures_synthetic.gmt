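molo_synthetic	synthetic reconstruction of an HSC-identity (MolO-style) signature	Procr	Slamf1	Hlf	Meis1	Fgd5	Mllt3	Pdzk1ip1	Gata2	Mycn	Ltb	Sult1a1	Gimap1	Vwf	Molo01	Molo02	Molo03	Molo04	Molo05	Molo06	Molo07	Molo08	Molo09	Molo10	Molo11	Molo12	Molo13	Molo14	Molo15	Molo16	Molo17	Molo18	Molo19	Molo20	Molo21	Molo22	Molo23	Molo24	Molo25	Molo26	Molo27
proliferation	HSC proliferation program: S and G2M phase markers	Mcm2	Mcm4	Mcm10	Rad51	Rad51ap1	Pcna	Ccnb1	Cdk1	Top2a	Mki67	Aurka	Bub1	Plk1
s_phase	S-phase marker genes	Mcm2	Mcm4	Mcm10	Rad51	Rad51ap1	Pcna
g2m_phase	G2M-phase marker genes	Ccnb1	Cdk1	Top2a	Mki67	Aurka	Bub1	Plk1
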