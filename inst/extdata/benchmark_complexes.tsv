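pdb_id	classification	protein_chain	peptide_chain	peptide_length	resolution
1CJR	Hydrolase	B	A	15	2.3
1CKA	Oncogene protein	A	B	9	1.5
1D4T	Signaling protein	A	B	11	1.1
1EG4	Structural protein	A	P	13	2.0
1H6W	Structural protein	A	B	10	1.9
1HC9	Toxin protein	A	C	13	1.8
1JBU	Hydrolase	H	X	15	2.0
1MFG	Signaling protein	A	B	9	1.25
1NLN	Hydrolase	A	B	11	1.6
1NQ7	Transcription	A	B	10	1.5
1NTV	Signaling protein	A	B	10	1.5
1NX1	Hydrolase inhibitor	A	C	11	2.0
1OAI	Nuclear transport	A	B	9	1.55
1OJ5	Transcriptional activator	A	B	14	2.21
1OW6	Transferase	A	D	12	2.35
1PZL	Transcription	A	B	14	2.1
1QKZ	Immune system	H	P	10	1.95
1RXZ	Replication	A	B	11	2.0
1SFI	Hydrolase	A	I	14	1.65
1SSH	Contractile protein	A	B	11	1.4
1 T0	8Cell cycle protein	A	C	15	2.1
1T4F	Ligase	M	P	9	1.9
1T7R	Growth factor protein	A	B	10	1.4
1TFC	Transcription	A	C	11	2.4
1 U0	0Chaperone protein	A	P	9	1.95
1UJ0	Signaling protein	A	B	9	1.7
1X2R	Transcription	A	B	9	1.7
1XOC	Transport protein	A	B	9	1.55
1YMT	Transcription	A	B	10	1.2
1YUC	Transcriptional Regulation	A	C	14	1.9
1YWO	Signaling protein	A	P	10	1.81
2A31	Transferase	A	B	12	1.25
2AQ9	Transferase	A	X	12	1.8
2B9H	Transferase	A	C	12	1.55
2BBA	Signaling protein	A	P	14	1.65
2CCH	Cell cycle protein	D	F	12	1.7
2D0N	Signaling protein	C	D	9	1.57
2DRK	Contractile protein	A	B	10	1.42
2FFF	Transferase	B	A	15	2.23
2FKA	Signaling protein	A	B	10	2.0
2FMF	Signaling protein	A	B	13	1.99
2FTS	Structural protein	A	P	13	2.41
2FVJ	Signaling protein	A	B	10	1.99
2HO2	Protein binding	A	B	10	1.33
2HT9	Oxidoreductase	A	X	12	1.9
2O02	Toxin protein	A	P	14	1.5
2O4J	Growth factor protein	A	C	12	1.74
2O9V	Signaling protein	A	B	10	1.63
2P0W	Transferase	A	P	15	1.9
2P1O	Hydrolase	B	C	13	1.9
2P1T	Hormone receptor	A	B	10	1.8
2P54	Transcription	A	B	12	1.79
2PEH	Protein binding	A	C	10	2.11
2PUX	Hydrolase	B	C	13	2.0
2PUY	Transcription	B	E	10	1.43
2QBX	Signaling protein	B	D	11	2.3
2QOS	Immune System	C	A	11	1.81
2QSE	Transcription	B	D	11	1.85
2R7G	Transcription repressor	C	D	10	1.67
2V8Y	Translation	A	B	14	2.1
2VR3	Cell adhesion protein	B	D	13	1.95
2VWF	Signaling	A	B	14	1.58
2W2U	Hydrolase	A	C	11	2.2
2WHX	Hydrolase	A	C	14	2.2
2XRW	Transcription	A	B	12	1.33
2XU7	Transcription	B	C	12	1.9
2XVC	Cell cycle protein	A	B	13	2.15
2ZJD	Apoptosis protein	A	B	10	1.56
3AWR	Transport protein	A	C	12	2.0
3AYU	Hydrolase	A	B	10	2.0
3BFQ	Structural	G	F	15	1.34
3C3R	Transport	A	B	13	2.02
3D32	Transport	A	C	12	1.3
3DS4	Viral protein	A	T	12	1.12
3FDO	Cell cycle protein	A	B	12	1.4
3G2S	Signaling protein	A	C	11	1.7
3GYT	Transcription	A	B	10	2.4
3H1Z	Transferase	A	P	15	1.83
3KMR	Transcription	A	C	10	1.8
3KUJ	Protein binding	A	B	15	1.4
3KUS	Protein binding	A	C	11	1.4
3L0E	Transcription	A	B	12	2.3
3LLZ	Sugar binding	A	B	14	1.55
3OLF	Hormone protein	A	B	11	1.9
3P72	Clotting protein	A	B	11	1.9
3P8F	Hydrolase	A	I	14	2.0
3PTL	Hydrolase	A	B	10	1.3
3QIS	Hydrolase	A	B	13	2.3
3RQG	Protein binding	C	E	12	2.5
3SFJ	Signaling protein	A	B	10	1.24
3SO6	Protein binding	A	Q	13	1.37
3TZY	Transferase	B	C	10	2.2
3UP3	Transcription	A	P	13	1.25
3V2X	Protein binding	A	B	11	1.85
3VTC	Transcription	A	B	11	1.5
3W1B	Ligase	A	B	10	2.4
3ZQH	Transcription	A	C	12	1.6
4B4N	Viral protein	A	B	15	1.81
4DCB	Hydrolase	A	F	11	2.03
4E34	Transport	B	D	10	1.39
4EIK	Protein binding	A	B	11	1.6
4ERY	Transcription	A	D	14	1.3
4F14	Actin binding	A	B	11	1.2
4F1Z	Cell adhesion protein	A	Q	14	2.3
4GQ6	Transcription	A	B	12	1.55
4GXL	Protein binding	A	B	11	2.02
4GYW	Transferase	A	B	14	1.7
4H4F	Hydrolase	A	Q	10	1.9
4HOM	Hydrolase	A	B	11	1.9
4HTP	Hydrolase	A	C	10	2.25
4IIM	Endocytosis	A	C	12	1.8
4J8S	Protein binding	A	B	12	1.55
4K0U	Protein transport	A	B	15	2.15
1CVU	Oxidoreductase	B	F	9	2.4
1K5N	Immune system	A	C	9	1.09
1OU8	Transport	A	C	11	1.6
1RST	Signaling	B	P	9	1.7
2A25	Ligase	A	B	9	2.2
2 CE	8Transcription	A	X	9	2.03
2DYP	Immune system	A	C	9	2.5
2FFU	Transferase	A	P	9	1.64
2OEI	Protein binding	A	B	9	1.35
2R9Q	Hydrolase	B	Y	9	2.2
2VKN	Membrane protein	A	C	9	2.05
3ASL	DNA binding protein	A	B	9	1.41
3ERY	Immune system	A	P	9	1.95
3I5R	Protein binding	A	B	9	1.7
3IVV	Ligase	A	D	10	1.25
3LL8	Protein binding	A	E	11	2.0
3OBQ	Transport	A	B	9	1.4
3RM1	Protein binding	A	B	9	1.24
3TJV	Hydrolase	A	B	9	2.4
3U9Q	Transcription	A	B	9	1.52
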