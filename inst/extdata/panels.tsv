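name	wash_mode	is_verify	FL1	FL2	FL3	FL4	FL5	FL6	FL7	FL8	FL9	FL10
Verify-LNW	lyse_no_wash	TRUE	CD8	CD2	CD20	CD14	CD3	CD7	CD19	CD5	CD4	CD45
TBNK/M/G	lyse_no_wash	FALSE	CD15	gdTCR	CD16	CD14	CD56	CD19	CD8	CD3	CD4	CD45
Verify-LW	lyse_wash	TRUE	CD8	CD2	CD20	CD14	CD3	CD7	CD19	CD5	CD4	CD45
T Cell-1	lyse_wash	FALSE	CCR7	CD27	CD45RO	CD25	CD3	CD62L	CD127	CD45RA	CD4	CD8
T Cell-2	lyse_wash	FALSE	CCR7	CD272	CD45RO	TIM-3	PD-1	CTLA4	CD8	CD28	CD4	CD3
B cell	lyse_wash	FALSE	IgD	CD27	CD20	CD38	CD5	IgM	CD19	CD24	CD21	CD45
Myeloid	lyse_wash	FALSE	LIN2	CD123	HLA-DR	CD11c	CD11b	CD33	CD16	CD66b	CD15	CD45
Monocytes-1	lyse_wash	FALSE	CD80	CD142	CD14	CD32	CD64	CD86	unstained	CD16	HLA-DR	CD45
Monocytes-2	lyse_wash	FALSE	B7H1	TNFR2	CD14	unstained	PD-1	CD40	unstained	CD16	HLA-DR	CD45
Granulocytes	lyse_wash	FALSE	CD66b	CD63	CD14	CD44	CD203c	CCR3	CD16	CD49d	CD15	CD45
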