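code	common_name	function_note	ss	CD33	CD11b	CD11c	CD14	CD16	HLA-DR	CD15	CD66b	CD123
CM1	Classical monocytes	Mixed	med	++	++	++	+	-	+	-	-	-
CM2	Intermediate monocytes	Positive	med	++	++	++	+	+	+	-	-	-
CM3	Non-classical monocytes	Positive (killer myeloid cells)	med	++	++	++	lo	+	+	-	-	-
CM4	Suppressive monocytes (MO-MDSC)	Suppressive	med	++	++	++	+	-/+	lo/neg	-	-	-
CM5	Monocytic dendritic cells	Positive	lo	++	+/-	++	-	-	+	-	-	-
CM6	CD16+ dendritic cells	Positive	lo	+	+/-	++	-	+	+	-	-	-
CM7	Immature myeloid cells and/or MDSCs	Suppressive	lo	+	++	+	-	-	-	-	-	+
CM8	Granulocytes/neutrophils	Mixed	hi	+	++	+	-	+	-	+	+	-
CM9	Granulocytes/eosinophils	Mixed	hi	+	++	+	-	-	-	+	+	-
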