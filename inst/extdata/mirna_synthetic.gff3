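##gff-version 3
# synthetic miRNA coordinates on the simulated two-chromosome layout
2	cnvseg	miRNA	1508000	1508090	.	+	.	ID=miR-24
2	cnvseg	miRNA	1530000	1530085	.	+	.	ID=miR-27a
2	cnvseg	miRNA	1555000	1555090	.	-	.	ID=miR-146b
2	cnvseg	miRNA	1580000	1580090	.	+	.	ID=miR-331
2	cnvseg	miRNA	1605000	1605090	.	-	.	ID=miR-503
2	cnvseg	miRNA	1630000	1630090	.	+	.	ID=miR-185
2	cnvseg	miRNA	1655000	1655090	.	+	.	ID=miR-424
2	cnvseg	miRNA	1680000	1680090	.	-	.	ID=miR-23a
1	cnvseg	miRNA	200000	200090	.	+	.	ID=miR-100
1	cnvseg	miRNA	400000	400090	.	-	.	ID=miR-200b
1	cnvseg	miRNA	600000	600090	.	+	.	ID=miR-335
1	cnvseg	miRNA	800000	800090	.	+	.	ID=miR-451
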