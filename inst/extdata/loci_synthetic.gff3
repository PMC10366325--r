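##gff-version 3
# Synthetic genomic placements for the packaged mature miRNA set.
# Cluster composition mirrors the annotated human clusters
# (miR-302-367, miR-17-92, miR-106a-363, miR-106b-25, miR-200c-141);
# coordinates themselves are invented but internally consistent
# (end - start + 1 equals the mature length; intra-cluster gaps << 10 kb).
chr4	synthetic	miRNA	1128000	1128022	.	-	.	ID=hsa-mir-302b;Name=hsa-miR-302b-3p
chr4	synthetic	miRNA	1128150	1128172	.	-	.	ID=hsa-mir-302c;Name=hsa-miR-302c-3p
chr4	synthetic	miRNA	1128300	1128322	.	-	.	ID=hsa-mir-302a;Name=hsa-miR-302a-3p
chr4	synthetic	miRNA	1128450	1128472	.	-	.	ID=hsa-mir-302d;Name=hsa-miR-302d-3p
chr4	synthetic	miRNA	1128600	1128621	.	-	.	ID=hsa-mir-367;Name=hsa-miR-367-3p
chr13	synthetic	miRNA	9200000	9200022	.	+	.	ID=hsa-mir-17;Name=hsa-miR-17-5p
chr13	synthetic	miRNA	9200200	9200222	.	+	.	ID=hsa-mir-18a;Name=hsa-miR-18a-5p
chr13	synthetic	miRNA	9200400	9200422	.	+	.	ID=hsa-mir-19a;Name=hsa-miR-19a-3p
chr13	synthetic	miRNA	9200600	9200622	.	+	.	ID=hsa-mir-20a;Name=hsa-miR-20a-5p
chr13	synthetic	miRNA	9200800	9200822	.	+	.	ID=hsa-mir-19b-1;Name=hsa-miR-19b-3p
chr13	synthetic	miRNA	9201000	9201021	.	+	.	ID=hsa-mir-92a-1;Name=hsa-miR-92a-3p
chrX	synthetic	miRNA	1340000	1340022	.	-	.	ID=hsa-mir-106a;Name=hsa-miR-106a-5p
chrX	synthetic	miRNA	1340200	1340222	.	-	.	ID=hsa-mir-18b;Name=hsa-miR-18b-5p
chrX	synthetic	miRNA	1340400	1340422	.	-	.	ID=hsa-mir-20b;Name=hsa-miR-20b-5p
chrX	synthetic	miRNA	1340600	1340622	.	-	.	ID=hsa-mir-19b-2;Name=hsa-miR-19b-3p
chrX	synthetic	miRNA	1340800	1340821	.	-	.	ID=hsa-mir-92a-2;Name=hsa-miR-92a-3p
chrX	synthetic	miRNA	1341000	1341021	.	-	.	ID=hsa-mir-363;Name=hsa-miR-363-3p
chr7	synthetic	miRNA	2500000	2500020	.	-	.	ID=hsa-mir-106b;Name=hsa-miR-106b-5p
chr7	synthetic	miRNA	2500200	2500222	.	-	.	ID=hsa-mir-93;Name=hsa-miR-93-5p
chr7	synthetic	miRNA	2500400	2500421	.	-	.	ID=hsa-mir-25;Name=hsa-miR-25-3p
chr12	synthetic	miRNA	6964000	6964022	.	+	.	ID=hsa-mir-200c;Name=hsa-miR-200c-3p
chr12	synthetic	miRNA	6964500	6964521	.	+	.	ID=hsa-mir-141;Name=hsa-miR-141-3p
chr1	synthetic	miRNA	1561000	1561022	.	+	.	ID=hsa-mir-9-1;Name=hsa-miR-9-5p
chr8	synthetic	miRNA	9760000	9760019	.	-	.	ID=hsa-mir-124-1;Name=hsa-miR-124-3p
chr6	synthetic	miRNA	7140000	7140021	.	-	.	ID=hsa-mir-30a;Name=hsa-miR-30a-5p
chr1	synthetic	miRNA	1988280	1988302	.	-	.	ID=hsa-mir-181a-1;Name=hsa-miR-181a-5p
chr9	synthetic	miRNA	944000	944021	.	+	.	ID=hsa-let-7a-1;Name=hsa-let-7a-5p
chr6	synthetic	miRNA	332000	332020	.	+	.	ID=hsa-mir-219a-1;Name=hsa-miR-219a-5p
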