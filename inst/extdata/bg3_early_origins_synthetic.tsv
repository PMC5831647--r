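chrom	center
chr2L	944410
chr2L	2520042
chr2L	3708479
chr2L	5961563
chr2L	7467361
chr2L	8696042
chr2L	10634561
chr2L	12050573
chr2L	12917948
chr2L	14871325
chr2L	16371049
chr2L	18217234
chr2L	19903230
chr2L	20933313
chr2L	22269981
chr2R	670403
chr2R	2397799
chr2R	4260636
chr2R	5700503
chr2R	7628899
chr2R	9082984
chr2R	10016955
chr2R	12191279
chr2R	13627617
chr2R	15277686
chr2R	16339368
chr2R	18206663
chr2R	19209082
chr2R	20874987
chr2R	22887054
chr2R	24588954
chr3L	894650
chr3L	2485531
chr3L	5079100
chr3L	7042870
chr3L	8350271
chr3L	9949209
chr3L	12536854
chr3L	13855418
chr3L	16074023
chr3L	17238180
chr3L	20104941
chr3L	21955520
chr3L	22983032
chr3L	25360822
chr3L	27538167
chr3R	1154775
chr3R	2691978
chr3R	4889407
chr3R	6996034
chr3R	8758595
chr3R	10817143
chr3R	12068238
chr3R	14167640
chr3R	16112684
chr3R	17933716
chr3R	19299254
chr3R	21939056
chr3R	23343201
chr3R	25037057
chr3R	27711344
chr3R	28577799
chr3R	30518070
chrX	1032386
chrX	2333818
chrX	4186293
chrX	5531002
chrX	6921124
chrX	8483406
chrX	10245777
chrX	11392932
chrX	13221272
chrX	15058072
chrX	16390237
chrX	17640912
chrX	19570332
chrX	21037126
chrX	22564092
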