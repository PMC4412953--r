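# Exon -> protein-residue ranges for human tafazzin, full-length numbering,
# 1-based inclusive. Exon 5 (125-154, 30 residues) is exact; the remaining
# boundaries are approximate, chosen consistent with the published per-exon
# residue assignments (e.g. Asn40/Gly80 in exon 2, Leu82/Arg94 in exon 3,
# Gly240 in exon 10).
exon_id	start	end
1	1	39
2	40	80
3	81	100
4	101	124
5	125	154
6	155	182
7	183	196
8	197	226
9	227	238
10	239	248
11	249	292
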