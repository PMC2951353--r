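# Synthetic opposing-lesion (pQTo-like) architecture: both strands carry
# a T-T lesion at the same site, so no error-free (template-switch)
# product exists.  Coordinates are 0-based half-open.
id: pqto_synthetic
arrangement: opposing
reference: CAAAAATCTTCGTCTGCTCATAAGAGGGCTGGGCGCGGATAAATGTGTTCTTTGTAACCTGCTCAGCAATGCTGGAGCGGCACGGACCACATGCATTGTT
top_site: [50, 52]
bottom_site: [50, 52]
marker: GC
accurate: AA
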