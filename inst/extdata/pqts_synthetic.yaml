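# Synthetic staggered-lesion (pQTs-like) architecture for examples and
# tests.  The reference is the marker-form top strand: the GC marker
# dinucleotide is read at both lesion sites, which are separated by 28
# intervening nucleotides.  Coordinates are 0-based half-open.
id: pqts_synthetic
arrangement: staggered
reference: GATCGCGATCCATACGACAAAACGTATAGTTCATCGCGAACAATCACAAAGCCGCGAGCCAGTTTGCCCCATGCTTAATTGCTTAACTCCTGATCTATAC
top_site: [35, 37]
bottom_site: [65, 67]
marker: GC
accurate: AA
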