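# Peptide-binding-region (PBR) mask for the 159-bp MHC class II beta exon 2
# fragment (53 codons, frame offset 0).
#
# PBR codons are inferred by assuming functional congruence to the human
# HLA-DR1 molecule (beta-chain peptide-contact residues of Brown et al. 1993,
# Nature 364:33-39), with the fragment assumed to start at beta-chain
# position 11 so that fragment codon i corresponds to HLA-DR beta residue
# i + 10.  Contact residues 11, 13, 26, 28, 30, 32, 37, 38, 47, 56, 60 and 61
# fall inside that window.  The register against HLA-DR1 is an assumption:
# replace this file if locus-specific structural information is available.
frame_offset: 0
fragment_length: 159
pbr_codons: [1, 3, 16, 18, 20, 22, 27, 28, 37, 46, 50, 51]
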