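Optional inputs for the VPS72 cross-species conservation comparison
-------------------------------------------------------------------

Reference protein sequences are not redistributed with this package. To run
the full conservation comparison (including the acceptance test in
tests/testthat/test-acceptance.R), place two files in this directory:

1. vps72_clustalo_aln.fasta
   ClustalO alignment (aligned FASTA) of the five VPS72 orthologs, with the
   NCBI accession as the sequence id:
     NP_005988.1      human
     NP_033362.2      mouse
     NP_001085907.1   Xenopus
     NP_001285823.1   fruit fly
     AHY75432.1       budding yeast (SWC2)

2. yl1c_spans.csv
   Per-sequence YL1-C (pfam08265) spans in ungapped 1-based residue
   coordinates, per the NCBI domain annotations:
     id,start,end
     NP_005988.1,<start>,<end>
     ...

Fetch the sequences from NCBI (e.g. efetch), align with ClustalO default
settings, and read the YL1-C coordinates from each accession's feature
table.
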