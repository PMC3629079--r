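# Default full-text-allusion trigger lexicon: phrases whose presence in an
# abstract suggests additional curatable content in the full text
# (high-throughput assays, supplementary material). One phrase per line;
# matching is case-insensitive and anchored at token boundaries.
microarray
microarrays
proteomic
proteomics
transcriptome
transcriptomic
high-throughput
high throughput
genome-wide
rna-seq
supplementary
supporting information
mass spectrometry
expression profiling
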