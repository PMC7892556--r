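# Synthetic Masson-trichrome-like stain optical-density vectors (unit norm).
# Rows: collagen (aniline-blue-like), cytoplasm/nuclei (fuchsin/hematoxylin
# blend), residual (orthogonal complement). Columns: R G B.
0.74966273 0.59973018 0.27987408
0.26987858 0.71967622 0.63971219
0.31295469 0.69385348 0.64855741
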