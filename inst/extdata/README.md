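# Bundled fixtures (all synthetic)

- `prnp_mu_weights_synthetic.tsv` — synthetic PRNP-like per-codon
  mutation-frequency weights (253 codons, uniform weight 1 per codon).
  Real per-site mutation frequencies from a trinucleotide mutation model
  are not bundled; the uniform weights stand in for them.
- `prnp_gene_synthetic.tsv` — matching one-gene metadata table. The
  whole-transcript expected pLoF count (10.65) is a synthetic calibration
  chosen so that restricting to codons 1-144 under the uniform weights
  yields the curated region expectation of ~6.06 used in the package's
  worked examples.
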