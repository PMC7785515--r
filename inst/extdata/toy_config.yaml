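# Toy run configuration: package defaults with a smaller permutation
# budget, suitable for the worked example in the README.
n_perm_gwas: 1000
n_perm_gsea: 1000
seed: 42
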